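#' Build a transaction database from item lists
#'
#' Each transaction is a character vector of item identifiers
#' (\code{"attribute=value"}). The item universe is the union of all items,
#' in canonical (radix-sorted) order; the per-item tid-sets are the columns
#' of the resulting incidence matrix.
#'
#' @param transactions list of character vectors of item ids; names, if
#'   present, become transaction identifiers.
#' @param labels optional class labels (one per transaction), coerced to a
#'   factor; used by [mineCARs()].
#' @return a [TransactionDB-class] object.
#' @examples
#' db <- buildTransactionDB(list(c("a=1"), c("a=1", "b=2"), c("b=2")))
#' supportCount(db, "a=1")
#' @export
buildTransactionDB <- function(transactions, labels = NULL) {
  if (length(transactions) == 0) {
    stop("empty database: no transactions supplied")
  }
  for (i in seq_along(transactions)) {
    tr <- transactions[[i]]
    attrs <- itemAttribute(tr)
    if (anyDuplicated(attrs)) {
      dup <- attrs[duplicated(attrs)][1]
      stop(sprintf(
        "transaction %s carries two values for attribute '%s'",
        names(transactions)[i] %||% i, dup))
    }
  }
  universe <- sortItems(unique(unlist(transactions, use.names = FALSE)))
  n <- length(transactions)
  A <- matrix(FALSE, n, length(universe),
              dimnames = list(names(transactions) %||% as.character(seq_len(n)),
                              universe))
  for (i in seq_len(n)) {
    A[i, transactions[[i]]] <- TRUE
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    labels <- as.factor(labels)
  }
  methods::new("TransactionDB", incidence = A, labels = labels)
}

#' @describeIn buildTransactionDB number of transactions.
#' @param db a TransactionDB.
#' @export
nTransactions <- function(db) nrow(db@incidence)

#' @describeIn buildTransactionDB the item universe (canonical order).
#' @export
itemUniverse <- function(db) colnames(db@incidence)

#' @describeIn buildTransactionDB per-transaction class labels (or NULL).
#' @export
classLabels <- function(db) db@labels

#' Transactions supporting an itemset
#'
#' Returns the tid-set of an itemset: the (1-based) indices of the
#' transactions that contain every item of `itemset`. The empty itemset is
#' supported by all transactions.
#'
#' @param db a [TransactionDB-class].
#' @param itemset character vector of item ids (possibly empty).
#' @return integer vector of transaction indices.
#' @export
tidsOf <- function(db, itemset) {
  A <- db@incidence
  unknown <- setdiff(itemset, colnames(A))
  if (length(unknown)) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "))
  }
  if (length(itemset) == 0) return(seq_len(nrow(A)))
  unname(which(rowSums(A[, itemset, drop = FALSE]) == length(itemset)))
}

#' Support of an itemset
#'
#' The absolute support sigma(J) = |tids(J)|, the number of transactions
#' containing all items of J. `supportCount(db, character(0))` equals the
#' number of transactions.
#'
#' @inheritParams tidsOf
#' @return integer count.
#' @export
supportCount <- function(db, itemset) {
  length(tidsOf(db, itemset))
}

#' Restrict a database to a subset of transactions and/or items
#'
#' @param db a [TransactionDB-class].
#' @param tids integer or character transaction selector (default all).
#' @param items character vector of item ids to keep (default all).
#' @param dropEmptyItems drop items no longer present in any kept
#'   transaction (default FALSE).
#' @return a [TransactionDB-class].
#' @export
subsetDB <- function(db, tids = NULL, items = NULL, dropEmptyItems = FALSE) {
  A <- db@incidence
  if (!is.null(tids)) {
    A <- A[tids, , drop = FALSE]
  }
  labels <- db@labels
  if (!is.null(labels) && !is.null(tids)) labels <- labels[tids]
  if (!is.null(items)) {
    A <- A[, intersect(colnames(A), items), drop = FALSE]
  }
  if (dropEmptyItems && nrow(A) > 0) {
    A <- A[, colSums(A) > 0, drop = FALSE]
  }
  methods::new("TransactionDB", incidence = A, labels = labels)
}

#' Combine two databases over the same transactions
#'
#' Joins the item universes of two databases describing the same subjects
#' (matched by transaction identifier), e.g. gene items and clinical-code
#' items for the microarray subset.
#'
#' @param db1,db2 [TransactionDB-class] objects with identical transaction
#'   identifier sets.
#' @return a [TransactionDB-class] whose universe is the union; labels are
#'   taken from `db1` if present, else `db2`.
#' @export
combineDB <- function(db1, db2) {
  ids <- rownames(db1@incidence)
  if (!setequal(ids, rownames(db2@incidence))) {
    stop("databases do not cover the same transactions")
  }
  B <- db2@incidence[ids, , drop = FALSE]
  shared <- intersect(colnames(db1@incidence), colnames(B))
  if (length(shared)) {
    stop("item universes overlap: ", paste(utils::head(shared, 3), collapse = ", "))
  }
  A <- cbind(db1@incidence, B)
  A <- A[, sortItems(colnames(A)), drop = FALSE]
  labels <- db1@labels %||% db2@labels[match(ids, rownames(db2@incidence))]
  methods::new("TransactionDB", incidence = A, labels = labels)
}

#' @describeIn buildTransactionDB show method
#' @export
setMethod("show", "TransactionDB", function(object) {
  cat(sprintf("TransactionDB: %d transactions x %d items\n",
              nrow(object@incidence), ncol(object@incidence)))
  if (!is.null(object@labels)) {
    tab <- table(object@labels)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
})
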