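#' TransactionDB: a binary transaction database
#'
#' Stores the n x m incidence matrix A of a transaction database: one row
#' per transaction (subject), one column per item, where an item is an
#' attribute=value pair such as \code{"FPG=3"} or \code{"229026_at=+1"}.
#' Transactions may optionally carry a class label (the patient group) for
#' class association rule mining.
#'
#' @slot incidence logical matrix, transactions x items; rownames are
#'   transaction identifiers, colnames are item identifiers of the form
#'   \code{attribute=value}.
#' @slot labels factor of class labels parallel to the rows, or NULL.
#'
#' @seealso [buildTransactionDB()], [mineClosed()], [mineCARs()]
#' @export
setClass("TransactionDB",
  representation(incidence = "matrix", labels = "ANY"),
  prototype(incidence = matrix(logical(0), 0, 0), labels = NULL)
)

setValidity("TransactionDB", function(object) {
  A <- object@incidence
  msg <- character(0)
  if (!is.logical(A)) {
    msg <- c(msg, "incidence matrix must be logical")
  }
  if (is.null(colnames(A)) && ncol(A) > 0) {
    msg <- c(msg, "incidence matrix must have item identifiers as colnames")
  }
  if (anyDuplicated(colnames(A))) {
    msg <- c(msg, "duplicated item identifiers")
  }
  if (!is.null(object@labels) && length(object@labels) != nrow(A)) {
    msg <- c(msg, "labels must have one entry per transaction")
  }
  ## one value per attribute within a transaction
  if (ncol(A) > 0) {
    attrs <- itemAttribute(colnames(A))
    for (a in unique(attrs)) {
      cols <- which(attrs == a)
      if (length(cols) > 1 && nrow(A) > 0) {
        if (any(rowSums(A[, cols, drop = FALSE]) > 1)) {
          msg <- c(msg, sprintf(
            "some transaction holds two values of attribute '%s'", a))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' RuleSet: a collection of association rules with their metrics
#'
#' Holds mined association rules (or class association rules) together with
#' the exact counts and metrics: rule support sigma_rule, antecedent support
#' sigma_head, consequent support sigma_tail, confidence and completeness
#' (stored as exact percentages) and relative-frequency lift. Metrics are
#' stored unrounded; display and file output round half-up to 2 decimals.
#'
#' @slot rules data.frame with list-columns `antecedent` and `consequent`
#'   (character vectors of item ids), optional `class` (class label for
#'   CARs, NA otherwise), integer counts `sigma_rule`, `sigma_head`,
#'   `sigma_tail`, and numeric `conf`, `comp` (percent), `lift`.
#' @slot n number of transactions the metrics refer to.
#' @slot params list of mining parameters (minSup, minConf, ...).
#' @export
setClass("RuleSet",
  representation(rules = "data.frame", n = "integer", params = "list"),
  prototype(rules = data.frame(), n = 0L, params = list())
)

setValidity("RuleSet", function(object) {
  df <- object@rules
  if (nrow(df) == 0) return(TRUE)
  need <- c("antecedent", "consequent", "sigma_rule", "sigma_head",
            "sigma_tail", "conf", "comp", "lift")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    return(paste("missing rule columns:", paste(miss, collapse = ", ")))
  }
  if (any(df$sigma_rule > pmin(df$sigma_head, df$sigma_tail))) {
    return("sigma_rule exceeds an antecedent/consequent support")
  }
  TRUE
})
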