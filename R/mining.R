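## Closed frequent itemset enumeration.
##
## mineClosed() is a depth-first closure-extension enumerator (LCM-style
## prefix-preserving closure extension): each node holds a closed itemset
## P with tid-set T; extending by an item i > core(P) and taking the
## closure yields a new closed set, accepted only if the closure adds no
## item ordered before i outside P (the canonical prefix test), which
## guarantees each closed set is visited exactly once. Correctness is
## checked against the exhaustive brute-force oracle in the test suite:
## the closed set of a database at a given minimum support is unique, so
## oracle equivalence fully characterizes the output.

.emitClosed <- function(acc, items, tids) {
  acc$k <- acc$k + 1L
  acc$res[[acc$k]] <- list(items = items, tids = tids,
                           support = length(tids))
}

#' Enumerate all closed frequent itemsets
#'
#' Returns every itemset J with support >= `minSup` that is closed (no
#' proper superset has the same supporting transaction set), together
#' with its tid-set. The closure of the empty itemset (the items present
#' in every transaction) is always among the results; it is the empty
#' itemset itself iff no item is universal.
#'
#' @param db a [TransactionDB-class].
#' @param minSup minimum absolute support (a transaction count, >= 1).
#' @return list of records `list(items, tids, support)`, `items` being a
#'   character vector of item ids in canonical order.
#' @examples
#' db <- buildTransactionDB(list(c("a=1","b=2"), c("a=1","b=2"), "a=1"))
#' length(mineClosed(db, 1))  # {a=1} and {a=1,b=2}
#' @export
mineClosed <- function(db, minSup) {
  A <- db@incidence
  n <- nrow(A); m <- ncol(A)
  if (minSup < 1) stop("minSup must be a positive transaction count")
  if (minSup > n) {
    warning("minSup exceeds the number of transactions; no frequent itemsets")
    return(list())
  }
  acc <- new.env(parent = emptyenv())
  acc$res <- vector("list", 64L); acc$k <- 0L
  ids <- colnames(A)
  counts0 <- if (m > 0) colSums(A) else numeric(0)
  inP0 <- counts0 == n
  .emitClosed(acc, ids[inP0], seq_len(n))
  dfs <- function(inP, tids, core, counts) {
    cand <- which(!inP & counts >= minSup)
    cand <- cand[cand > core]
    for (i in cand) {
      newTids <- tids[A[tids, i]]
      newCounts <- colSums(A[newTids, , drop = FALSE])
      closed <- newCounts == length(newTids)
      ## prefix test: reject if the closure pulls in an item ordered
      ## before i that was not already in P
      added <- closed & !inP
      if (i > 1L && any(added[seq_len(i - 1L)])) next
      .emitClosed(acc, ids[closed], newTids)
      dfs(closed, newTids, i, newCounts)
    }
  }
  if (m > 0) dfs(inP0, seq_len(n), 0L, counts0)
  acc$res[seq_len(acc$k)]
}

#' Brute-force closed frequent itemset oracle
#'
#' Exhaustively enumerates all 2^m itemsets of a small database, keeps the
#' frequent ones and filters to those no single-item extension of which
#' preserves the support. Intended as an independent correctness oracle
#' for [mineClosed()] on small instances.
#'
#' @inheritParams mineClosed
#' @return same structure as [mineClosed()].
#' @export
bruteForceClosed <- function(db, minSup) {
  A <- db@incidence
  n <- nrow(A); m <- ncol(A)
  if (m > 20) stop("brute-force oracle refuses item universes above 20")
  if (n > 30) stop("brute-force oracle refuses more than 30 transactions")
  if (minSup < 1) stop("minSup must be a positive transaction count")
  if (minSup > n) {
    warning("minSup exceeds the number of transactions; no frequent itemsets")
    return(list())
  }
  bitOf <- bitwShiftL(1L, 0:(max(n, m) - 1L))
  fullTid <- sum(bitOf[seq_len(n)])
  ## tid-bitmask per item, then per itemset by DP over the subset lattice
  itemMask <- vapply(seq_len(m), function(j) {
    r <- which(A[, j])
    if (length(r)) sum(bitOf[r]) else 0L
  }, 0L)
  nMasks <- bitwShiftL(1L, m)
  tm <- integer(nMasks)
  tm[1] <- fullTid
  if (m > 0) {
    for (mask in seq_len(nMasks - 1L)) {
      low <- bitwAnd(mask, -mask)
      j <- match(low, bitOf)
      tm[mask + 1L] <- bitwAnd(tm[bitwXor(mask, low) + 1L], itemMask[j])
    }
  }
  popcount <- function(x) {
    s <- 0L
    for (b in seq_len(n)) s <- s + bitwAnd(bitwShiftR(x, b - 1L), 1L)
    s
  }
  supp <- vapply(tm, popcount, 0L)
  res <- list()
  for (mask in 0:(nMasks - 1L)) {
    s <- supp[mask + 1L]
    if (s < minSup) next
    isClosed <- TRUE
    for (j in seq_len(m)) {
      if (bitwAnd(mask, bitOf[j]) == 0L &&
          supp[bitwOr(mask, bitOf[j]) + 1L] == s) {
        isClosed <- FALSE
        break
      }
    }
    if (isClosed) {
      members <- which(bitwAnd(mask, bitOf[seq_len(m)]) != 0L)
      tids <- which(bitwAnd(tm[mask + 1L], bitOf[seq_len(n)]) != 0L)
      res[[length(res) + 1L]] <- list(items = colnames(A)[members],
                                      tids = tids, support = s)
    }
  }
  res
}

#' Closure of an itemset
#'
#' The maximal superset of `itemset` supported by exactly the same
#' transactions. Undefined (an error) when the itemset's tid-set is empty.
#'
#' @param db a [TransactionDB-class].
#' @param itemset character vector of item ids.
#' @return character vector: the closure, in canonical order.
#' @export
closureOf <- function(db, itemset) {
  tids <- tidsOf(db, itemset)
  if (length(tids) == 0) {
    stop("closure undefined: itemset is supported by no transaction")
  }
  A <- db@incidence
  counts <- colSums(A[tids, , drop = FALSE])
  colnames(A)[counts == length(tids)]
}
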