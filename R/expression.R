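## Expression preprocessing: range filter -> z-normalization -> ternary
## discretization into over/under-expressed gene items. The steps are
## order-fixed: the range filter operates on the raw (RMA-summarized)
## values, normalization and discretization follow.

.exprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "exprs")
  } else {
    as.matrix(x)
  }
}

.replaceMatrix <- function(x, m) {
  if (methods::is(x, "SummarizedExperiment")) {
    out <- x[rownames(m), ]
    SummarizedExperiment::assay(out, "exprs") <- m
    out
  } else {
    m
  }
}

#' Range-based gene selection
#'
#' Removes probes whose profile variation, measured as max minus min over
#' subjects, is below `threshold`. A probe with range exactly equal to the
#' threshold is kept (the removal condition is strictly "less than").
#'
#' @param x a SummarizedExperiment (assay `exprs`) or numeric matrix,
#'   probes x subjects.
#' @param threshold minimum retained range (default 0.1, on the scale of
#'   the input values).
#' @return object of the same kind restricted to kept probes, with
#'   attribute/metadata `rangeFilter` = list(kept, removed, threshold).
#' @export
rangeFilter <- function(x, threshold = 0.1) {
  stopifnot(threshold > 0)
  m <- .exprMatrix(x)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix")
  rng <- apply(m, 1, max) - apply(m, 1, min)
  keep <- rng >= threshold
  out <- .replaceMatrix(x, m[keep, , drop = FALSE])
  info <- list(kept = sum(keep), removed = sum(!keep), threshold = threshold)
  if (methods::is(out, "SummarizedExperiment")) {
    S4Vectors::metadata(out)$rangeFilter <- info
  } else {
    attr(out, "rangeFilter") <- info
  }
  out
}

#' Per-gene zero-mean normalization
#'
#' Each profile g becomes (g - avg(g)) / std(g), with the sample mean and
#' sample (n-1) standard deviation computed across subjects.
#'
#' @inheritParams rangeFilter
#' @return object of the same kind with normalized values.
#' @export
zNormalize <- function(x) {
  m <- .exprMatrix(x)
  if (ncol(m) < 2) stop("need at least 2 subjects to normalize")
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  if (any(sd == 0)) {
    stop("zero-variance profile(s), e.g. '",
         rownames(m)[sd == 0][1],
         "': apply rangeFilter() before normalizing")
  }
  .replaceMatrix(x, (m - mu) / sd)
}

#' Ternary discretization into gene items
#'
#' A normalized value strictly above `hi` yields an over-expressed item
#' (probe, +1); strictly below `lo` an under-expressed item (probe, -1);
#' values in [lo, hi] are regarded as uninteresting and yield no item.
#'
#' @param x normalized SummarizedExperiment or matrix, probes x subjects.
#' @param hi over-expression threshold (default +1.0).
#' @param lo under-expression threshold (default -1.0).
#' @return a [TransactionDB-class]: one transaction per subject holding
#'   its gene items; class labels are taken from the `group` column of
#'   `colData` when present.
#' @export
ternaryDiscretize <- function(x, hi = 1.0, lo = -1.0) {
  stopifnot(hi > lo)
  m <- .exprMatrix(x)
  labels <- NULL
  if (methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if ("group" %in% names(cd)) labels <- cd$group
  }
  tx <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    c(makeItem(rownames(m)[v > hi], "+1"),
      makeItem(rownames(m)[v < lo], "-1"))
  })
  names(tx) <- colnames(m)
  buildTransactionDB(tx, labels = labels)
}
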