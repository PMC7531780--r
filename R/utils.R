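## Small shared helpers.

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero for
#' positive values (half-up), the convention used when formatting rule
#' metrics for display. `base::round()` rounds half-to-even, which would
#' print e.g. 22/26 as 84.61 rather than 84.62.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  ## tiny nudge counters binary representation of exact .5 ratios
  floor(x * p + 0.5 + 1e-9) / p
}

## Item identifiers: "<attribute>=<value>". Gene items use values "+1"/"-1".
makeItem <- function(attribute, value) {
  if (length(attribute) == 0) return(character(0))
  paste0(attribute, "=", value)
}

itemAttribute <- function(item) {
  sub("=[^=]*$", "", item)
}

itemValue <- function(item) {
  sub("^.*=", "", item)
}

## Canonical, locale-independent item order.
sortItems <- function(items) {
  sort(items, method = "radix")
}

## Deterministic key for an itemset (character vector of item ids).
itemsetKey <- function(items) {
  paste(sortItems(items), collapse = ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
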