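## Shared fixtures: random small databases, canonical keys, and
## independent brute-force oracles used to cross-check the mining path.

## random transaction database: n transactions over m single-valued
## attributes, each item present with probability p (every transaction is
## kept, possibly empty)
randomDB <- function(n, m, p = 0.4) {
  items <- sprintf("a%02d=1", seq_len(m))
  tx <- lapply(seq_len(n), function(i) items[stats::runif(m) < p])
  buildTransactionDB(tx)
}

## canonical fingerprint of a closed-set listing (order-free comparison)
closedKey <- function(cs) {
  sort(vapply(cs, function(x) {
    paste(paste(sort(x$items), collapse = ","), x$support,
          paste(x$tids, collapse = "."), sep = "|")
  }, ""))
}

## independent support count: scan rows directly
naiveSupport <- function(db, itemset) {
  A <- db@incidence
  if (length(itemset) == 0) return(nrow(A))
  sum(apply(A[, itemset, drop = FALSE], 1, all))
}

## all frequent itemsets by exhaustive subset enumeration
naiveFrequent <- function(db, minSup) {
  items <- itemUniverse(db)
  out <- list(list(items = character(0), support = nrow(db@incidence)))
  for (k in seq_along(items)) {
    combs <- utils::combn(items, k, simplify = FALSE)
    for (J in combs) {
      s <- naiveSupport(db, J)
      if (s >= minSup) out[[length(out) + 1L]] <- list(items = J, support = s)
    }
  }
  out
}

## independent brute-force rule enumerator: every split (J, H) of every
## frequent closed itemset, same constraints as generateRules
naiveRules <- function(db, minSup, minConf,
                       constraint = consequentConstraint(mode = "any"),
                       antecedentPool = NULL) {
  freq <- naiveFrequent(db, minSup)
  isClosed <- function(J, s) {
    others <- setdiff(itemUniverse(db), J)
    !any(vapply(others, function(i) naiveSupport(db, c(J, i)) == s, TRUE))
  }
  keys <- character(0)
  for (f in freq) {
    C <- f$items
    if (length(C) < 2 || !isClosed(C, f$support)) next
    for (mask in seq_len(2^length(C) - 1)) {
      H <- C[bitwAnd(mask, bitwShiftL(1L, seq_along(C) - 1L)) != 0L]
      J <- setdiff(C, H)
      if (length(J) == 0) next
      if (!all(ClosedARM:::itemAttribute(H) %in% constraint$pool)) next
      if (constraint$mode == "at-least-one" &&
          !any(H %in% constraint$required)) next
      if (!is.null(antecedentPool) &&
          !all(ClosedARM:::itemAttribute(J) %in% antecedentPool)) next
      if (f$support / naiveSupport(db, J) < minConf - 1e-12) next
      keys <- c(keys, paste(paste(sort(J), collapse = ","),
                            paste(sort(H), collapse = ","), sep = " => "))
    }
  }
  sort(keys)
}

ruleKeys <- function(rules) {
  df <- rules@rules
  sort(vapply(seq_len(nrow(df)), function(i) {
    paste(paste(sort(df$antecedent[[i]]), collapse = ","),
          paste(sort(df$consequent[[i]]), collapse = ","), sep = " => ")
  }, ""))
}

## synthetic spec tailored for exact pattern recovery: disjoint planted
## attribute sets per group, neutral fixed background codes, one
## qualifying periodontal consequent per group
recoverySpec <- function(adherence = 1.0, ...) {
  patterns <- list(
    `1` = c(FPG = 3, HbA1c = 4, GI = 3),
    `2` = c(TC = 4, LDL = 5, BOP = 3),
    `3` = c(TG = 3, "N-HDL-C" = 5, "CALi3-4mm" = 3),
    `4` = c(BMI = 5, "HOMA-IR" = 2, CALi5mm = 3),
    `5` = c(WHR = 4, AC = 3, SUPP = 2)
  )
  background <- list(
    FPG = 1, HbA1c = 1, GI = 1, TC = 1, LDL = 1, BOP = 1,
    TG = 1, "N-HDL-C" = 1, "CALi3-4mm" = 1, BMI = 2, "HOMA-IR" = 1,
    CALi5mm = 1, WHR = 1, AC = 1, SUPP = 1, PPDi6mm = 1, HDL = 2
  )
  syntheticSpec(patterns = patterns, adherence = adherence,
                background = background, nDdlp = 0, ...)
}
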