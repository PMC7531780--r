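## Association-rule induction from closed frequent itemsets, the four rule
## metrics, interestingness constraints, and ranking heuristics.

#' The four rule metrics from raw counts
#'
#' Computes confidence (= sigma_rule/sigma_head) and completeness
#' (= sigma_rule/sigma_tail) as percentages, and relative-frequency lift
#' n*sigma_rule/(sigma_head*sigma_tail), all rounded half-up to 2
#' decimals. Lift is the ratio of the observed co-occurrence frequency to
#' the frequency expected under independence of antecedent and
#' consequent; values above 1 indicate positive association.
#'
#' @param sigma_rule support of the rule (transactions holding antecedent
#'   and consequent).
#' @param sigma_head antecedent support.
#' @param sigma_tail consequent support.
#' @param n number of transactions.
#' @return named numeric vector `c(conf, comp, lift)`.
#' @examples
#' ruleMetrics(14, 14, 74, 143)  # conf 100.00, comp 18.92, lift 1.93
#' @export
ruleMetrics <- function(sigma_rule, sigma_head, sigma_tail, n) {
  if (any(c(sigma_rule, sigma_head, sigma_tail, n) < 1)) {
    stop("all counts must be >= 1")
  }
  if (sigma_rule > sigma_head || sigma_rule > sigma_tail || sigma_tail > n ||
      sigma_head > n) {
    stop("count ordering violated: need sigma_rule <= sigma_head, ",
         "sigma_rule <= sigma_tail <= n")
  }
  c(conf = roundHalfUp(100 * sigma_rule / sigma_head),
    comp = roundHalfUp(100 * sigma_rule / sigma_tail),
    lift = roundHalfUp(n * sigma_rule / (sigma_head * sigma_tail)))
}

#' Default "interesting consequent" items for the CF analyses
#'
#' A rule is interesting when its consequent contains at least one marker
#' of periodontal disease activity: PPDi6mm = 2, or GI, BOP, CALi3-4mm,
#' CALi5mm or SUPP at code 2 or 3.
#' @return character vector of item ids.
#' @export
interestingPeriodontalItems <- function() {
  c(makeItem("PPDi6mm", 2),
    as.vector(outer(c("GI", "BOP", "CALi3-4mm", "CALi5mm", "SUPP"), 2:3,
                    makeItem)))
}

#' Consequent constraint for rule generation
#'
#' Restricts which consequents a generated rule may have: the consequent
#' may only contain items whose attribute is in `pool`, and (depending on
#' `mode`) must contain at least one / all of the `required` items, or
#' carry no item-level requirement ("any").
#'
#' @param pool attribute names allowed in the consequent (default the
#'   periodontal attributes).
#' @param required item ids triggering interestingness (default
#'   [interestingPeriodontalItems()]).
#' @param mode "at-least-one" (default), "all", or "any" (no requirement
#'   beyond the attribute pool).
#' @return a list of class `ConsequentConstraint`.
#' @export
consequentConstraint <- function(pool = periodontalAttributes(),
                                 required = interestingPeriodontalItems(),
                                 mode = c("at-least-one", "all", "any")) {
  mode <- match.arg(mode)
  if (mode != "any" && length(required) == 0) {
    stop("required item set must be nonempty")
  }
  structure(list(pool = pool, required = required, mode = mode),
            class = "ConsequentConstraint")
}

.constraintOK <- function(H, constraint) {
  switch(constraint$mode,
    "at-least-one" = any(H %in% constraint$required),
    "all" = all(constraint$required %in% H),
    "any" = TRUE)
}

.newRuleSet <- function(rows, n, params) {
  if (length(rows) == 0) {
    df <- data.frame(sigma_rule = integer(0), sigma_head = integer(0),
                     sigma_tail = integer(0), conf = numeric(0),
                     comp = numeric(0), lift = numeric(0),
                     class = character(0))
    df$antecedent <- I(list())
    df$consequent <- I(list())
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      d <- data.frame(sigma_rule = r$sigma_rule, sigma_head = r$sigma_head,
                      sigma_tail = r$sigma_tail, conf = r$conf,
                      comp = r$comp, lift = r$lift,
                      class = r$class %||% NA_character_,
                      stringsAsFactors = FALSE)
      d$antecedent <- I(list(r$antecedent))
      d$consequent <- I(list(r$consequent))
      d
    }))
  }
  methods::new("RuleSet", rules = df, n = as.integer(n), params = params)
}

## all nonempty subsets of a character vector (small cardinalities only)
.nonemptySubsets <- function(x) {
  k <- length(x)
  if (k == 0) return(list())
  if (k > 14) stop("consequent pool too large to enumerate subsets")
  lapply(seq_len(2^k - 1), function(mask) x[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L])
}

#' Generate strong association rules from closed frequent itemsets
#'
#' For each closed frequent itemset C, emits every rule J => H where H is
#' a nonempty subset of C's items satisfying the consequent constraint,
#' J = C \\ H is nonempty (and, when `antecedentPool` is given, contains
#' only attributes from that pool), and confidence >= `minConf`.
#' Antecedent and consequent supports are computed exactly by tid-set
#' intersection, even when J or H is itself not closed. The output is
#' sorted by confidence (desc), rule support (desc), then antecedent.
#'
#' @param closedSets result of [mineClosed()].
#' @param db the [TransactionDB-class] the sets were mined from.
#' @param minConf minimum confidence as a fraction in (0, 1].
#' @param constraint a [consequentConstraint()].
#' @param antecedentPool optional attribute names allowed in antecedents.
#' @return a [RuleSet-class].
#' @export
generateRules <- function(closedSets, db, minConf,
                          constraint = consequentConstraint(),
                          antecedentPool = NULL) {
  n <- nTransactions(db)
  rows <- list()
  for (cs in closedSets) {
    C <- cs$items
    if (length(C) < 2) next
    poolItems <- C[itemAttribute(C) %in% constraint$pool]
    if (length(poolItems) == 0) next
    for (H in .nonemptySubsets(poolItems)) {
      if (!.constraintOK(H, constraint)) next
      J <- setdiff(C, H)
      if (length(J) == 0) next
      if (!is.null(antecedentPool) &&
          !all(itemAttribute(J) %in% antecedentPool)) next
      sh <- supportCount(db, J)
      conf <- cs$support / sh
      if (conf < minConf - 1e-12) next
      st <- supportCount(db, H)
      rows[[length(rows) + 1L]] <- list(
        antecedent = sortItems(J), consequent = sortItems(H),
        sigma_rule = cs$support, sigma_head = sh, sigma_tail = st,
        conf = 100 * conf, comp = 100 * cs$support / st,
        lift = n * cs$support / (sh * st))
    }
  }
  rs <- .newRuleSet(rows, n, list(minConf = minConf))
  sortRules(rs)
}

#' Sort rules by confidence, support, then antecedent
#' @param rules a [RuleSet-class].
#' @return the same set, deterministically ordered.
#' @export
sortRules <- function(rules) {
  df <- rules@rules
  if (nrow(df) < 2) return(rules)
  key <- vapply(df$antecedent, itemsetKey, "")
  ord <- order(-df$conf, -df$sigma_rule, key, method = "radix")
  rules@rules <- df[ord, , drop = FALSE]
  rownames(rules@rules) <- NULL
  rules
}

#' Mine class association rules
#'
#' For each class label c, the closed frequent itemsets of the
#' transactions belonging to class c are enumerated at `minSup` (so the
#' rule support is sigma(J union {c})). A rule J => c is kept when its
#' confidence sigma(J union {c}) / sigma(J) — with sigma(J) counted over
#' ALL transactions — reaches `minConf`. Completeness is taken against
#' the class size and lift uses the full transaction count.
#'
#' @param db a labeled [TransactionDB-class] (see [buildTransactionDB()]).
#' @param minSup minimum absolute support within the class.
#' @param minConf minimum confidence as a fraction.
#' @return a [RuleSet-class] whose `class` column holds the consequent
#'   class label.
#' @export
mineCARs <- function(db, minSup, minConf) {
  labels <- classLabels(db)
  if (is.null(labels)) stop("class association rules need labeled transactions")
  n <- nTransactions(db)
  rows <- list()
  for (cl in levels(as.factor(labels))) {
    tids <- which(as.character(labels) == cl)
    if (length(tids) < minSup) {
      warning(sprintf("class %s has fewer transactions (%d) than minSup=%d",
                      cl, length(tids), minSup))
      next
    }
    sub <- subsetDB(db, tids = tids)
    for (cs in suppressWarnings(mineClosed(sub, minSup))) {
      J <- cs$items
      if (length(J) == 0) next
      sh <- supportCount(db, J)
      conf <- cs$support / sh
      if (conf < minConf - 1e-12) next
      st <- length(tids)
      rows[[length(rows) + 1L]] <- list(
        antecedent = sortItems(J), consequent = cl, class = cl,
        sigma_rule = cs$support, sigma_head = sh, sigma_tail = st,
        conf = 100 * conf, comp = 100 * cs$support / st,
        lift = n * cs$support / (sh * st))
    }
  }
  sortRules(.newRuleSet(rows, n, list(minSup = minSup, minConf = minConf)))
}

.isGeneItem <- function(items) itemValue(items) %in% c("+1", "-1")

#' Probes occurring in any rule antecedent
#'
#' The coverage of a CAR set: the set of distinct probes whose gene items
#' (probe, +1/-1) occur in at least one antecedent.
#'
#' @param cars a [RuleSet-class] of class association rules.
#' @return character vector of probe ids.
#' @export
coveredGenes <- function(cars) {
  items <- unlist(cars@rules$antecedent, use.names = FALSE)
  genes <- items[.isGeneItem(items)]
  unique(itemAttribute(genes))
}

#' Find genes carried by conflicting rules
#'
#' A probe conflicts when a gene item of it appears both in a rule for the
#' control class and in a rule for a non-control class. With
#' `key = "value"` (default) the same signed item (probe, value) must
#' appear on both sides; with `key = "gene"` any two items of the probe
#' suffice regardless of direction.
#'
#' @param cars a [RuleSet-class] of class association rules.
#' @param controlClass label of the control group (default "5").
#' @param key "value" or "gene".
#' @return character vector of conflicting probe ids.
#' @export
findConflictingGenes <- function(cars, controlClass = "5",
                                 key = c("value", "gene")) {
  key <- match.arg(key)
  df <- cars@rules
  if (nrow(df) == 0) return(character(0))
  perRule <- lapply(df$antecedent, function(a) a[.isGeneItem(a)])
  ctrl <- unique(unlist(perRule[df$class == controlClass], use.names = FALSE))
  other <- unique(unlist(perRule[df$class != controlClass], use.names = FALSE))
  if (key == "gene") {
    ctrl <- unique(itemAttribute(ctrl))
    other <- unique(itemAttribute(other))
    return(intersect(ctrl, other))
  }
  unique(itemAttribute(intersect(ctrl, other)))
}

#' Rank rules by an ordered criteria profile
#'
#' Stable lexicographic sort, all keys descending, mirroring the expert
#' selection requirements. Available keys: `"altered"` (number of
#' antecedent items whose code is clinically altered per
#' [alteredCodes()]), `"over_gene"` (presence of an over-expressed gene
#' item, +1), `"conf"`, `"comp"`.
#'
#' @param rules a [RuleSet-class].
#' @param profile ordered character vector of keys; default the CF-rule
#'   profile `c("altered", "conf")`. The CF+DEG profile is
#'   `c("altered", "over_gene", "conf", "comp")`.
#' @param altered named list attribute -> altered codes.
#' @return the reordered [RuleSet-class].
#' @export
rankRules <- function(rules, profile = c("altered", "conf"),
                      altered = alteredCodes()) {
  df <- rules@rules
  if (nrow(df) < 2) return(rules)
  keyOf <- function(key) {
    switch(key,
      altered = vapply(df$antecedent, function(a) {
        attrs <- itemAttribute(a); vals <- itemValue(a)
        sum(mapply(function(at, v) {
          !is.null(altered[[at]]) && suppressWarnings(!is.na(as.integer(v))) &&
            as.integer(v) %in% altered[[at]]
        }, attrs, vals))
      }, 0),
      over_gene = vapply(df$antecedent,
                         function(a) as.numeric(any(itemValue(a) == "+1")), 0),
      conf = df$conf,
      comp = df$comp,
      stop("unknown ranking key: ", key))
  }
  keys <- lapply(profile, keyOf)
  ord <- do.call(order, c(lapply(keys, function(k) -k),
                          list(method = "radix")))
  rules@rules <- df[ord, , drop = FALSE]
  rownames(rules@rules) <- NULL
  rules
}

#' @describeIn ruleMetrics number of rules in a RuleSet.
#' @param x a RuleSet.
#' @export
nRules <- function(x) nrow(x@rules)

#' Rules as a plain data.frame
#'
#' @param rules a [RuleSet-class].
#' @return data.frame with antecedent/consequent rendered as comma-joined
#'   strings and metrics rounded half-up to 2 decimals.
#' @export
rulesAsDataFrame <- function(rules) {
  df <- rules@rules
  data.frame(
    antecedent = if (nrow(df)) .formatItemset(df$antecedent) else character(0),
    consequent = if (nrow(df)) .formatItemset(df$consequent) else character(0),
    sigma_rule = df$sigma_rule, sigma_head = df$sigma_head,
    sigma_tail = df$sigma_tail,
    conf = roundHalfUp(df$conf), comp = roundHalfUp(df$comp),
    lift = roundHalfUp(df$lift),
    stringsAsFactors = FALSE)
}

#' @rdname rulesAsDataFrame
#' @export
setMethod("show", "RuleSet", function(object) {
  df <- object@rules
  cat(sprintf("RuleSet: %d rule(s) over %d transactions\n", nrow(df), object@n))
  if (nrow(df)) {
    top <- utils::head(rulesAsDataFrame(object), 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s => %s  (supp %d, conf %.2f%%, lift %.2f)\n",
                  top$antecedent[i], top$consequent[i], top$sigma_rule[i],
                  top$conf[i], top$lift[i]))
    }
    if (nrow(df) > 5) cat(sprintf("  ... and %d more\n", nrow(df) - 5))
  }
})
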