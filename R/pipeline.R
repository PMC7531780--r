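## End-to-end analyses. Defaults reproduce the study settings:
## CF-only mining at minSup = 14, minConf = 70% with the periodontal
## interestingness constraint; CAR mining at minSup = 3, minConf = 90%
## with the patient group as target.

#' Cardiovascular / obesity risk attributes
#' @return character vector of attribute aliases.
#' @export
cardioAttributes <- function() c("BMI", "WHR", "AC", "FPG", "N-HDL-C")

#' Mine association rules from the clinical features alone
#'
#' Builds the 17-attribute transaction database, enumerates closed
#' frequent itemsets at `minSup`, and induces strong rules whose
#' consequents are periodontal and contain at least one marker of
#' periodontal disease activity.
#'
#' @param coded coded clinical records (see [discretizeRecords()] or
#'   [readClinicalTable()]).
#' @param minSup minimum absolute support (default 14).
#' @param minConf minimum confidence (default 0.70).
#' @param constraint consequent constraint (default
#'   [consequentConstraint()]).
#' @param out optional path: write the rule table (tab-separated).
#' @return list with `db`, `closed`, `rules` (a [RuleSet-class]) and a
#'   `summary` of stage counts.
#' @export
runCFAnalysis <- function(coded, minSup = 14, minConf = 0.70,
                          constraint = consequentConstraint(), out = NULL) {
  db <- selectCFSubset(coded)
  closed <- mineClosed(db, minSup)
  rules <- generateRules(closed, db, minConf, constraint)
  if (!is.null(out)) writeRuleTable(rules, out)
  list(db = db, closed = closed, rules = rules,
       summary = list(n = nTransactions(db), items = length(itemUniverse(db)),
                      closedSets = length(closed), rules = nRules(rules)))
}

#' Mine rules with cardiovascular/obesity antecedents only
#'
#' Restricts the mining universe to the cardiovascular and obesity risk
#' attributes (BMI, WHR, AC, FPG, N-HDL-C) plus the periodontal
#' consequent attributes, and keeps only rules whose antecedents contain
#' cardiovascular attributes exclusively.
#'
#' @inheritParams runCFAnalysis
#' @return as [runCFAnalysis()].
#' @export
runCardioAnalysis <- function(coded, minSup = 14, minConf = 0.70,
                              constraint = consequentConstraint(),
                              out = NULL) {
  univ <- c(cardioAttributes(), periodontalAttributes())
  db <- selectCFSubset(coded, attributes = univ)
  closed <- mineClosed(db, minSup)
  rules <- generateRules(closed, db, minConf, constraint,
                         antecedentPool = cardioAttributes())
  if (!is.null(out)) writeRuleTable(rules, out)
  list(db = db, closed = closed, rules = rules,
       summary = list(n = nTransactions(db), items = length(itemUniverse(db)),
                      closedSets = length(closed), rules = nRules(rules)))
}

#' Mine rules on the diabetic-dyslipidemia subset
#'
#' Restricts the cohort to the T2DM patients with diabetic dyslipidemia
#' (groups 1-2, raw TG >= 204 mg/dL and HDL < 38 mg/dL, or an explicit
#' subject-id list when raw lipids are unavailable) and mines with the
#' subset size as n. The consequent constraint is relaxed to any
#' periodontal attribute at any code.
#'
#' @param coded coded clinical records.
#' @param raw raw records (used to select the subset); omit if
#'   `subjectIds` is given.
#' @param subjectIds explicit subset of subject ids.
#' @param minSup minimum absolute support within the subset (default 5).
#' @param minConf minimum confidence (default 0.70).
#' @param out optional output path.
#' @return as [runCFAnalysis()], plus `subjects`.
#' @export
runDiabeticDlpAnalysis <- function(coded, raw = NULL, subjectIds = NULL,
                                   minSup = 5, minConf = 0.70, out = NULL) {
  if (is.null(subjectIds)) {
    if (is.null(raw)) {
      stop("supply either raw records (for the TG/HDL filter) or subjectIds")
    }
    subjectIds <- selectDiabeticDyslipidemia(raw)$subject
  }
  sel <- coded[coded$subject %in% subjectIds, , drop = FALSE]
  if (nrow(sel) == 0) stop("empty diabetic-dyslipidemia subset")
  db <- selectCFSubset(sel)
  closed <- mineClosed(db, minSup)
  rules <- generateRules(closed, db, minConf,
                         consequentConstraint(mode = "any"))
  if (!is.null(out)) writeRuleTable(rules, out)
  list(db = db, closed = closed, rules = rules, subjects = subjectIds,
       summary = list(n = nTransactions(db), items = length(itemUniverse(db)),
                      closedSets = length(closed), rules = nRules(rules)))
}

#' Two-phase CF + DEG class association rule mining
#'
#' The joint clinical-feature / gene-expression analysis: (1) preprocess
#' the expression matrix (range filter at `rangeThreshold`, per-gene
#' z-normalization, ternary discretization at `hi`/`lo`); (2) phase-1 CAR
#' mining on gene items alone; (3) compute the gene coverage of the
#' phase-1 rules, discard genes present in conflicting rules (same item
#' in a control-group rule and a non-control rule); (4) phase-2 CAR
#' mining over the retained genes' items together with all 29 coded
#' clinical features, the patient group again being the target.
#'
#' @param se expression SummarizedExperiment (probes x subjects, `group`
#'   in colData; see [readExpressionMatrix()] or [generateExpression()]).
#' @param coded coded clinical records covering the array subjects
#'   (matched by subject id against `colnames(se)`).
#' @param minSup,minConf CAR mining parameters (defaults 3 and 0.90).
#' @param rangeThreshold range-filter threshold (default 0.1).
#' @param hi,lo ternary discretization thresholds (defaults +1, -1).
#' @param conflictKey "value" or "gene" (see [findConflictingGenes()]).
#' @param geneDirections "both" (default) to forward both items of each
#'   retained gene into phase 2, or "observed" to forward only the
#'   directions seen in phase-1 rules.
#' @param outDir optional directory: writes phase1.tsv / phase2.tsv.
#' @return list with `phase1`, `phase2` ([RuleSet-class]s), `coverage`,
#'   `conflicts`, `forwardedGenes`, and a `summary` of the stage counts.
#' @export
runCFDEGAnalysis <- function(se, coded, minSup = 3, minConf = 0.90,
                             rangeThreshold = 0.1, hi = 1.0, lo = -1.0,
                             conflictKey = c("value", "gene"),
                             geneDirections = c("both", "observed"),
                             outDir = NULL) {
  conflictKey <- match.arg(conflictKey)
  geneDirections <- match.arg(geneDirections)
  nIn <- nrow(se)
  filt <- rangeFilter(se, rangeThreshold)
  norm <- zNormalize(filt)
  geneDB <- ternaryDiscretize(norm, hi = hi, lo = lo)
  phase1 <- mineCARs(geneDB, minSup, minConf)
  cov <- coveredGenes(phase1)
  confl <- findConflictingGenes(phase1, key = conflictKey)
  keep <- setdiff(cov, confl)
  keepItems <- if (geneDirections == "both") {
    intersect(itemUniverse(geneDB),
              c(makeItem(keep, "+1"), makeItem(keep, "-1")))
  } else {
    items <- unique(unlist(phase1@rules$antecedent, use.names = FALSE))
    items <- items[.isGeneItem(items)]
    items[itemAttribute(items) %in% keep]
  }
  subjects <- rownames(geneDB@incidence)
  sel <- coded[match(subjects, as.character(coded$subject)), , drop = FALSE]
  if (anyNA(sel$subject)) {
    stop("coded clinical records missing for array subject(s): ",
         paste(setdiff(subjects, coded$subject), collapse = ", "))
  }
  clinDB <- selectCFSubset(sel, attributes = clinicalAttributes())
  db2 <- combineDB(subsetDB(geneDB, items = keepItems), clinDB)
  phase2 <- mineCARs(db2, minSup, minConf)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRuleTable(phase1, file.path(outDir, "phase1.tsv"))
    writeRuleTable(phase2, file.path(outDir, "phase2.tsv"))
  }
  list(phase1 = phase1, phase2 = phase2, coverage = cov, conflicts = confl,
       forwardedGenes = keep, geneDB = geneDB, db2 = db2,
       summary = list(probesIn = nIn,
                      probesKept = nIn - S4Vectors::metadata(filt)$rangeFilter$removed,
                      probesRemoved = S4Vectors::metadata(filt)$rangeFilter$removed,
                      phase1Rules = nRules(phase1),
                      coverage = length(cov),
                      conflicts = length(confl),
                      forwarded = length(keep),
                      phase2Rules = nRules(phase2)))
}
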