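## Synthetic cohort and expression-matrix generator with planted,
## recoverable structure. The generator emulates the study design: a
## 5-group clinical cohort (143 subjects) whose groups differ in
## glycemic, lipid and periodontal attribute patterns, a 10-patient
## diabetic-dyslipidemia subset inside the two diabetic groups, and a
## 30-subject microarray subset with mostly flat expression profiles, a
## low-variance fraction removed by the range filter, and group-specific
## over/under-expressed signature probes.

#' Specification of a synthetic study
#'
#' @param groupSizes clinical cohort sizes of groups 1..5.
#' @param microarraySizes per-group sizes of the microarray subset.
#' @param patterns named list (group label -> named integer vector
#'   attribute -> target code): the planted clinical pattern per group.
#' @param adherence probability that a subject expresses its group's full
#'   planted pattern; non-adherent subjects draw background codes that
#'   avoid the target code.
#' @param background "uniform" (draw uniformly from the attribute
#'   domain), or a named list attribute -> fixed code (or probability
#'   weights over the domain) for non-patterned draws.
#' @param nDdlp number of planted diabetic-dyslipidemia patients
#'   (groups 1-2 subjects given raw TG >= 204 and HDL < 38).
#' @param nProbes total probes on the synthetic array.
#' @param lowVarFrac fraction of probes given near-constant profiles
#'   (range below the 0.1 filter threshold).
#' @param sigPerGroup signature probes planted per group.
#' @param shift planted signature shift, in units of `noiseSd`.
#' @param noiseSd standard deviation of background expression noise.
#' @param lowVarSd standard deviation of the near-constant profiles.
#' @return a list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(groupSizes = c(28, 29, 29, 29, 28),
                          microarraySizes = c(5, 7, 6, 6, 6),
                          patterns = defaultClinicalPatterns(),
                          adherence = 0.8,
                          background = "uniform",
                          nDdlp = 10,
                          nProbes = 54675,
                          lowVarFrac = 0.9226,
                          sigPerGroup = 20,
                          shift = 3,
                          noiseSd = 0.25,
                          lowVarSd = 0.01) {
  stopifnot(length(groupSizes) == 5, all(groupSizes >= 1),
            length(microarraySizes) == 5,
            all(microarraySizes <= groupSizes),
            adherence >= 0, adherence <= 1, shift > 0)
  structure(list(groupSizes = groupSizes, microarraySizes = microarraySizes,
                 patterns = patterns, adherence = adherence,
                 background = background, nDdlp = nDdlp,
                 nProbes = nProbes, lowVarFrac = lowVarFrac,
                 sigPerGroup = sigPerGroup, shift = shift,
                 noiseSd = noiseSd, lowVarSd = lowVarSd),
            class = "SyntheticSpec")
}

#' Default planted clinical patterns per group
#'
#' Group 1: poorly controlled T2DM with dyslipidemia and periodontitis;
#' Group 2: well-controlled T2DM with dyslipidemia and periodontitis;
#' Group 3: dyslipidemia and periodontitis; Group 4: systemically healthy
#' with periodontitis; Group 5: systemically and periodontally healthy.
#' @return named list group -> (attribute -> target code).
#' @export
defaultClinicalPatterns <- function() {
  list(
    `1` = c(FPG = 3, HbA1c = 4, "HOMA-IR" = 2, TC = 4, TG = 3,
            WHR = 4, AC = 3, BOP = 3, SUPP = 2),
    `2` = c(FPG = 3, HbA1c = 3, "HOMA-IR" = 2, TC = 4, TG = 3,
            "N-HDL-C" = 5, BOP = 3, SUPP = 2),
    `3` = c(FPG = 1, HbA1c = 1, TC = 4, LDL = 4, TG = 3,
            BOP = 3, "CALi3-4mm" = 3),
    `4` = c(FPG = 1, HbA1c = 1, TC = 2, TG = 1,
            BOP = 3, "CALi3-4mm" = 3, CALi5mm = 2),
    `5` = c(FPG = 1, HbA1c = 1, TC = 2, TG = 1,
            GI = 1, BOP = 1, SUPP = 1)
  )
}

## draw a background code for `attribute`, avoiding `exclude`
.backgroundCode <- function(spec, attribute, exclude = NULL) {
  dom <- attributeDomain(attribute)
  bg <- spec$background
  if (!identical(bg, "uniform") && !is.null(bg[[attribute]])) {
    b <- bg[[attribute]]
    if (length(b) == 1) return(as.integer(b))
    dom2 <- dom; w <- rep_len(b, length(dom))
    if (!is.null(exclude)) { w <- w[dom2 != exclude]; dom2 <- dom2[dom2 != exclude] }
    return(sample(dom2, 1, prob = w))
  }
  if (!is.null(exclude)) dom <- dom[dom != exclude]
  if (length(dom) == 1) return(dom)
  sample(dom, 1)
}

## sample a raw value strictly inside the bin of `code`, away from edges
.sampleInBin <- function(bins, code, span) {
  b <- bins[bins$code == code, , drop = FALSE]
  lo <- if (is.na(b$lower)) span[1] else b$lower
  hi <- if (is.na(b$upper)) span[2] else b$upper
  if (hi < lo) hi <- lo + 1  # degenerate span guard
  w <- hi - lo
  stats::runif(1, lo + 0.05 * w, hi - 0.05 * w)
}

.rawForCode <- function(attribute, code, sex, age, cfg) {
  if (attribute == "Sex") return(code)
  if (attribute == "WHR") {
    stratum <- 1L + (age > cfg$WHR$age_breaks[1]) + (age > cfg$WHR$age_breaks[2])
    bins <- cfg$WHR[[sex]][[stratum]]
    return(.sampleInBin(bins, code, cfg$WHR$span))
  }
  if (attribute == "AC") {
    return(.sampleInBin(cfg$AC[[sex]], code, cfg$AC$span))
  }
  att <- cfg$attributes[[attribute]]
  v <- .sampleInBin(att$bins, code, att$span)
  if (attribute == "TNT") v <- round(v)
  v
}

#' Generate a synthetic clinical cohort
#'
#' Draws one subject per row: group membership, sex, age, then for each
#' planted attribute the group's target code (with probability
#' `adherence`, as a single per-subject Bernoulli over the whole pattern)
#' or a background code avoiding the target; non-patterned attributes
#' draw background codes. Raw measurements are sampled strictly inside
#' the chosen code's bin, so discretization round-trips exactly. A
#' diabetic-dyslipidemia subset (`nDdlp` subjects of groups 1-2) is
#' planted via raw TG >= 204 mg/dL and HDL < 38 mg/dL; all other
#' group-1/2 subjects are kept out of the subset.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer RNG seed.
#' @return list with `raw` (raw cohort table), `coded` (discretized
#'   records), and `truth`: planted patterns, per-subject adherence flags
#'   (`match`), and `ddlp` subject ids.
#' @export
generateClinical <- function(spec, seed) {
  set.seed(seed)
  cfg <- clinicalCutoffs()
  groups <- rep(1:5, spec$groupSizes)
  nTot <- length(groups)
  ids <- sprintf("S%03d", seq_len(nTot))
  sexCode <- sample(1:2, nTot, replace = TRUE)
  sex <- c("female", "male")[sexCode]
  age <- stats::runif(nTot, 35, 60)
  adheres <- stats::runif(nTot) < spec$adherence
  raw <- data.frame(subject = ids, group = groups, Sex = sexCode, Age = age,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attrs <- setdiff(clinicalAttributes(), c("Sex", "Age"))
  codes <- matrix(NA_integer_, nTot, length(attrs),
                  dimnames = list(ids, attrs))
  for (i in seq_len(nTot)) {
    pat <- spec$patterns[[as.character(groups[i])]]
    for (a in attrs) {
      if (!is.null(pat) && a %in% names(pat)) {
        target <- as.integer(pat[[a]])
        codes[i, a] <- if (adheres[i]) target else
          .backgroundCode(spec, a, exclude = target)
      } else {
        codes[i, a] <- .backgroundCode(spec, a)
      }
    }
  }
  for (a in attrs) {
    raw[[a]] <- vapply(seq_len(nTot), function(i) {
      .rawForCode(a, codes[i, a], sex[i], age[i], cfg)
    }, 0)
  }
  ## plant the diabetic-dyslipidemia subset on raw TG/HDL
  pool <- which(groups %in% c(1, 2))
  ddlp <- sort(sample(pool, min(spec$nDdlp, length(pool))))
  for (i in ddlp) {
    raw$TG[i] <- stats::runif(1, 204, 400)      # code 3 and >= 204
    raw$HDL[i] <- stats::runif(1, 22, 37.9)     # code 1 and < 38
    codes[i, "TG"] <- 3L; codes[i, "HDL"] <- 1L
  }
  for (i in setdiff(pool, ddlp)) {
    if (raw$TG[i] >= 204 && raw$HDL[i] < 38) {
      raw$HDL[i] <- stats::runif(1, 38, 39.9)   # still code 1, not ddlp
    }
  }
  coded <- discretizeRecords(raw)
  list(raw = raw, coded = coded,
       truth = list(patterns = spec$patterns,
                    match = stats::setNames(adheres, ids),
                    group = stats::setNames(groups, ids),
                    ddlp = ids[ddlp]))
}

#' Identifiers of the microarray subset
#'
#' The first `microarraySizes[g]` subjects of each group, matching the
#' ids produced by [generateClinical()].
#' @param spec a [syntheticSpec()].
#' @return character vector of subject ids.
#' @export
microarraySubjects <- function(spec) {
  groups <- rep(1:5, spec$groupSizes)
  ids <- sprintf("S%03d", seq_along(groups))
  unlist(lapply(1:5, function(g) {
    utils::head(ids[groups == g], spec$microarraySizes[g])
  }), use.names = FALSE)
}

#' Generate a synthetic expression matrix with planted signatures
#'
#' Probes carry a per-probe baseline (log-scale summaries around 4-12); a
#' `lowVarFrac` fraction gets near-constant profiles (range below the 0.1
#' filter threshold), the rest get Gaussian noise of sd `noiseSd`. Each
#' group receives `sigPerGroup` signature probes whose values for that
#' group's subjects are shifted by `shift * noiseSd` up (over-expressed)
#' or down (under-expressed, alternating).
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer RNG seed (use a different seed than the clinical
#'   draw to keep streams independent, or the same for a paired cohort).
#' @return list with `se` (a SummarizedExperiment, probes x subjects,
#'   `group` in colData) and `truth`: data.frame(probe, group, direction).
#' @export
generateExpression <- function(spec, seed) {
  set.seed(seed)
  subjects <- microarraySubjects(spec)
  groups <- rep(1:5, spec$microarraySizes)
  nSub <- length(subjects)
  nP <- spec$nProbes
  probes <- sprintf("%06d_at", seq_len(nP))
  nLow <- round(spec$lowVarFrac * nP)
  lowIdx <- seq_len(nLow)  # which probes are near-constant
  baseline <- stats::runif(nP, 4, 12)
  m <- matrix(stats::rnorm(nP * nSub, 0, spec$noiseSd), nP, nSub,
              dimnames = list(probes, subjects))
  if (nLow > 0) {
    m[lowIdx, ] <- stats::rnorm(nLow * nSub, 0, spec$lowVarSd)
  }
  m <- m + baseline
  highIdx <- setdiff(seq_len(nP), lowIdx)
  need <- 5 * spec$sigPerGroup
  if (need > length(highIdx)) {
    stop("not enough variable probes for the requested signatures")
  }
  sigIdx <- sample(highIdx, need)
  truth <- data.frame(probe = probes[sigIdx],
                      group = rep(1:5, each = spec$sigPerGroup),
                      direction = rep_len(c(1, -1), need),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(truth))) {
    cols <- which(groups == truth$group[r])
    m[truth$probe[r], cols] <- m[truth$probe[r], cols] +
      truth$direction[r] * spec$shift * spec$noiseSd
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    colData = S4Vectors::DataFrame(group = groups, row.names = subjects))
  list(se = se, truth = truth)
}
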