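## Clinical discretization: raw measurements -> categorical codes.
##
## The cutoffs live in inst/extdata/clinical_cutoffs.json (versioned data,
## not code): fixed guideline bins per attribute, plus sex/age-stratified
## waist-hip-ratio bins and sex-stratified abdominal-circumference bins.

.cutoffEnv <- new.env(parent = emptyenv())

#' Load the clinical cutoff configuration
#'
#' Reads (and memoizes) the JSON cutoff tables shipped with the package:
#' per-attribute discretization bins, the sex/age-stratified waist/hip
#' ratio domain and the sex-stratified abdominal circumference domain,
#' plus the codes the rule-ranking heuristic treats as "altered".
#'
#' @param path optional path to an alternative cutoff file.
#' @return nested list mirroring the JSON structure.
#' @export
clinicalCutoffs <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cutoffEnv$cfg)) return(.cutoffEnv$cfg)
    path <- system.file("extdata", "clinical_cutoffs.json",
                        package = "ClosedARM", mustWork = TRUE)
    cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                              simplifyVector = TRUE)
    .cutoffEnv$cfg <- cfg
    return(cfg)
  }
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
}

## bins: data.frame(code, lower, upper, lower_incl, upper_incl); NA = infinite
.binCode <- function(value, bins) {
  lo <- ifelse(is.na(bins$lower), -Inf, bins$lower)
  hi <- ifelse(is.na(bins$upper), Inf, bins$upper)
  code <- rep(NA_integer_, length(value))
  for (b in seq_len(nrow(bins))) {
    okLo <- if (bins$lower_incl[b]) value >= lo[b] else value > lo[b]
    okHi <- if (bins$upper_incl[b]) value <= hi[b] else value < hi[b]
    hit <- okLo & okHi & is.na(code)
    code[hit] <- bins$code[b]
  }
  code
}

.normSex <- function(sex) {
  if (is.numeric(sex)) {
    out <- c("female", "male")[sex]
  } else {
    s <- tolower(as.character(sex))
    out <- ifelse(s %in% c("female", "f", "1"), "female",
           ifelse(s %in% c("male", "m", "2"), "male", NA))
  }
  if (anyNA(out)) stop("sex must be female/male (or codes 1/2)")
  out
}

#' Discretize a fixed-cutoff clinical attribute
#'
#' Maps raw measurements of an attribute with sex/age-independent cutoffs
#' to its categorical code. Interval conventions follow the printed
#' guideline domains: e.g. HDL is coded 1 below 40 mg/dL, 2 on the closed
#' interval [40, 60], 3 strictly above 60. Waist/hip ratio and abdominal
#' circumference have stratified cutoffs; use [discretizeWHR()] and
#' [discretizeAC()].
#'
#' @param name attribute alias (e.g. "FPG", "HbA1c", "SUPP").
#' @param value numeric vector of raw measurements.
#' @return integer vector of category codes.
#' @examples
#' discretizeAttribute("FPG", c(99, 100, 126))   # 1 2 3
#' discretizeAttribute("HbA1c", 5.7)             # 2
#' @export
discretizeAttribute <- function(name, value) {
  cfg <- clinicalCutoffs()
  if (name %in% c("WHR", "AC")) {
    stop(sprintf("'%s' has stratified cutoffs; use discretize%s()", name, name))
  }
  att <- cfg$attributes[[name]]
  if (is.null(att)) stop("unknown clinical attribute: ", name)
  if (identical(att$type, "categorical")) {
    bad <- !(value %in% att$codes)
    if (any(bad)) {
      stop(sprintf("value %s outside the domain of categorical attribute '%s'",
                   value[bad][1], name))
    }
    return(as.integer(value))
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop(sprintf("negative measurement for '%s'", name))
  }
  .binCode(value, att$bins)
}

#' Discretize waist/hip ratio (sex- and age-stratified)
#'
#' Codes 1 (low) to 4 (very high) from cutoffs stratified by sex and by
#' raw age in years (strata: <=39, (39, 49], >49).
#'
#' @param whr numeric waist/hip ratio.
#' @param sex "female"/"male" (or codes 1/2).
#' @param age age in years.
#' @return integer codes 1..4.
#' @examples
#' discretizeWHR(0.85, "female", 45)  # 3
#' discretizeWHR(1.05, "male", 55)    # 4
#' @export
discretizeWHR <- function(whr, sex, age) {
  cfg <- clinicalCutoffs()
  sex <- .normSex(sex)
  k <- max(length(whr), length(sex), length(age))
  whr <- rep_len(whr, k); sex <- rep_len(sex, k); age <- rep_len(age, k)
  breaks <- cfg$WHR$age_breaks
  stratum <- 1L + (age > breaks[1]) + (age > breaks[2])
  out <- integer(k)
  for (i in seq_len(k)) {
    bins <- cfg$WHR[[sex[i]]][[stratum[i]]]
    out[i] <- .binCode(whr[i], bins)
  }
  out
}

#' Discretize abdominal circumference (sex-stratified)
#'
#' Codes 1 (low risk) to 3 (very high risk); cutoffs 80/88 cm for women,
#' 94/102 cm for men.
#'
#' @param ac abdominal circumference in cm.
#' @param sex "female"/"male" (or codes 1/2).
#' @return integer codes 1..3.
#' @examples
#' discretizeAC(90, "female")  # 3
#' discretizeAC(95, "male")    # 2
#' @export
discretizeAC <- function(ac, sex) {
  cfg <- clinicalCutoffs()
  sex <- .normSex(sex)
  k <- max(length(ac), length(sex))
  ac <- rep_len(ac, k); sex <- rep_len(sex, k)
  out <- integer(k)
  for (i in seq_len(k)) {
    out[i] <- .binCode(ac[i], cfg$AC[[sex[i]]])
  }
  out
}

#' The full clinical attribute set, in table order
#' @return character vector of the 29 attribute aliases.
#' @export
clinicalAttributes <- function() {
  c("Sex", "Age", "BMI", "WHR", "AC", "FPG", "INS", "HbA1c", "HOMA-IR",
    "TC", "HDL", "LDL", "TG", "N-HDL-C", "VP", "GI", "BOP", "TNT",
    "PPDi3mm", "PPDi4-5mm", "PPDi6mm", "CALi2mm", "CALi3-4mm", "CALi5mm",
    "SUPP", "NDI", "MNCF", "MNF", "FNB")
}

#' The 17 clinically most relevant attributes for CF-only mining
#'
#' Cardiovascular/obesity risk, glycemic, lipid and periodontal attributes;
#' demographic and mutagenesis attributes are excluded because they are not
#' used for routine diagnosis.
#' @return character vector of 17 attribute aliases.
#' @export
cfAttributes <- function() {
  c("BMI", "WHR", "AC", "FPG", "HbA1c", "HOMA-IR", "TC", "HDL", "LDL",
    "TG", "N-HDL-C", "GI", "BOP", "PPDi6mm", "CALi3-4mm", "CALi5mm", "SUPP")
}

#' Periodontal attributes eligible as rule consequents
#' @return character vector of attribute aliases.
#' @export
periodontalAttributes <- function() {
  c("GI", "BOP", "PPDi6mm", "CALi3-4mm", "CALi5mm", "SUPP")
}

#' Domain (valid codes) of an attribute
#' @param name attribute alias (including "WHR", "AC").
#' @return integer vector of valid codes.
#' @export
attributeDomain <- function(name) {
  cfg <- clinicalCutoffs()
  if (name == "WHR") return(1:4)
  if (name == "AC") return(1:3)
  att <- cfg$attributes[[name]]
  if (is.null(att)) stop("unknown clinical attribute: ", name)
  if (identical(att$type, "categorical")) return(as.integer(att$codes))
  as.integer(att$bins$code)
}

#' Codes regarded as clinically altered, per attribute
#'
#' Used by the rule-ranking heuristic: an antecedent item counts as
#' "altered" when its code is in this set for its attribute.
#' @return named list, attribute -> integer codes.
#' @export
alteredCodes <- function() {
  cfg <- clinicalCutoffs()
  out <- lapply(cfg$attributes, function(a) as.integer(a$altered))
  out$WHR <- as.integer(cfg$WHR$altered)
  out$AC <- as.integer(cfg$AC$altered)
  out
}

#' Discretize a raw clinical cohort table
#'
#' Converts raw measurements to category codes for every attribute,
#' dispatching the sex/age-stratified cutoffs for WHR and AC. Columns
#' `subject` and `group` pass through; `Sex` is re-coded 1/2.
#'
#' @param raw data.frame with columns `subject`, `group`, `Sex`, `Age` and
#'   raw measurement columns named by attribute alias.
#' @return data.frame of coded records (same rows, attribute columns now
#'   integer codes).
#' @export
discretizeRecords <- function(raw) {
  stopifnot(all(c("subject", "group", "Sex", "Age") %in% names(raw)))
  sex <- .normSex(raw$Sex)
  coded <- data.frame(subject = raw$subject, group = as.integer(raw$group),
                      check.names = FALSE)
  for (a in clinicalAttributes()) {
    if (!a %in% names(raw)) next
    coded[[a]] <- switch(a,
      Sex = ifelse(sex == "female", 1L, 2L),
      WHR = discretizeWHR(raw[[a]], sex, raw$Age),
      AC  = discretizeAC(raw[[a]], sex),
      discretizeAttribute(a, raw[[a]]))
  }
  coded
}

## coded records -> list of item transactions over the given attributes;
## a missing (NA) code yields no item for that attribute, with a warning.
.codedToTransactions <- function(coded, attributes) {
  present <- intersect(attributes, names(coded))
  miss <- setdiff(attributes, names(coded))
  if (length(miss)) {
    stop("coded records lack attribute(s): ", paste(miss, collapse = ", "))
  }
  nmissing <- 0L
  tx <- lapply(seq_len(nrow(coded)), function(i) {
    vals <- unlist(coded[i, present], use.names = FALSE)
    keep <- !is.na(vals)
    nmissing <<- nmissing + sum(!keep)
    makeItem(present[keep], vals[keep])
  })
  names(tx) <- as.character(coded$subject)
  if (nmissing > 0) {
    warning(sprintf("%d missing value(s) produced no item", nmissing))
  }
  tx
}

#' Build the 17-attribute clinical-feature transaction database
#'
#' @param coded data.frame of coded records (see [discretizeRecords()]).
#' @param attributes attribute subset to use (default the 17 CF-mining
#'   attributes of [cfAttributes()]).
#' @return a [TransactionDB-class] with one transaction per subject and
#'   group labels attached.
#' @export
selectCFSubset <- function(coded, attributes = cfAttributes()) {
  tx <- .codedToTransactions(coded, attributes)
  buildTransactionDB(tx, labels = coded$group)
}

#' Select the diabetic-dyslipidemia patient subset
#'
#' Patients of the two T2DM groups (1 and 2) with raw triglycerides
#' >= 204 mg/dL and raw HDL < 38 mg/dL. Requires raw values: codes alone
#' cannot resolve these cutoffs (TG code 3 starts at 200, HDL code 1 ends
#' at 40).
#'
#' @param raw data.frame of raw records with columns `group`, `TG`, `HDL`.
#' @return the qualifying subset of `raw`.
#' @export
selectDiabeticDyslipidemia <- function(raw) {
  if (!all(c("TG", "HDL") %in% names(raw))) {
    stop("raw TG and HDL values are required: coded categories cannot ",
         "distinguish TG >= 204 or HDL < 38; supply raw values or an ",
         "explicit subject-id list")
  }
  raw[raw$group %in% c(1, 2) & raw$TG >= 204 & raw$HDL < 38, , drop = FALSE]
}
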