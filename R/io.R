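## Readers/writers for the clinical CSV, the expression matrix and rule
## tables. The supplementary files' exact column layout is not fixed, so
## the clinical reader is config-driven (header aliases, coded vs raw).

#' Read a clinical cohort table (CSV)
#'
#' One row per subject; a group column plus clinical attribute columns
#' named by their aliases ("FPG", "HbA1c", ...). Values may be already
#' coded categories or raw measurements.
#'
#' @param path CSV file path.
#' @param values "coded" (categories, validated against each attribute's
#'   domain) or "raw" (measurements, to be passed to
#'   [discretizeRecords()]).
#' @param headerMap optional named character vector mapping nonstandard
#'   column headers to attribute aliases, e.g. `c(glucose = "FPG")`.
#' @param subjectCol,groupCol column names for subject id and group.
#' @return data.frame of subject records with columns `subject`, `group`
#'   and attribute columns.
#' @export
readClinicalTable <- function(path, values = c("coded", "raw"),
                              headerMap = NULL,
                              subjectCol = "subject", groupCol = "group") {
  values <- match.arg(values)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty clinical table: ", path)
  if (!is.null(headerMap)) {
    hit <- names(df) %in% names(headerMap)
    names(df)[hit] <- headerMap[names(df)[hit]]
  }
  if (!groupCol %in% names(df)) stop("missing group column '", groupCol, "'")
  names(df)[names(df) == groupCol] <- "group"
  if (subjectCol %in% names(df)) {
    names(df)[names(df) == subjectCol] <- "subject"
  } else {
    df$subject <- as.character(seq_len(nrow(df)))
  }
  if (!all(df$group %in% 1:5)) {
    bad <- which(!df$group %in% 1:5)[1]
    stop(sprintf("subject %s: group '%s' outside 1..5",
                 df$subject[bad], df$group[bad]))
  }
  if (values == "coded") {
    for (a in intersect(clinicalAttributes(), names(df))) {
      dom <- attributeDomain(a)
      v <- df[[a]]
      bad <- which(!is.na(v) & !(v %in% dom))
      if (length(bad)) {
        stop(sprintf(
          "subject %s: attribute %s value %s outside domain {%s}",
          df$subject[bad[1]], a, v[bad[1]], paste(dom, collapse = ",")))
      }
      df[[a]] <- as.integer(v)
    }
  }
  df
}

#' Read a probeset x subject expression matrix (tab-delimited text)
#'
#' First column: probeset identifiers (kept verbatim, e.g. "229026_at");
#' remaining columns: numeric expression summaries, one column per subject.
#' The subject-to-group mapping is supplied via `groups` (a named vector,
#' names matching the column headers) or a two-column mapping file.
#'
#' @param path tab-delimited file path.
#' @param groups named vector (subject -> group) or path to a two-column
#'   (subject, group) tab/comma-delimited file.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` and a `group` column in `colData` when a mapping is given.
#' @export
readExpressionMatrix <- function(path, groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed matrix: ", path)
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes)) {
    stop("duplicated probe id: ", probes[duplicated(probes)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                 !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric cell at probe '%s', subject '%s'",
                   probes[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    storage.mode(m) <- "numeric"
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing cell at probe '%s', subject '%s'",
                 probes[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- probes
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
      gmap <- utils::read.table(groups, header = TRUE, sep = "",
                                stringsAsFactors = FALSE)
      groups <- stats::setNames(gmap[[2]], as.character(gmap[[1]]))
    }
    if (!all(colnames(m) %in% names(groups))) {
      stop("group mapping misses subject(s): ",
           paste(setdiff(colnames(m), names(groups)), collapse = ", "))
    }
    cd$group <- as.integer(groups[colnames(m)])
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = cd)
}

.formatItemset <- function(items) {
  vapply(items, function(x) paste(sortItems(x), collapse = ", "), "")
}

.parseItemset <- function(s) {
  lapply(strsplit(s, ", ", fixed = TRUE),
         function(x) if (length(x) == 1 && x == "") character(0) else x)
}

#' Write a rule table to CSV/TSV
#'
#' Columns: antecedent, consequent, sigma_rule, sigma_head, sigma_tail,
#' conf, comp, lift; confidence/completeness as percentages and lift, all
#' rounded half-up to 2 decimals. Output is deterministic (rules are
#' written in their stored order; items within a side in canonical order).
#'
#' @param rules a [RuleSet-class].
#' @param path output file path.
#' @param sep field separator: "\\t" (default) or ",".
#' @return invisibly, the formatted data.frame written.
#' @export
writeRuleTable <- function(rules, path, sep = "\t") {
  df <- rules@rules
  out <- data.frame(
    antecedent = if (nrow(df)) .formatItemset(df$antecedent) else character(0),
    consequent = if (nrow(df)) .formatItemset(df$consequent) else character(0),
    sigma_rule = df$sigma_rule %||% integer(0),
    sigma_head = df$sigma_head %||% integer(0),
    sigma_tail = df$sigma_tail %||% integer(0),
    conf = sprintf("%.2f", roundHalfUp(df$conf %||% numeric(0))),
    comp = sprintf("%.2f", roundHalfUp(df$comp %||% numeric(0))),
    lift = sprintf("%.2f", roundHalfUp(df$lift %||% numeric(0))),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(out)
}

#' Read a rule table written by [writeRuleTable()]
#'
#' @param path file path.
#' @param sep field separator used at write time.
#' @param n transaction count to attach to the returned set.
#' @return a [RuleSet-class] (metrics as printed, i.e. at 2-decimal
#'   precision).
#' @export
readRuleTable <- function(path, sep = "\t", n = NA_integer_) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(antecedent = "character",
                                         consequent = "character"))
  rules <- data.frame(sigma_rule = as.integer(df$sigma_rule),
                      sigma_head = as.integer(df$sigma_head),
                      sigma_tail = as.integer(df$sigma_tail),
                      conf = df$conf, comp = df$comp, lift = df$lift)
  rules$antecedent <- I(.parseItemset(df$antecedent))
  rules$consequent <- I(.parseItemset(df$consequent))
  methods::new("RuleSet", rules = rules, n = as.integer(n), params = list())
}

#' Write a clinical cohort table to CSV
#'
#' Writes the same comma-separated layout [readClinicalTable()] consumes.
#' @param records raw or coded clinical records.
#' @param path output CSV path.
#' @export
writeClinicalTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
}

#' Write an expression matrix to tab-delimited text
#'
#' Probe ids in the first column ("probe"), one column per subject; the
#' layout [readExpressionMatrix()] consumes.
#' @param se SummarizedExperiment (assay `exprs`) or numeric matrix.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- if (methods::is(se, "SummarizedExperiment")) {
    SummarizedExperiment::assay(se, "exprs")
  } else {
    as.matrix(se)
  }
  df <- data.frame(probe = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
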