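#' Read per-study genotype counts from a delimited text file
#'
#' Parses a comma- or tab-separated file of candidate-gene case-control
#' studies, one row per primary study per locus per ethnicity stratum.
#' Required header columns (in any order):
#' \code{study_id, year, ethnicity, locus_id, case_AA, case_Aa, case_aa,
#' ctrl_AA, ctrl_Aa, ctrl_aa}, where \code{A} is the major and \code{a} the
#' minor allele as oriented by the locus design configuration (the minor
#' allele is never re-estimated per study; see [locus_design()]).
#'
#' Ethnicity labels are matched case-insensitively and stored lower-case;
#' \code{"caucasian"} and \code{"asian"} are the canonical strata, any other
#' non-empty alphanumeric label is kept as given.
#'
#' @param path Path to a delimited text file. The separator is detected from
#'   the header line (tab if present, otherwise comma).
#' @return A data frame of class \code{dgs_studies}, sorted by
#'   \code{(year, study_id)}, with the ten schema columns plus
#'   \code{case_n} and \code{ctrl_n} subject totals.
#' @details Rows violating the schema abort with an error naming the
#'   offending row: missing or non-integer genotype cells, negative counts,
#'   a year outside \[1900, 2100\], both arms empty, an empty ethnicity
#'   label, or a duplicated \code{(study_id, locus_id, ethnicity)} key.
#' @seealso [genotype_to_alleles()], [simulate_locus()] which emits this
#'   schema, [write_studies()]
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    return(empty_studies())
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          check.names = TRUE)
  validate_studies(df)
}

#' @keywords internal
#' @noRd
studies_schema <- function() {
  c("study_id", "year", "ethnicity", "locus_id",
    "case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa")
}

empty_studies <- function() {
  df <- data.frame(study_id = character(), year = integer(),
                   ethnicity = character(), locus_id = character(),
                   case_AA = integer(), case_Aa = integer(),
                   case_aa = integer(), ctrl_AA = integer(),
                   ctrl_Aa = integer(), ctrl_aa = integer(),
                   case_n = integer(), ctrl_n = integer(),
                   stringsAsFactors = FALSE)
  class(df) <- c("dgs_studies", "data.frame")
  df
}

# Validate a raw character data frame against the study schema and coerce.
# Row numbers in errors refer to data rows (header excluded).
validate_studies <- function(df) {
  schema <- studies_schema()
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[schema]
  if (nrow(df) == 0L) return(empty_studies())

  count_cols <- schema[5:10]
  for (col in c("year", count_cols)) {
    raw <- df[[col]]
    bad <- is.na(raw) | !grepl("^-?[0-9]+$", raw)
    if (any(bad)) {
      stop("malformed integer in column '", col, "' at row ",
           which(bad)[1L], call. = FALSE)
    }
    df[[col]] <- as.integer(raw)
  }
  for (col in count_cols) {
    neg <- df[[col]] < 0L
    if (any(neg)) {
      stop("negative genotype count in column '", col, "' at row ",
           which(neg)[1L], call. = FALSE)
    }
  }
  bad_year <- df$year < 1900L | df$year > 2100L
  if (any(bad_year)) {
    stop("year outside [1900, 2100] at row ", which(bad_year)[1L],
         call. = FALSE)
  }
  df$ethnicity <- tolower(trimws(df$ethnicity))
  bad_eth <- !grepl("^[a-z][a-z0-9_-]*$", df$ethnicity)
  if (any(bad_eth)) {
    stop("unknown ethnicity label at row ", which(bad_eth)[1L],
         call. = FALSE)
  }
  df$case_n <- df$case_AA + df$case_Aa + df$case_aa
  df$ctrl_n <- df$ctrl_AA + df$ctrl_Aa + df$ctrl_aa
  empty <- df$case_n + df$ctrl_n == 0L
  if (any(empty)) {
    stop("no subjects in either arm at row ", which(empty)[1L],
         call. = FALSE)
  }
  key <- paste(df$study_id, df$locus_id, df$ethnicity, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (study_id, locus_id, ethnicity) at row ",
         which(duplicated(key))[1L], call. = FALSE)
  }
  df <- df[order(df$year, df$study_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dgs_studies", "data.frame")
  df
}

#' Write a study table back to delimited text
#'
#' Inverse of [read_studies()]: writes the ten schema columns as
#' comma-separated text so that reading the file back reproduces the table.
#'
#' @param studies A \code{dgs_studies} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_studies <- function(studies, path) {
  utils::write.table(as.data.frame(studies)[studies_schema()], path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse genotype counts to a 2x2 allele table
#'
#' Under the allele model each subject contributes two alleles, so a study's
#' genotype triple (hom-major, het, hom-minor) collapses to minor and major
#' allele counts: minor = 2 x hom-minor + het, major = 2 x hom-major + het,
#' separately for cases and controls.
#'
#' @param record A single-row \code{dgs_studies} data frame (or any list
#'   with the genotype columns).
#' @return A list of class \code{allele_table} with integer fields
#'   \code{a} (case minor), \code{b} (case major), \code{c} (control minor),
#'   \code{d} (control major).
#' @examples
#' rec <- list(case_AA = 70, case_Aa = 20, case_aa = 10,
#'             ctrl_AA = 80, ctrl_Aa = 15, ctrl_aa = 5)
#' genotype_to_alleles(rec)  # a = 40, b = 160
#' @export
genotype_to_alleles <- function(record) {
  tab <- list(
    a = 2L * as.integer(record$case_aa) + as.integer(record$case_Aa),
    b = 2L * as.integer(record$case_AA) + as.integer(record$case_Aa),
    c = 2L * as.integer(record$ctrl_aa) + as.integer(record$ctrl_Aa),
    d = 2L * as.integer(record$ctrl_AA) + as.integer(record$ctrl_Aa)
  )
  if (any(unlist(tab) < 0L)) stop("negative allele count")
  class(tab) <- "allele_table"
  tab
}

#' Read per-locus design configuration
#'
#' Reads a YAML (or JSON) document mapping each locus to its sequential
#' design inputs. Each locus entry may set \code{maf}, \code{assumed_or},
#' \code{alpha}, \code{power}, \code{d2} (a number for a fixed diversity
#' adjustment, or the string \code{"estimate"} to use the D-squared
#' estimated from the accumulated studies). Omitted fields take the
#' defaults of [locus_design()].
#'
#' @param path Path to the YAML/JSON config file.
#' @return A named list of per-locus parameter lists.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stop("locus config does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (length(cfg) > 0L && (is.null(names(cfg)) || any(names(cfg) == ""))) {
    stop("locus config must be a mapping of locus_id to parameters")
  }
  cfg
}

#' Write a DGS verdict table as delimited text
#'
#' Writes one row per locus/ethnicity verdict with the columns
#' \code{locus_id, ethnicity, articles, maf, accumulated_samples,
#' tsa_result, or, ci_low, ci_high, p_value, i2, remaining_samples}.
#' OR and CI bounds are formatted to 2 decimal places, p-values to 4,
#' and I-squared as an integer percent; reading the file back with
#' [read_report()] reproduces the formatted table exactly.
#'
#' @param verdicts A \code{dgs_verdicts} data frame as returned by
#'   [run_dgs()] or built from [classify_locus()] results via
#'   [verdict_table()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(verdicts, path) {
  df <- as.data.frame(verdicts)
  cols <- report_columns()
  if (nrow(df) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
  } else {
    out <- data.frame(
      locus_id = df$locus_id,
      ethnicity = df$ethnicity,
      articles = df$articles,
      maf = sprintf("%.2f", df$maf),
      accumulated_samples = df$accumulated_samples,
      tsa_result = df$tsa_result,
      or = sprintf("%.2f", df$or),
      ci_low = sprintf("%.2f", df$ci_low),
      ci_high = sprintf("%.2f", df$ci_high),
      p_value = sprintf("%.4f", df$p_value),
      i2 = as.integer(round(df$i2)),
      remaining_samples = df$remaining_samples,
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_columns <- function() {
  c("locus_id", "ethnicity", "articles", "maf", "accumulated_samples",
    "tsa_result", "or", "ci_low", "ci_high", "p_value", "i2",
    "remaining_samples")
}

#' Read a verdict report written by [write_report()]
#'
#' @param path Path to a report file.
#' @return A data frame with the documented report columns; numeric columns
#'   parsed back to numeric, formatted at the precision they were written.
#' @export
read_report <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(report_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("report missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("maf", "or", "ci_low", "ci_high", "p_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("articles", "accumulated_samples", "i2",
                "remaining_samples")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Published per-locus summaries of osteoporosis candidate-gene meta-analyses
#'
#' Returns the packaged per-locus summary of published candidate-gene
#' meta-analyses for osteoporosis, stratified by ethnicity: pooled
#' allele-model odds ratio with 95\% CI, p-value, I-squared, number of
#' contributing articles, accumulated subjects, reference minor-allele
#' frequency, and the sequential-monitoring verdict string. These are
#' compiled display values; the per-study counts behind them are not
#' included, so they serve classification and reporting, not re-pooling.
#'
#' @param ethnicity \code{"caucasian"} or \code{"asian"}.
#' @return A data frame with one row per locus.
#' @seealso [summary_to_verdicts()], [cross_tab()]
#' @export
published_summary <- function(ethnicity = c("caucasian", "asian")) {
  ethnicity <- match.arg(ethnicity)
  path <- system.file("extdata",
                      paste0("osteoporosis_", ethnicity, "_summary.csv"),
                      package = "dgsmeta", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE, quote = "\"")
  df$ethnicity <- ethnicity
  df
}
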