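#' Classify a locus from its cumulative series and sequential design
#'
#' The verdict engine of the decisive gene strategy. A significance
#' crossing (first look where |Z| meets the monitoring boundary) declares
#' the locus a conclusive risk factor if the pooled log-OR at the crossing
#' look is positive, or a conclusive protective factor if negative (the
#' minor allele, as oriented by the design's MAF reference, is the
#' exposure). Without a significance crossing, entering the futility wedge
#' or accumulating the required information size declares the locus
#' conclusively unassociated. Otherwise the locus is inconclusive, with
#' \code{remaining_subjects = RIS - accumulated subjects} still needed.
#'
#' A locus whose final look is nominally significant (p below alpha)
#' without any boundary crossing stays inconclusive; the verdict carries a
#' \code{nominal_significance} note so such loci can be surfaced.
#'
#' @param series A \code{dgs_series} from [cumulative_series()].
#' @param design A \code{dgs_design}; an \code{"estimate"}-mode design has
#'   its D-squared resolved from the final look before classification.
#' @param boundaries Optional precomputed \code{dgs_boundaries} aligned
#'   with the series looks.
#' @param ethnicity Stratum label stored on the verdict.
#' @return A list of class \code{dgs_verdict}: \code{locus_id},
#'   \code{ethnicity}, \code{category} (one of \code{conclusive_risk},
#'   \code{conclusive_protective}, \code{conclusive_null},
#'   \code{inconclusive}), \code{remaining_subjects} (0 unless
#'   inconclusive), \code{pooled} (final-look \code{pooled_result}),
#'   \code{het_label} (\code{"high"}/\code{"low"}), \code{crossing},
#'   \code{design}, \code{decisive_look} (crossing look or NA),
#'   \code{nominal_significance}, and \code{allele_note} recording the
#'   direction convention.
#' @export
classify_locus <- function(series, design, boundaries = NULL,
                           ethnicity = "all") {
  stopifnot(inherits(series, "dgs_series"), length(series) > 0L,
            inherits(design, "dgs_design"))
  final <- series[[length(series)]]
  if (design$d2_mode == "estimate" && is.na(design$ris)) {
    design <- apply_d2(design, final$d2)
  }
  z <- vapply(series, function(p) p$z, numeric(1))
  subj <- vapply(series, function(p) p$cumulative_subjects, numeric(1))
  crossing <- evaluate_crossing(z, subj, design, boundaries)

  if (!is.na(crossing$significance_look)) {
    at <- series[[crossing$significance_look]]
    category <- if (at$pooled_log_or > 0) "conclusive_risk"
                else "conclusive_protective"
    decisive <- crossing$significance_look
    remaining <- 0L
  } else if (!is.na(crossing$futility_look) || crossing$ris_reached) {
    category <- "conclusive_null"
    decisive <- if (!is.na(crossing$futility_look)) crossing$futility_look
                else which(subj >= design$ris)[1L]
    remaining <- 0L
  } else {
    category <- "inconclusive"
    decisive <- NA_integer_
    remaining <- max(0L, design$ris - as.integer(subj[length(subj)]))
  }
  structure(list(
    locus_id = design$locus_id,
    ethnicity = ethnicity,
    category = category,
    remaining_subjects = as.integer(remaining),
    pooled = final,
    het_label = heterogeneity_label(final$i2),
    crossing = crossing,
    design = design,
    decisive_look = decisive,
    nominal_significance = final$p_value < design$alpha,
    allele_note = "OR for the minor allele (design MAF reference); OR > 1 = risk"),
    class = "dgs_verdict")
}

#' Heterogeneity label from I-squared
#'
#' Strict rule: I-squared above 50 percent is \code{"high"}; 50 itself is
#' \code{"low"}.
#'
#' @param i2 I-squared in percent, vectorized.
#' @return Character vector of \code{"high"}/\code{"low"}.
#' @export
heterogeneity_label <- function(i2) {
  stopifnot(all(i2 >= 0), all(i2 <= 100))
  ifelse(i2 > 50, "high", "low")
}

#' Subjects still to accumulate before the required information size
#'
#' @param design A resolved \code{dgs_design}.
#' @param subjects Accumulated subjects.
#' @return \code{max(0, ris - subjects)} as an integer.
#' @export
remaining_samples <- function(design, subjects) {
  stopifnot(inherits(design, "dgs_design"))
  if (is.na(design$ris)) stop("design RIS unresolved; call apply_d2() first")
  as.integer(max(0, design$ris - subjects))
}

#' @export
print.dgs_verdict <- function(x, ...) {
  lab <- c(conclusive_risk = "conclusive risk factor",
           conclusive_protective = "conclusive protective factor",
           conclusive_null = "conclusively not associated",
           inconclusive = "inconclusive")[x$category]
  cat(sprintf("%s (%s): %s\n", x$locus_id, x$ethnicity, lab))
  if (x$category == "inconclusive") {
    cat(sprintf("  still need %d subjects (RIS %d, accumulated %d)\n",
                x$remaining_subjects, x$design$ris,
                x$pooled$cumulative_subjects))
  }
  cat(sprintf("  final look: OR %.2f (%.2f-%.2f), p = %.4g, I2 = %.0f%% (%s heterogeneity)\n",
              x$pooled$or, x$pooled$ci_low, x$pooled$ci_high,
              x$pooled$p_value, x$pooled$i2, x$het_label))
  if (isTRUE(x$nominal_significance) && x$category == "inconclusive") {
    cat("  note: nominally significant at the final look without a boundary crossing\n")
  }
  invisible(x)
}

#' Flatten verdicts into a report table
#'
#' @param verdicts A list of \code{dgs_verdict} objects.
#' @return A data frame of class \code{dgs_verdicts} with one row per
#'   verdict and the columns consumed by [write_report()] and
#'   [cross_tab()].
#' @export
verdict_table <- function(verdicts) {
  rows <- lapply(verdicts, function(v) {
    data.frame(locus_id = v$locus_id,
               ethnicity = v$ethnicity,
               articles = v$pooled$k,
               maf = v$design$maf,
               accumulated_samples = v$pooled$cumulative_subjects,
               tsa_result = category_token(v$category),
               remaining_samples = v$remaining_subjects,
               or = v$pooled$or,
               ci_low = v$pooled$ci_low,
               ci_high = v$pooled$ci_high,
               p_value = v$pooled$p_value,
               i2 = v$pooled$i2,
               het_label = v$het_label,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), ethnicity = character(),
               articles = integer(), maf = numeric(),
               accumulated_samples = integer(), tsa_result = character(),
               remaining_samples = integer(), or = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               p_value = numeric(), i2 = numeric(),
               het_label = character(), stringsAsFactors = FALSE)
  class(df) <- c("dgs_verdicts", "data.frame")
  df
}

# report token <-> verdict category
category_token <- function(category) {
  c(conclusive_risk = "risk", conclusive_protective = "protective",
    conclusive_null = "not_associated", inconclusive = "still_need")[category]
}

#' Cross-tabulate verdict category against heterogeneity
#'
#' Builds the 2x4 grid \{high, low heterogeneity\} x \{risk, protective,
#' not associated, still need samples\}: each locus falls in exactly one
#' cell; cells carry counts and sorted locus lists.
#'
#' @param verdicts A \code{dgs_verdicts} data frame (or a list of
#'   \code{dgs_verdict} objects, flattened via [verdict_table()]); must
#'   have columns \code{locus_id}, \code{tsa_result}, \code{het_label}.
#' @return A list of class \code{dgs_crosstab} with a \code{counts} 2x4
#'   matrix and a \code{loci} list of sorted rs-number vectors per cell.
#' @export
cross_tab <- function(verdicts) {
  if (is.list(verdicts) && !is.data.frame(verdicts)) {
    verdicts <- verdict_table(verdicts)
  }
  cats <- c("risk", "protective", "not_associated", "still_need")
  hets <- c("high", "low")
  stopifnot(all(verdicts$tsa_result %in% cats),
            all(verdicts$het_label %in% hets))
  counts <- matrix(0L, nrow = 2, ncol = 4, dimnames = list(hets, cats))
  loci <- stats::setNames(vector("list", 8),
                          as.vector(outer(hets, cats, paste, sep = ".")))
  for (h in hets) for (cc in cats) {
    sel <- verdicts$het_label == h & verdicts$tsa_result == cc
    counts[h, cc] <- sum(sel)
    loci[[paste(h, cc, sep = ".")]] <- sort(verdicts$locus_id[sel])
  }
  structure(list(counts = counts, loci = loci, n = nrow(verdicts)),
            class = "dgs_crosstab")
}

#' @export
print.dgs_crosstab <- function(x, ...) {
  cat(sprintf("Verdict x heterogeneity cross-tabulation (%d loci)\n", x$n))
  print(x$counts)
  for (nm in names(x$loci)) {
    if (length(x$loci[[nm]])) {
      cat(sprintf("  %-24s %s\n", nm, paste(x$loci[[nm]], collapse = " ")))
    }
  }
  invisible(x)
}

#' Convert a published summary table to verdict rows
#'
#' Maps a [published_summary()] data frame onto the column contract of
#' [cross_tab()]: the printed verdict token and the strict I-squared rule
#' of [heterogeneity_label()] applied to the printed I-squared column.
#'
#' @param summary_df A data frame with columns \code{locus_id},
#'   \code{tsa_result}, \code{i2}, and optionally \code{ethnicity}.
#' @return A \code{dgs_verdicts}-shaped data frame usable by
#'   [cross_tab()].
#' @export
summary_to_verdicts <- function(summary_df) {
  df <- data.frame(locus_id = summary_df$locus_id,
                   ethnicity = summary_df$ethnicity %||% "all",
                   tsa_result = summary_df$tsa_result,
                   i2 = summary_df$i2,
                   het_label = heterogeneity_label(summary_df$i2),
                   stringsAsFactors = FALSE)
  class(df) <- c("dgs_verdicts", "data.frame")
  df
}
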