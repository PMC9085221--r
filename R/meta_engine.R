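#' Per-study log odds ratio from a 2x2 allele table
#'
#' Woolf estimator on the minor-vs-major allele table: \code{log_or =
#' log(a*d / (b*c))} with standard error \code{sqrt(1/a + 1/b + 1/c + 1/d)}.
#' If any cell is zero, 0.5 is added to all four cells first
#' (Haldane-Anscombe continuity correction); the correction is applied only
#' when a zero cell occurs.
#'
#' @param table An \code{allele_table} from [genotype_to_alleles()], or any
#'   list with non-negative fields \code{a, b, c, d} (case minor, case
#'   major, control minor, control major allele counts).
#' @return A list of class \code{effect_estimate} with \code{log_or},
#'   \code{se}, and \code{corrected} (logical, continuity correction used).
#' @export
study_effect <- function(table) {
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c <- as.numeric(table$c); d <- as.numeric(table$d)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0)) {
    stop("allele counts must be non-negative")
  }
  if (a + b == 0 || c + d == 0) {
    stop("unusable study: an arm has no alleles")
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  structure(
    list(log_or = log(a * d / (b * c)),
         se = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
         corrected = corrected),
    class = "effect_estimate"
  )
}

#' Compute per-study effects for a study table
#'
#' Applies [genotype_to_alleles()] and [study_effect()] row-wise and returns
#' an effects data frame ordered by \code{(year, study_id)} — the look order
#' used by the cumulative analysis (ties in year broken lexicographically by
#' study_id, since sequential boundaries depend on look order).
#'
#' @param studies A \code{dgs_studies} data frame.
#' @return A data frame with columns \code{study_id, year, log_or, se,
#'   subjects}.
#' @export
study_effects <- function(studies) {
  df <- as.data.frame(studies)
  if (nrow(df) > 0L) {
    df <- df[order(df$year, df$study_id), , drop = FALSE]
  }
  eff <- data.frame(study_id = character(nrow(df)), year = integer(nrow(df)),
                    log_or = numeric(nrow(df)), se = numeric(nrow(df)),
                    subjects = integer(nrow(df)), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    est <- study_effect(genotype_to_alleles(df[i, ]))
    eff$study_id[i] <- df$study_id[i]
    eff$year[i] <- df$year[i]
    eff$log_or[i] <- est$log_or
    eff$se[i] <- est$se
    eff$subjects[i] <- df$case_n[i] + df$ctrl_n[i]
  }
  eff
}

# Core DerSimonian-Laird computation on vectors of effects and variances.
# Returns the full set of pooled statistics; shared by pool_fixed,
# pool_random and the cumulative path.
dl_core <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  sw <- sum(w)
  mu_f <- sum(w * y) / sw
  v_f <- 1 / sw
  q <- sum(w * (y - mu_f)^2)
  if (k > 1L) {
    denom <- sw - sum(w^2) / sw
    tau2 <- max(0, (q - (k - 1)) / denom)
  } else {
    tau2 <- 0
  }
  wr <- 1 / (v + tau2)
  swr <- sum(wr)
  mu_r <- sum(wr * y) / swr
  v_r <- 1 / swr
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  d2 <- if (v_r > 0) max(0, 1 - v_f / v_r) else 0
  list(k = k, mu_f = mu_f, v_f = v_f, mu_r = mu_r, v_r = v_r,
       q = q, tau2 = tau2, i2 = i2, d2 = d2)
}

pooled_result <- function(core, mu, v, subjects, conf_level = 0.95) {
  se <- sqrt(v)
  z <- mu / se
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(k = core$k,
         pooled_log_or = mu,
         se = se,
         or = exp(mu),
         ci_low = exp(mu - crit * se),
         ci_high = exp(mu + crit * se),
         z = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         q = core$q,
         tau2 = core$tau2,
         i2 = core$i2,
         d2 = core$d2,
         cumulative_subjects = as.integer(subjects)),
    class = "pooled_result"
  )
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Weights each study by the reciprocal of its sampling variance. Used
#' internally for Cochran's Q and the fixed-model variance entering the
#' diversity D-squared; exposed for completeness.
#'
#' @param effects Data frame with columns \code{log_or}, \code{se} and
#'   optionally \code{subjects}.
#' @param conf_level Confidence level for the OR-scale interval.
#' @return A \code{pooled_result} list; see [pool_random()] for fields.
#' @export
pool_fixed <- function(effects, conf_level = 0.95) {
  if (nrow(effects) == 0L) stop("no studies to pool")
  core <- dl_core(effects$log_or, effects$se^2)
  pooled_result(core, core$mu_f, core$v_f,
                sum(effects$subjects %||% rep(0L, nrow(effects))),
                conf_level)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis of log odds ratios:
#' Cochran's \eqn{Q = \sum w_i (y_i - \hat y_F)^2} with fixed-effect weights
#' \eqn{w_i = 1/se_i^2}; between-study variance
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))};
#' random-effects weights \eqn{1/(se_i^2 + \tau^2)};
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100};
#' diversity \eqn{D^2 = 1 - v_F / v_R}, the fraction of the random-model
#' pooled variance attributable to between-study heterogeneity.
#' The p-value is two-sided normal-theory (no small-k t correction).
#'
#' @inheritParams pool_fixed
#' @return A list of class \code{pooled_result}: \code{k},
#'   \code{pooled_log_or}, \code{se}, \code{or}, \code{ci_low},
#'   \code{ci_high} (OR scale), \code{z}, \code{p_value}, \code{q},
#'   \code{tau2}, \code{i2} (percent), \code{d2},
#'   \code{cumulative_subjects}.
#' @examples
#' eff <- data.frame(log_or = c(0.2, 0.5, -0.1), se = c(0.2, 0.25, 0.3),
#'                   subjects = c(200, 150, 120))
#' pool_random(eff)
#' @export
pool_random <- function(effects, conf_level = 0.95) {
  if (nrow(effects) == 0L) stop("no studies to pool")
  core <- dl_core(effects$log_or, effects$se^2)
  pooled_result(core, core$mu_r, core$v_r,
                sum(effects$subjects %||% rep(0L, nrow(effects))),
                conf_level)
}

#' Cumulative random-effects series in publication order
#'
#' Re-pools after each added study, mirroring the sequential view of a
#' growing literature: element \code{j} is the DerSimonian-Laird pooling of
#' the first \code{j} studies in \code{(year, study_id)} order.
#'
#' @param effects Data frame with columns \code{study_id, year, log_or, se,
#'   subjects} (as from [study_effects()]); re-sorted defensively.
#' @param conf_level Confidence level for OR-scale intervals.
#' @return A list of class \code{dgs_series} of \code{pooled_result}
#'   objects, one per look; \code{cumulative_subjects} is non-decreasing.
#' @export
cumulative_series <- function(effects, conf_level = 0.95) {
  if (nrow(effects) == 0L) stop("no studies to pool")
  effects <- effects[order(effects$year, effects$study_id), , drop = FALSE]
  v <- effects$se^2
  subj <- cumsum(effects$subjects)
  out <- vector("list", nrow(effects))
  for (j in seq_len(nrow(effects))) {
    core <- dl_core(effects$log_or[seq_len(j)], v[seq_len(j)])
    out[[j]] <- pooled_result(core, core$mu_r, core$v_r, subj[j], conf_level)
  }
  class(out) <- "dgs_series"
  out
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Random-effects pooling of %d stud%s (%d subjects)\n",
              x$k, if (x$k == 1L) "y" else "ies", x$cumulative_subjects))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), z = %.3f, p = %.4g\n",
              x$or, x$ci_low, x$ci_high, x$z, x$p_value))
  cat(sprintf("  Q = %.3f, tau2 = %.4f, I2 = %.1f%%, D2 = %.3f\n",
              x$q, x$tau2, x$i2, x$d2))
  invisible(x)
}

#' @export
print.dgs_series <- function(x, ...) {
  cat(sprintf("Cumulative meta-analysis with %d looks\n", length(x)))
  if (length(x) > 0L) {
    last <- x[[length(x)]]
    cat("Final look:\n")
    print(last)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
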