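#' Case minor-allele proportion implied by an odds ratio
#'
#' Applies an assumed allelic odds ratio to a control minor-allele
#' frequency: \eqn{p_t = OR \cdot p_c / (1 + p_c (OR - 1))}. This is the
#' comparator proportion entering the required-information-size
#' calculation, and also the case allele frequency used by the
#' Hardy-Weinberg simulator.
#'
#' @param maf Control minor-allele frequency, in (0, 1).
#' @param or Allelic odds ratio (positive).
#' @return The implied case-group minor-allele proportion.
#' @examples
#' comparator_proportion(0.38, 1.5)  # 0.4790
#' @export
comparator_proportion <- function(maf, or) {
  stopifnot(maf > 0, maf < 1, or > 0)
  or * maf / (1 + maf * (or - 1))
}

#' Fixed-sample required information size (subjects)
#'
#' Two-proportion normal-approximation sample size on the allele scale,
#' converted to subjects. With per-group allele count
#' \eqn{m = (z_{1-\alpha/2} + z_{1-\beta})^2 (p_c(1-p_c) + p_t(1-p_t)) /
#' (p_t - p_c)^2}, the total is \eqn{2m} alleles; each subject contributes
#' two alleles split across two equal groups, so the subject requirement is
#' \code{ceiling(m)}.
#'
#' @param alpha Two-sided type-I error.
#' @param power Desired power (1 - beta).
#' @param p_c Control minor-allele proportion.
#' @param p_t Case minor-allele proportion (see
#'   [comparator_proportion()]).
#' @return Required number of subjects (ceiling integer).
#' @export
fixed_information_size <- function(alpha, power, p_c, p_t) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            p_c > 0, p_c < 1, p_t > 0, p_t < 1)
  if (p_c == p_t) stop("undefined design: p_c equals p_t")
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  m <- zsum^2 * (p_c * (1 - p_c) + p_t * (1 - p_t)) / (p_t - p_c)^2
  as.integer(ceiling(m))
}

#' Diversity-adjusted required information size
#'
#' Inflates the fixed-sample requirement for between-study heterogeneity:
#' \code{ris = ceiling(n_fixed / (1 - d2))}, where D-squared is the
#' fraction of the random-model pooled variance due to heterogeneity.
#'
#' @param n_fixed Fixed-sample subject requirement.
#' @param d2 Diversity, in \[0, 1).
#' @return Adjusted subject requirement (ceiling integer).
#' @export
diversity_adjusted_is <- function(n_fixed, d2) {
  stopifnot(d2 >= 0, d2 < 1, n_fixed > 0)
  # epsilon guards against 389/0.2 = 1945.0000000000002-style float noise
  as.integer(ceiling(n_fixed / (1 - d2) - 1e-9))
}

#' Sequential design for one locus
#'
#' Bundles the design inputs of the sequential analysis of a locus and
#' derives its required information size. Defaults follow common
#' candidate-gene practice: two-sided alpha 0.05, power 0.80, assumed
#' allelic OR 1.5, and a fixed 0.80 diversity adjustment; \code{d2 =
#' "estimate"} defers the adjustment to the D-squared estimated from the
#' accumulated studies at classification time.
#'
#' @param locus_id Locus identifier (rs number).
#' @param maf Reference control minor-allele frequency in (0, 0.5].
#' @param assumed_or Anticipated allelic odds ratio (default 1.5).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power 1 - beta (default 0.8).
#' @param d2 Either a fixed diversity value in \[0, 1) (default 0.8) or the
#'   string \code{"estimate"}.
#' @return A list of class \code{dgs_design} with fields \code{locus_id,
#'   maf, assumed_or, alpha, power, p_t, n_fixed, d2_mode, d2_applied,
#'   ris}; \code{ris} is \code{NA} until [apply_d2()] when \code{d2 =
#'   "estimate"}.
#' @export
locus_design <- function(locus_id, maf, assumed_or = 1.5, alpha = 0.05,
                         power = 0.8, d2 = 0.8) {
  stopifnot(maf > 0, maf <= 0.5, assumed_or > 0,
            alpha > 0, alpha < 1, power > 0, power < 1)
  if (assumed_or == 1) stop("assumed_or = 1 gives an undefined design")
  if (identical(d2, "estimate")) {
    d2_mode <- "estimate"; d2_applied <- NA_real_
  } else {
    d2 <- as.numeric(d2)
    stopifnot(d2 >= 0, d2 < 1)
    d2_mode <- "fixed"; d2_applied <- d2
  }
  p_t <- comparator_proportion(maf, assumed_or)
  n_fixed <- fixed_information_size(alpha, power, maf, p_t)
  design <- list(locus_id = locus_id, maf = maf, assumed_or = assumed_or,
                 alpha = alpha, power = power, p_t = p_t,
                 n_fixed = n_fixed, d2_mode = d2_mode,
                 d2_applied = d2_applied,
                 ris = if (is.na(d2_applied)) NA_integer_ else
                   diversity_adjusted_is(n_fixed, d2_applied))
  class(design) <- "dgs_design"
  design
}

#' Resolve the diversity adjustment of a design
#'
#' For a fixed-D2 design this is a no-op; for an \code{"estimate"} design
#' it applies the supplied D-squared (typically from the final cumulative
#' [pool_random()] look) and fills in \code{ris}.
#'
#' @param design A \code{dgs_design}.
#' @param d2 Estimated diversity in \[0, 1).
#' @return The design with \code{d2_applied} and \code{ris} set.
#' @export
apply_d2 <- function(design, d2) {
  if (design$d2_mode == "fixed") return(design)
  stopifnot(d2 >= 0, d2 < 1)
  design$d2_applied <- d2
  design$ris <- diversity_adjusted_is(design$n_fixed, d2)
  design
}

#' @export
print.dgs_design <- function(x, ...) {
  cat(sprintf("Sequential design for %s\n", x$locus_id))
  cat(sprintf("  MAF %.3f, assumed OR %.2f -> comparator proportion %.4f\n",
              x$maf, x$assumed_or, x$p_t))
  cat(sprintf("  alpha %.3f (two-sided), power %.2f\n", x$alpha, x$power))
  cat(sprintf("  n_fixed %d subjects; D2 %s -> RIS %s subjects\n",
              x$n_fixed,
              if (x$d2_mode == "fixed") sprintf("fixed %.2f", x$d2_applied)
              else if (is.na(x$d2_applied)) "estimated (pending)"
              else sprintf("estimated %.3f", x$d2_applied),
              if (is.na(x$ris)) "NA" else format(x$ris)))
  invisible(x)
}

#' O'Brien-Fleming-type alpha-spending function
#'
#' Lan-DeMets spending of the O'Brien-Fleming type:
#' \eqn{\alpha^*(t) = 2 (1 - \Phi(z_{1-\alpha/2} / \sqrt t))}. Spends
#' almost nothing at small information fractions and reaches \code{alpha}
#' at \code{t = 1}.
#'
#' @param t Information fraction(s) in (0, 1]; vectorized.
#' @param alpha Total two-sided type-I error.
#' @return Cumulative alpha spent at each \code{t}.
#' @export
alpha_spending <- function(t, alpha = 0.05) {
  stopifnot(all(t > 0), all(t <= 1), alpha > 0, alpha < 1)
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)))
}

# Beta spending of the same O'Brien-Fleming form, reaching beta at t = 1.
beta_spending <- function(t, beta) {
  2 * (1 - stats::pnorm(stats::qnorm(1 - beta / 2) / sqrt(t)))
}

# Trapezoid quadrature weights for a uniform grid.
trap_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

#' Symmetric two-sided monitoring boundaries by recursive integration
#'
#' Computes the O'Brien-Fleming-type monitoring thresholds at a set of
#' information fractions by Lan-DeMets alpha spending: at each look the
#' symmetric Z-threshold is solved so that the cumulative boundary-crossing
#' probability under the null equals the spent alpha, using recursive
#' numerical integration of the sequential sub-density over the
#' independent-increment Brownian representation (trapezoid grid;
#' absolute error on crossing probabilities about 1e-4 at the default
#' grid size).
#'
#' Following the standard two-sided convention, the spending form of
#' [alpha_spending()] is applied to each side at level \code{alpha/2}, so
#' the total spent at each look is \code{2 * alpha_spending(t, alpha/2)}
#' and reaches \code{alpha} at full information; a single look at
#' \code{t = 1} reduces to the conventional critical value
#' \eqn{z_{1-\alpha/2}}. This reproduces the published Lan-DeMets
#' O'Brien-Fleming tables (e.g. 2.963, 1.969 for two equal looks at
#' alpha 0.05).
#'
#' @param fractions Strictly increasing information fractions in (0, 1].
#' @param alpha Total two-sided type-I error.
#' @param grid_points Integration grid size per look.
#' @param z_max Cap on boundary values; looks whose spending increment is
#'   smaller than the crossing probability at \code{z_max} report
#'   \code{z_max}.
#' @return A list of class \code{dgs_boundaries} with \code{fractions},
#'   \code{monitor_upper}, \code{monitor_lower}, \code{spent_alpha}
#'   (cumulative), \code{alpha}.
#' @examples
#' monitoring_boundaries(c(0.5, 1), alpha = 0.05)  # ~ 2.963, 1.969
#' @export
monitoring_boundaries <- function(fractions, alpha = 0.05,
                                  grid_points = 512L, z_max = 8) {
  check_fractions(fractions)
  K <- length(fractions)
  # per-side O'Brien-Fleming spending at alpha/2; total is twice that
  spend <- 2 * alpha_spending(fractions, alpha / 2)
  zb <- numeric(K)
  attained <- numeric(K)

  # look 1: crossing probability is exactly 2*(1 - pnorm(z))
  zb[1] <- min(z_max, stats::qnorm(1 - spend[1] / 2))
  attained[1] <- 2 * stats::pnorm(-zb[1])
  bw <- zb[1] * sqrt(fractions[1])
  x <- seq(-bw, bw, length.out = grid_points)
  fx <- stats::dnorm(x, 0, sqrt(fractions[1]))

  for (k in seq_len(K)[-1]) {
    delta <- fractions[k] - fractions[k - 1]
    sd_d <- sqrt(delta)
    wts <- trap_weights(length(x), x[2] - x[1])
    fw <- fx * wts
    exit_prob <- function(z) {
      b <- z * sqrt(fractions[k])
      sum(fw * (stats::pnorm((x - b) / sd_d) +
                stats::pnorm((-b - x) / sd_d)))
    }
    target <- spend[k] - attained[k - 1]
    if (target <= exit_prob(z_max)) {
      zb[k] <- z_max
    } else {
      zb[k] <- stats::uniroot(function(z) exit_prob(z) - target,
                              lower = 1e-6, upper = z_max,
                              tol = 1e-9)$root
    }
    attained[k] <- attained[k - 1] + exit_prob(zb[k])
    bw <- zb[k] * sqrt(fractions[k])
    y <- seq(-bw, bw, length.out = grid_points)
    fx <- as.vector(stats::dnorm(outer(y, x, "-"), 0, sd_d) %*% fw)
    x <- y
  }
  structure(list(fractions = fractions, monitor_upper = zb,
                 monitor_lower = -zb, spent_alpha = attained,
                 alpha = alpha),
            class = "dgs_boundaries")
}

check_fractions <- function(fractions) {
  if (length(fractions) == 0L) stop("no information fractions supplied")
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("information fractions must lie in (0, 1]")
  }
  if (length(fractions) > 1L && any(diff(fractions) <= 0)) {
    stop("information fractions must be strictly increasing")
  }
  invisible(fractions)
}

#' Futility (inner-wedge) boundaries by beta spending
#'
#' Computes the inner futility wedge from a beta-spending function of the
#' same O'Brien-Fleming form as [alpha_spending()], evaluated under the
#' design alternative with drift \eqn{\theta \sqrt t} on the Z scale,
#' where \eqn{\theta = z_{1-\alpha/2} + z_{1-\beta}} at full information.
#' At each look the wedge value is solved so that the cumulative
#' probability, under the alternative, of the Z-curve falling below it
#' equals the spent beta, by the same recursive integration as the
#' monitoring boundary (efficacy bound treated as binding). Looks where
#' the computed wedge value is not positive are reported \code{NA}
#' (undefined wedge: too little information for a futility claim). At a
#' look with information fraction 1 the wedge closes onto the monitoring
#' boundary (reaching the required information size without crossing is
#' itself conclusive); below 1 the wedge lies strictly inside the
#' monitoring band.
#'
#' @inheritParams monitoring_boundaries
#' @param power Design power (1 - beta).
#' @param monitor Optional \code{dgs_boundaries} from
#'   [monitoring_boundaries()] on the same fractions; computed if omitted.
#' @return A list of class \code{dgs_boundaries} with \code{fractions},
#'   \code{futility_upper}, \code{futility_lower} (NA where undefined),
#'   \code{spent_beta} (cumulative), plus the monitoring fields.
#' @export
futility_boundaries <- function(fractions, alpha = 0.05, power = 0.8,
                                monitor = NULL, grid_points = 512L,
                                z_max = 8) {
  check_fractions(fractions)
  if (is.null(monitor)) {
    monitor <- monitoring_boundaries(fractions, alpha,
                                     grid_points = grid_points,
                                     z_max = z_max)
  }
  stopifnot(identical(monitor$fractions, fractions))
  K <- length(fractions)
  beta <- 1 - power
  spend_b <- beta_spending(fractions, beta)
  theta <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  g <- numeric(K)
  attained <- numeric(K)

  # look 1: P_H1(Z <= g) = pnorm(g - theta*sqrt(t1))
  g[1] <- max(-z_max, theta * sqrt(fractions[1]) +
                stats::qnorm(spend_b[1]))
  attained[1] <- stats::pnorm(g[1] - theta * sqrt(fractions[1]))
  lo <- g[1] * sqrt(fractions[1])
  hi <- monitor$monitor_upper[1] * sqrt(fractions[1])
  x <- seq(lo, hi, length.out = grid_points)
  fx <- stats::dnorm(x, theta * fractions[1], sqrt(fractions[1]))

  for (k in seq_len(K)[-1]) {
    delta <- fractions[k] - fractions[k - 1]
    sd_d <- sqrt(delta)
    mu_d <- theta * delta
    wts <- trap_weights(length(x), x[2] - x[1])
    fw <- fx * wts
    below_prob <- function(z) {
      gb <- z * sqrt(fractions[k])
      sum(fw * stats::pnorm((gb - x - mu_d) / sd_d))
    }
    target <- spend_b[k] - attained[k - 1]
    upper_z <- monitor$monitor_upper[k]
    if (k == K && fractions[k] >= 1 - 1e-9) {
      # wedge closes onto the monitoring boundary at full information
      g[k] <- upper_z
    } else if (target <= below_prob(-z_max)) {
      g[k] <- -z_max
    } else if (target >= below_prob(upper_z)) {
      g[k] <- upper_z
    } else {
      g[k] <- stats::uniroot(function(z) below_prob(z) - target,
                             lower = -z_max, upper = upper_z,
                             tol = 1e-9)$root
    }
    attained[k] <- attained[k - 1] + below_prob(g[k])
    lo <- g[k] * sqrt(fractions[k])
    hi <- upper_z * sqrt(fractions[k])
    y <- seq(lo, hi, length.out = grid_points)
    fx <- as.vector(stats::dnorm(outer(y, x, "-"), mu_d, sd_d) %*% fw)
    x <- y
  }
  fut <- ifelse(g > 0, g, NA_real_)
  structure(list(fractions = fractions,
                 monitor_upper = monitor$monitor_upper,
                 monitor_lower = monitor$monitor_lower,
                 spent_alpha = monitor$spent_alpha,
                 futility_upper = fut, futility_lower = -fut,
                 spent_beta = attained,
                 alpha = alpha, power = power),
            class = "dgs_boundaries")
}

#' Boundaries for a design at given cumulative subject counts
#'
#' Convenience wrapper: converts cumulative subjects to information
#' fractions \code{min(1, subjects / ris)} (one look per added study,
#' capped at 1; looks arriving after the RIS share fraction 1 and keep the
#' threshold of the look that reached it), then computes monitoring and
#' futility boundaries.
#'
#' @param design A \code{dgs_design} with resolved \code{ris}.
#' @param cum_subjects Strictly increasing cumulative subject counts.
#' @param futility Include the futility wedge (default TRUE).
#' @param grid_points,z_max Passed to the boundary routines.
#' @return A \code{dgs_boundaries} whose elements align with the looks in
#'   \code{cum_subjects}.
#' @export
design_boundaries <- function(design, cum_subjects, futility = TRUE,
                              grid_points = 512L, z_max = 8) {
  stopifnot(inherits(design, "dgs_design"))
  if (is.na(design$ris)) stop("design RIS unresolved; call apply_d2() first")
  if (any(diff(cum_subjects) <= 0) && length(cum_subjects) > 1L) {
    stop("cumulative subjects must be strictly increasing")
  }
  frac <- pmin(1, cum_subjects / design$ris)
  uniq <- !duplicated(frac)
  bset <- if (futility) {
    futility_boundaries(frac[uniq], design$alpha, design$power,
                        grid_points = grid_points, z_max = z_max)
  } else {
    monitoring_boundaries(frac[uniq], design$alpha,
                          grid_points = grid_points, z_max = z_max)
  }
  idx <- findInterval(frac, bset$fractions)
  expand <- function(v) if (is.null(v)) NULL else v[idx]
  structure(list(fractions = frac,
                 monitor_upper = expand(bset$monitor_upper),
                 monitor_lower = -expand(bset$monitor_upper),
                 spent_alpha = expand(bset$spent_alpha),
                 futility_upper = expand(bset$futility_upper),
                 futility_lower = if (futility)
                   -expand(bset$futility_upper) else NULL,
                 spent_beta = expand(bset$spent_beta),
                 alpha = design$alpha,
                 power = if (futility) design$power else NULL),
            class = "dgs_boundaries")
}

#' @export
print.dgs_boundaries <- function(x, ...) {
  cat(sprintf("Sequential boundaries at %d look(s), alpha = %.3f\n",
              length(x$fractions), x$alpha))
  df <- as.data.frame(x)
  print(format(df, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.dgs_boundaries <- function(x, ...) {
  df <- data.frame(fraction = x$fractions,
                   monitor_upper = x$monitor_upper,
                   monitor_lower = x$monitor_lower,
                   spent_alpha = x$spent_alpha)
  if (!is.null(x$futility_upper)) {
    df$futility_upper <- x$futility_upper
    df$futility_lower <- x$futility_lower
    df$spent_beta <- x$spent_beta
  }
  df
}

#' Scan a Z-curve against sequential boundaries
#'
#' Walks the cumulative Z-series look by look: the first look whose
#' absolute Z meets or exceeds the monitoring threshold is a significance
#' crossing (with the sign of Z there); the first look falling inside the
#' futility wedge (where defined) is a futility crossing. Equality with a
#' threshold counts as crossed.
#'
#' @param z_series Cumulative pooled Z statistics, one per look.
#' @param subject_series Cumulative subjects at each look (strictly
#'   increasing).
#' @param design A resolved \code{dgs_design}.
#' @param boundaries Optional precomputed \code{dgs_boundaries} aligned
#'   with the looks; computed from the design if omitted.
#' @return A list of class \code{dgs_crossing}: \code{significance_look}
#'   (NA if none), \code{direction} (+1 risk / -1 protective / NA),
#'   \code{futility_look} (NA if none), \code{ris_reached} (logical),
#'   \code{fractions}, and the per-look thresholds used.
#' @export
evaluate_crossing <- function(z_series, subject_series, design,
                              boundaries = NULL) {
  stopifnot(length(z_series) == length(subject_series))
  if (is.null(boundaries)) {
    boundaries <- design_boundaries(design, subject_series)
  }
  stopifnot(length(boundaries$monitor_upper) == length(z_series))
  sig <- which(abs(z_series) >= boundaries$monitor_upper)
  sig_look <- if (length(sig)) sig[1L] else NA_integer_
  fut_look <- NA_integer_
  if (!is.null(boundaries$futility_upper)) {
    fut <- which(!is.na(boundaries$futility_upper) &
                   abs(z_series) <= boundaries$futility_upper)
    if (length(fut)) fut_look <- fut[1L]
  }
  structure(list(
    significance_look = sig_look,
    direction = if (is.na(sig_look)) NA_real_ else
      sign(z_series[sig_look]),
    futility_look = fut_look,
    ris_reached = any(subject_series >= design$ris),
    fractions = boundaries$fractions,
    monitor_upper = boundaries$monitor_upper,
    futility_upper = boundaries$futility_upper,
    z_series = z_series,
    subject_series = subject_series),
    class = "dgs_crossing")
}
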