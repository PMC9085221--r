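#' Define a simulation scenario for a candidate-gene study stream
#'
#' Describes a stream of case-control studies at one locus with known
#' truth: Hardy-Weinberg genotype sampling in both arms, a control
#' minor-allele frequency, a true allelic odds ratio, and optional
#' between-study normal heterogeneity on the log-OR. Each study draws its
#' own log-OR \eqn{\ln OR_i = \ln OR + N(0, \tau^2)}; the case allele
#' frequency is the [comparator_proportion()] transform of the perturbed
#' OR, and genotypes in each arm are multinomial draws from
#' Hardy-Weinberg proportions.
#'
#' Reproducibility: the same scenario and seed give byte-identical
#' records. Each study uses a substream seed derived deterministically
#' from the global seed and the study index, so appending studies does not
#' reshuffle earlier ones.
#'
#' @param true_or True allelic odds ratio (positive).
#' @param maf Control minor-allele frequency in (0, 1).
#' @param tau Between-study SD of the log-OR (>= 0).
#' @param k Number of studies in the stream.
#' @param case_n,ctrl_n Subjects per arm per study; scalar or length-k.
#' @param seed Integer seed.
#' @param start_year First publication year; studies are dated
#'   sequentially.
#' @param locus_id,ethnicity Labels stamped on the records.
#' @return A list of class \code{dgs_scenario}.
#' @export
sim_scenario <- function(true_or, maf, tau = 0, k = 10L,
                         case_n = 200L, ctrl_n = 200L, seed = 1L,
                         start_year = 2000L, locus_id = "rs0000001",
                         ethnicity = "asian") {
  stopifnot(true_or > 0, tau >= 0, k >= 1, all(case_n >= 1),
            all(ctrl_n >= 1))
  if (maf <= 0 || maf >= 1) stop("maf must lie in (0, 1)")
  structure(list(true_or = true_or, maf = maf, tau = tau, k = as.integer(k),
                 case_n = rep_len(as.integer(case_n), k),
                 ctrl_n = rep_len(as.integer(ctrl_n), k),
                 seed = as.integer(seed),
                 start_year = as.integer(start_year),
                 locus_id = locus_id, ethnicity = ethnicity),
            class = "dgs_scenario")
}

# Deterministic substream seed for study i of replicate rep.
# Step sizes are primes large enough that study and replicate indices
# cannot collide at practical scales; kept below 2^31.
substream_seed <- function(seed, i, rep = 0L) {
  (as.numeric(seed) + rep * 104729 + i * 7919) %% 2147483647
}

# Genotype counts for every study of one replicate: list of k x 3 matrices
# (columns AA, Aa, aa with a = minor allele).
sim_counts <- function(scenario, rep = 0L) {
  k <- scenario$k
  case <- matrix(0L, k, 3, dimnames = list(NULL, c("AA", "Aa", "aa")))
  ctrl <- case
  hwe <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  for (i in seq_len(k)) {
    set.seed(substream_seed(scenario$seed, i, rep))
    log_or_i <- log(scenario$true_or) + stats::rnorm(1, 0, scenario$tau)
    p_case <- comparator_proportion(scenario$maf, exp(log_or_i))
    ctrl[i, ] <- as.integer(stats::rmultinom(1, scenario$ctrl_n[i],
                                             hwe(scenario$maf)))
    case[i, ] <- as.integer(stats::rmultinom(1, scenario$case_n[i],
                                             hwe(p_case)))
  }
  list(case = case, ctrl = ctrl)
}

#' Simulate a study stream as a study table
#'
#' Draws the scenario's \code{k} studies and returns them in the
#' [read_studies()] schema, so every downstream stage (effects, pooling,
#' boundaries, classification) can be exercised without external data.
#'
#' @param scenario A \code{dgs_scenario} from [sim_scenario()].
#' @param rep Replicate index (varies the substream seeds
#'   deterministically; default 0).
#' @return A \code{dgs_studies} data frame with one row per study.
#' @export
simulate_locus <- function(scenario, rep = 0L) {
  stopifnot(inherits(scenario, "dgs_scenario"))
  cnt <- sim_counts(scenario, rep)
  df <- data.frame(
    study_id = sprintf("sim%03d", seq_len(scenario$k)),
    year = scenario$start_year + seq_len(scenario$k) - 1L,
    ethnicity = scenario$ethnicity,
    locus_id = scenario$locus_id,
    case_AA = cnt$case[, "AA"], case_Aa = cnt$case[, "Aa"],
    case_aa = cnt$case[, "aa"],
    ctrl_AA = cnt$ctrl[, "AA"], ctrl_Aa = cnt$ctrl[, "Aa"],
    ctrl_aa = cnt$ctrl[, "aa"],
    stringsAsFactors = FALSE)
  df$case_n <- scenario$case_n
  df$ctrl_n <- scenario$ctrl_n
  class(df) <- c("dgs_studies", "data.frame")
  df
}

# Fast path: per-study log-ORs and variances straight from the counts.
effects_from_counts <- function(cnt) {
  a <- 2 * cnt$case[, "aa"] + cnt$case[, "Aa"]
  b <- 2 * cnt$case[, "AA"] + cnt$case[, "Aa"]
  c <- 2 * cnt$ctrl[, "aa"] + cnt$ctrl[, "Aa"]
  d <- 2 * cnt$ctrl[, "AA"] + cnt$ctrl[, "Aa"]
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  list(y = log(a * d / (b * c)), v = 1 / a + 1 / b + 1 / c + 1 / d)
}

# Cumulative DL z-statistics (and final-look extras) on plain vectors.
cum_dl_z <- function(y, v) {
  k <- length(y)
  z <- numeric(k)
  core <- NULL
  for (j in seq_len(k)) {
    core <- dl_core(y[seq_len(j)], v[seq_len(j)])
    z[j] <- core$mu_r / sqrt(core$v_r)
  }
  list(z = z, final = core)
}

#' Operating characteristics of the sequential procedure by simulation
#'
#' Replicates a scenario, runs the full cumulative-pooling plus
#' boundary-monitoring pipeline on each replicate, and tallies the verdict
#' distribution. Also tallies the naive alternative that tests at the
#' nominal level at every look (the repeated-testing procedure whose
#' type-I inflation sequential monitoring is designed to remove), so the
#' two error rates can be compared on identical study streams.
#'
#' @param scenario A \code{dgs_scenario}.
#' @param replicates Number of replicate streams.
#' @param design A \code{dgs_design} for the locus; defaults to the
#'   standard design at the scenario's MAF (assumed OR 1.5, alpha 0.05,
#'   power 0.8, fixed D2 0.8).
#' @param futility Monitor the futility wedge as well (default TRUE).
#' @return A list of class \code{dgs_ocs}: replicate counts and rates for
#'   significance crossing, futility, RIS-complete null, and inconclusive
#'   verdicts; \code{naive_rate}; mean decisive look among crossings; the
#'   mean final-look pooled log-OR and its Monte-Carlo SE; and the
#'   Monte-Carlo SEs of the rates.
#' @export
operating_characteristics <- function(scenario, replicates,
                                      design = NULL, futility = TRUE) {
  stopifnot(inherits(scenario, "dgs_scenario"), replicates >= 0)
  if (is.null(design)) {
    design <- locus_design(scenario$locus_id, maf = scenario$maf)
  }
  if (is.na(design$ris)) {
    stop("operating characteristics need a resolved (fixed-D2) design")
  }
  empty <- structure(list(replicates = 0L, categories = integer(0)),
                     class = "dgs_ocs")
  if (replicates == 0L) return(empty)

  subj <- cumsum(scenario$case_n + scenario$ctrl_n)
  bounds <- design_boundaries(design, subj, futility = futility)
  z_naive <- stats::qnorm(1 - design$alpha / 2)

  cats <- character(replicates)
  naive_hit <- logical(replicates)
  decisive <- rep(NA_integer_, replicates)
  final_log_or <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cnt <- sim_counts(scenario, rep = r)
    eff <- effects_from_counts(cnt)
    cz <- cum_dl_z(eff$y, eff$v)
    crossing <- evaluate_crossing(cz$z, subj, design, bounds)
    final_log_or[r] <- cz$final$mu_r
    naive_hit[r] <- any(abs(cz$z) >= z_naive)
    if (!is.na(crossing$significance_look)) {
      cats[r] <- if (cz$z[crossing$significance_look] > 0)
        "conclusive_risk" else "conclusive_protective"
      decisive[r] <- crossing$significance_look
    } else if (!is.na(crossing$futility_look) || crossing$ris_reached) {
      cats[r] <- "conclusive_null"
      decisive[r] <- if (!is.na(crossing$futility_look))
        crossing$futility_look else which(subj >= design$ris)[1L]
    } else {
      cats[r] <- "inconclusive"
    }
  }
  tab <- table(factor(cats, levels = c("conclusive_risk",
                                       "conclusive_protective",
                                       "conclusive_null",
                                       "inconclusive")))
  crossing_rate <- sum(cats %in% c("conclusive_risk",
                                   "conclusive_protective")) / replicates
  naive_rate <- mean(naive_hit)
  rate_se <- function(p) sqrt(p * (1 - p) / replicates)
  structure(list(
    replicates = as.integer(replicates),
    categories = tab,
    crossing_rate = crossing_rate,
    crossing_rate_se = rate_se(crossing_rate),
    naive_rate = naive_rate,
    naive_rate_se = rate_se(naive_rate),
    null_rate = as.numeric(tab["conclusive_null"]) / replicates,
    inconclusive_rate = as.numeric(tab["inconclusive"]) / replicates,
    mean_decisive_look = if (all(is.na(decisive))) NA_real_ else
      mean(decisive, na.rm = TRUE),
    mean_final_log_or = mean(final_log_or),
    mean_final_log_or_se = stats::sd(final_log_or) / sqrt(replicates),
    design = design),
    class = "dgs_ocs")
}

#' @export
print.dgs_ocs <- function(x, ...) {
  if (x$replicates == 0L) {
    cat("Operating characteristics: 0 replicates\n")
    return(invisible(x))
  }
  cat(sprintf("Operating characteristics over %d replicates\n",
              x$replicates))
  print(x$categories)
  cat(sprintf("  significance-crossing rate %.4f (MC-SE %.4f)\n",
              x$crossing_rate, x$crossing_rate_se))
  cat(sprintf("  naive look-every-study rate %.4f (MC-SE %.4f)\n",
              x$naive_rate, x$naive_rate_se))
  cat(sprintf("  mean final pooled log-OR %.4f (MC-SE %.4f)\n",
              x$mean_final_log_or, x$mean_final_log_or_se))
  invisible(x)
}
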