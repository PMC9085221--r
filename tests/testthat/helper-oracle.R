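# Independent oracles, coded from first principles and kept free of the
# package's own pooling/boundary code paths.

# DerSimonian-Laird meta-analysis, step by step with explicit loops.
oracle_dl <- function(log_or, se) {
  k <- length(log_or)
  w <- se^0
  for (i in seq_len(k)) w[i] <- 1 / se[i]^2
  fixed <- sum(w * log_or) / sum(w)
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (log_or[i] - fixed)^2
  tau2 <- 0
  if (k > 1) {
    c_dl <- sum(w) - sum(w * w) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / c_dl)
  }
  wr <- numeric(k)
  for (i in seq_len(k)) wr[i] <- 1 / (se[i]^2 + tau2)
  pooled <- sum(wr * log_or) / sum(wr)
  v_r <- 1 / sum(wr)
  v_f <- 1 / sum(w)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(fixed = fixed, pooled = pooled, q = q, tau2 = tau2,
       v_f = v_f, v_r = v_r, i2 = i2,
       d2 = max(0, 1 - v_f / v_r),
       ci_low = exp(pooled - qnorm(0.975) * sqrt(v_r)),
       ci_high = exp(pooled + qnorm(0.975) * sqrt(v_r)))
}

# Naive look-by-look scan of a Z-series against per-look thresholds.
oracle_scan <- function(z, monitor, futility) {
  sig <- NA_integer_; fut <- NA_integer_
  for (j in seq_along(z)) {
    if (is.na(sig) && abs(z[j]) >= monitor[j]) sig <- j
    if (is.na(fut) && !is.na(futility[j]) && abs(z[j]) <= futility[j]) {
      fut <- j
    }
  }
  list(significance = sig, futility = fut)
}

# Random small study sets (allele-scale effects) for pooling checks.
random_effects <- function(k, seed) {
  set.seed(seed)
  data.frame(log_or = rnorm(k, 0, 0.5),
             se = runif(k, 0.1, 0.6),
             subjects = sample(50:500, k, replace = TRUE))
}
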