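test_that("comparator proportion transforms MAF through the odds ratio", {
  expect_equal(comparator_proportion(0.27, 1), 0.27)
  expect_equal(comparator_proportion(0.38, 1.5), 0.57 / 1.19,
               tolerance = 1e-10)
  expect_equal(comparator_proportion(0.04, 1.5), 0.06 / 1.02,
               tolerance = 1e-10)
})

test_that("fixed information size matches the two-proportion closed form", {
  p_t <- comparator_proportion(0.38, 1.5)
  expect_equal(fixed_information_size(0.05, 0.8, 0.38, p_t), 389L)
  # recompute the closed form independently
  zsum <- qnorm(0.975) + qnorm(0.8)
  m <- zsum^2 * (0.38 * 0.62 + p_t * (1 - p_t)) / (p_t - 0.38)^2
  expect_equal(ceiling(m), 389)
  expect_error(fixed_information_size(0.05, 0.8, 0.3, 0.3), "undefined")
})

test_that("required size grows without bound as the effect vanishes", {
  p_c <- 0.3
  sizes <- vapply(c(2, 1.7, 1.5, 1.3, 1.15, 1.05), function(or) {
    fixed_information_size(0.05, 0.8, p_c, comparator_proportion(p_c, or))
  }, integer(1))
  expect_true(all(diff(sizes) > 0))
})

test_that("diversity adjustment inflates the information size as documented", {
  expect_equal(diversity_adjusted_is(389, 0), 389L)
  expect_equal(diversity_adjusted_is(389, 0.8), 1945L)
  for (n in c(100L, 389L, 1234L)) {
    expect_equal(diversity_adjusted_is(n, 0.8), 5L * n)
  }
})

test_that("alpha spending follows the O'Brien-Fleming form", {
  expect_equal(alpha_spending(1, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(alpha_spending(0.5, 0.05),
               2 * (1 - pnorm(qnorm(0.975) / sqrt(0.5))),
               tolerance = 1e-12)
  grid <- alpha_spending(seq(0.1, 1, 0.1), 0.05)
  expect_true(all(diff(grid) > 0))
  expect_lt(alpha_spending(0.1, 0.05), alpha_spending(0.5, 0.05))
})

test_that("a single look at full information reduces to the fixed-sample test", {
  b <- monitoring_boundaries(1, alpha = 0.05)
  expect_equal(b$monitor_upper, qnorm(0.975), tolerance = 1e-3)
  expect_equal(b$spent_alpha, 0.05, tolerance = 1e-10)
})

test_that("two equal looks reproduce the published Lan-DeMets values", {
  b <- monitoring_boundaries(c(0.5, 1), alpha = 0.05)
  expect_equal(b$monitor_upper, c(2.963, 1.969), tolerance = 2e-3)
  expect_equal(b$spent_alpha[2], 0.05, tolerance = 1e-4)
})

test_that("five equal looks reproduce the published Lan-DeMets values", {
  b <- monitoring_boundaries(seq(0.2, 1, 0.2), alpha = 0.05)
  expect_equal(b$monitor_upper, c(4.877, 3.357, 2.680, 2.290, 2.031),
               tolerance = 2e-3)
  expect_equal(b$spent_alpha[5], 0.05, tolerance = 1e-4)
})

test_that("monitoring thresholds are non-increasing and accounts balance", {
  grids <- list(seq(0.1, 1, 0.1),
                c(0.03, 0.2, 0.55, 0.8, 1),
                c(0.01, 0.02, 0.5, 1),
                seq(0.05, 1, length.out = 20))
  for (fr in grids) {
    b <- monitoring_boundaries(fr, alpha = 0.05)
    expect_true(all(diff(b$monitor_upper) <= 1e-9))
    expect_true(all(b$monitor_upper > 0))
    expect_equal(b$spent_alpha[length(fr)], 0.05, tolerance = 1e-4)
    expect_true(all(diff(b$spent_alpha) >= -1e-12))
  }
  expect_error(monitoring_boundaries(c(0.5, 0.5, 1)), "strictly increasing")
  expect_error(monitoring_boundaries(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("futility wedge lies inside the monitoring band and closes at t = 1", {
  fr <- seq(0.2, 1, 0.2)
  f <- futility_boundaries(fr, alpha = 0.05, power = 0.8)
  K <- length(fr)
  expect_equal(f$futility_upper[K], f$monitor_upper[K], tolerance = 0.05)
  defined <- which(!is.na(f$futility_upper))
  inner <- setdiff(defined, K)
  expect_true(all(f$futility_upper[inner] < f$monitor_upper[inner]))
  expect_true(all(f$futility_upper[defined] > 0))
  # beta account is monotone
  expect_true(all(diff(f$spent_beta) >= -1e-12))
})

test_that("very small information fractions leave the wedge undefined", {
  f <- futility_boundaries(c(0.05, 0.5, 1), alpha = 0.05, power = 0.8)
  expect_true(is.na(f$futility_upper[1]))
  expect_true(is.na(f$futility_lower[1]))
})

test_that("higher power pushes the futility wedge down", {
  fr <- seq(0.25, 1, 0.25)
  f80 <- futility_boundaries(fr, alpha = 0.05, power = 0.8)
  f95 <- futility_boundaries(fr, alpha = 0.05, power = 0.95)
  mid <- 2:3
  both <- !is.na(f80$futility_upper[mid]) & !is.na(f95$futility_upper[mid])
  expect_true(any(both))
  expect_true(all(f95$futility_upper[mid][both] <
                    f80$futility_upper[mid][both]))
})

test_that("crossing evaluation matches a naive look-by-look scan", {
  design <- locus_design("rs1", maf = 0.3, d2 = 0.8)
  subj <- cumsum(rep(110, 15))
  bounds <- design_boundaries(design, subj)
  set.seed(41)
  for (i in 1:20) {
    z <- cumsum(rnorm(15, 0, 1)) / sqrt(1:15) + rnorm(1, 0, 1.2)
    got <- evaluate_crossing(z, subj, design, bounds)
    want <- oracle_scan(z, bounds$monitor_upper, bounds$futility_upper)
    expect_identical(got$significance_look, want$significance)
    expect_identical(got$futility_look, want$futility)
    if (!is.na(got$significance_look)) {
      expect_equal(got$direction, sign(z[got$significance_look]))
    }
  }
})

test_that("crossing edge cases behave as specified", {
  design <- locus_design("rs1", maf = 0.3, d2 = 0)
  ris <- design$ris
  subj <- c(ris %/% 2, ris + 10)
  flat <- evaluate_crossing(c(0, 0), subj, design)
  expect_true(is.na(flat$significance_look))
  expect_true(flat$ris_reached)
  # a flat Z-curve at full information sits inside the closed wedge
  expect_false(is.na(flat$futility_look))

  spike <- evaluate_crossing(c(5, 0), subj, design)
  expect_equal(spike$significance_look, 1L)
  expect_equal(spike$direction, 1)
  # crossing at exactly the threshold counts as crossed
  bounds <- design_boundaries(design, subj)
  exact <- evaluate_crossing(c(bounds$monitor_upper[1], 0), subj, design,
                             bounds)
  expect_equal(exact$significance_look, 1L)
})

test_that("looks after the RIS share fraction 1 and its thresholds", {
  design <- locus_design("rs1", maf = 0.3, d2 = 0)
  subj <- c(200, design$ris, design$ris + 150, design$ris + 300)
  bounds <- design_boundaries(design, subj)
  expect_equal(bounds$fractions[2:4], rep(1, 3))
  expect_equal(bounds$monitor_upper[3], bounds$monitor_upper[2])
  expect_equal(bounds$monitor_upper[4], bounds$monitor_upper[2])
})

test_that("design construction derives p_t, n_fixed and RIS coherently", {
  d <- locus_design("rs2228570", maf = 0.38)
  expect_equal(d$p_t, comparator_proportion(0.38, 1.5))
  expect_equal(d$n_fixed, 389L)
  expect_equal(d$ris, 1945L)
  expect_gte(d$ris, d$n_fixed)

  est <- locus_design("rsX", maf = 0.2, d2 = "estimate")
  expect_true(is.na(est$ris))
  est <- apply_d2(est, 0.5)
  expect_equal(est$ris, 2L * est$n_fixed)
  expect_error(locus_design("rsX", maf = 0.7), "maf")
})
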