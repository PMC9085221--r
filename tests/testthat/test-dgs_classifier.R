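test_that("heterogeneity label applies the strict I2 > 50 rule", {
  expect_equal(heterogeneity_label(74), "high")
  expect_equal(heterogeneity_label(50), "low")
  expect_equal(heterogeneity_label(0), "low")
  expect_equal(heterogeneity_label(c(51, 49.9, 100)),
               c("high", "low", "high"))
})

test_that("an underpowered stream is inconclusive with exact remaining count", {
  sc <- sim_scenario(1.2, 0.3, k = 2, case_n = 80, ctrl_n = 80, seed = 5)
  series <- cumulative_series(study_effects(simulate_locus(sc)))
  design <- locus_design(sc$locus_id, maf = 0.3, d2 = 0.8)
  v <- classify_locus(series, design, ethnicity = "asian")
  expect_equal(v$category, "inconclusive")
  expect_equal(v$remaining_subjects, design$ris - 320L)
  expect_gt(v$remaining_subjects, 0L)
})

test_that("a strong effect crosses the monitoring boundary before the RIS", {
  sc <- sim_scenario(3, 0.3, k = 8, case_n = 250, ctrl_n = 250, seed = 31)
  series <- cumulative_series(study_effects(simulate_locus(sc)))
  design <- locus_design(sc$locus_id, maf = 0.3, d2 = 0.8)
  v <- classify_locus(series, design, ethnicity = "asian")
  expect_equal(v$category, "conclusive_risk")
  expect_false(is.na(v$decisive_look))
  expect_gt(series[[v$decisive_look]]$pooled_log_or, 0)
  # crossing agrees with the naive scan oracle
  z <- vapply(series, function(p) p$z, numeric(1))
  subj <- vapply(series, function(p) p$cumulative_subjects, numeric(1))
  bounds <- design_boundaries(design, subj)
  want <- oracle_scan(z, bounds$monitor_upper, bounds$futility_upper)
  expect_equal(v$decisive_look, want$significance)
  expect_lt(subj[v$decisive_look], design$ris)
})

test_that("a protective effect is classified by direction", {
  sc <- sim_scenario(1 / 3, 0.35, k = 8, case_n = 250, ctrl_n = 250,
                     seed = 32)
  series <- cumulative_series(study_effects(simulate_locus(sc)))
  design <- locus_design(sc$locus_id, maf = 0.35, d2 = 0.8)
  v <- classify_locus(series, design)
  expect_equal(v$category, "conclusive_protective")
  expect_lt(series[[v$decisive_look]]$pooled_log_or, 0)
})

test_that("a null stream accumulated past the RIS is conclusively null", {
  design <- locus_design("rs0000001", maf = 0.3, d2 = 0)
  sc <- sim_scenario(1, 0.3, k = 6, case_n = 120, ctrl_n = 120, seed = 104)
  series <- cumulative_series(study_effects(simulate_locus(sc)))
  subj <- vapply(series, function(p) p$cumulative_subjects, numeric(1))
  expect_gte(max(subj), design$ris)
  v <- classify_locus(series, design)
  expect_equal(v$category, "conclusive_null")
  expect_equal(v$remaining_subjects, 0L)
})

test_that("classification is deterministic and stopping-consistent", {
  sc <- sim_scenario(3, 0.3, k = 8, case_n = 250, ctrl_n = 250, seed = 31)
  eff <- study_effects(simulate_locus(sc))
  design <- locus_design(sc$locus_id, maf = 0.3, d2 = 0.8)
  v1 <- classify_locus(cumulative_series(eff), design)
  v2 <- classify_locus(cumulative_series(eff), design)
  expect_identical(v1$category, v2$category)
  # truncating after the crossing look leaves the verdict unchanged
  trunc <- cumulative_series(eff[seq_len(v1$decisive_look), ])
  v3 <- classify_locus(trunc, design)
  expect_identical(v3$category, v1$category)
  expect_identical(v3$decisive_look, v1$decisive_look)
})

test_that("remaining_samples is the clamped RIS shortfall", {
  design <- locus_design("rsX", maf = 0.38, d2 = 0.8)  # RIS 1945
  expect_equal(remaining_samples(design, 320), 1625L)
  expect_equal(remaining_samples(design, design$ris), 0L)
  expect_equal(remaining_samples(design, design$ris + 500), 0L)
  subj <- seq(100, 1900, by = 300)
  rem <- vapply(subj, function(s) remaining_samples(design, s), integer(1))
  expect_true(all(diff(rem) < 0))
})

test_that("cross_tab places each locus in exactly one cell", {
  expect_equal(sum(cross_tab(verdict_table(list()))$counts), 0L)

  vt <- data.frame(
    locus_id = c("rs1", "rs2", "rs3", "rs4"),
    tsa_result = c("risk", "protective", "not_associated", "still_need"),
    het_label = c("low", "high", "low", "low"),
    stringsAsFactors = FALSE)
  ct <- cross_tab(vt)
  expect_equal(sum(ct$counts), 4L)
  expect_equal(ct$counts["low", "risk"], 1L)
  expect_equal(ct$loci[["high.protective"]], "rs2")
})

test_that("the packaged Caucasian summary reproduces the published splits", {
  cauc <- summary_to_verdicts(published_summary("caucasian"))
  expect_equal(nrow(cauc), 17L)
  expect_equal(sum(cauc$het_label == "high"), 9L)
  expect_equal(sum(cauc$het_label == "low"), 8L)
  ct <- cross_tab(cauc)
  expect_equal(sum(ct$counts["high", ]), 9L)
  expect_equal(ct$loci[["high.not_associated"]],
               sort(c("rs7975232", "rs1544410", "rs1800012", "rs2234693",
                      "rs9340799", "rs3134069")))
  expect_equal(ct$loci[["high.still_need"]],
               sort(c("rs731236", "rs1800470", "rs4986938")))
  expect_equal(ct$loci[["low.not_associated"]],
               sort(c("rs1800795", "rs1256049")))
  expect_equal(sum(ct$counts[, c("risk", "protective")]), 0L)
})

test_that("the packaged Asian summary reproduces the published splits", {
  asi <- summary_to_verdicts(published_summary("asian"))
  expect_equal(nrow(asi), 15L)
  expect_equal(sum(asi$het_label == "high"), 6L)
  expect_equal(sum(asi$het_label == "low"), 9L)
  ct <- cross_tab(asi)
  expect_equal(sum(ct$counts["low", ]), 9L)
  expect_equal(ct$loci[["low.risk"]],
               sort(c("rs2228570", "rs2288377", "rs35767")))
  expect_equal(ct$loci[["low.protective"]], "rs1256049")
  expect_equal(ct$loci[["high.risk"]], "rs1800470")
  expect_equal(ct$loci[["high.still_need"]],
               sort(c("rs2234693", "rs7975232", "rs1544410", "rs2228480")))
})

test_that("nominal significance without a crossing stays inconclusive but is noted", {
  # modest effect, two small studies: final p can dip under alpha while
  # far from both the boundary and the RIS
  found <- FALSE
  for (seed in 1:40) {
    sc <- sim_scenario(1.6, 0.3, k = 2, case_n = 90, ctrl_n = 90,
                       seed = seed)
    series <- cumulative_series(study_effects(simulate_locus(sc)))
    design <- locus_design(sc$locus_id, maf = 0.3, d2 = 0.8)
    v <- classify_locus(series, design)
    if (v$category == "inconclusive" && isTRUE(v$nominal_significance)) {
      found <- TRUE
      expect_gt(v$remaining_subjects, 0L)
      break
    }
  }
  expect_true(found)
})
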