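test_that("RSD matches hand-computed values and is scale-invariant", {
  expect_equal(rsd(c(10, 10, 10)), 0)
  expect_equal(rsd(c(9, 10, 11)), 10, tolerance = 1e-12)
  expect_equal(rsd(c(90, 100, 110)), 10, tolerance = 1e-12)
  expect_error(rsd(5), "at least 2")
  expect_error(rsd(c(-2, 0, -1)), "positive mean")
})

test_that("spike recovery follows the standard-addition formula", {
  expect_equal(recovery(15, 10, 5), 100)
  expect_equal(recovery(14.5, 10, 5), 90, tolerance = 1e-12)
  expect_error(recovery(15, 10, 0), "positive")

  tab <- data.frame(analyte = "a", level = c("low", "medium", "high"),
                    found = c(14.4, 15, 15.6), original = 10, spiked = 5)
  rep <- recovery_report(tab, band = c(85.25, 113.61))
  expect_equal(rep$recovery_pct, c(88, 100, 112), tolerance = 1e-9)
  expect_true(all(rep$acceptable))   # inside the observed-satisfactory band
  expect_false(recovery_report(transform(tab, found = c(14, 10 + 5 * 1.2, 16)),
                               band = c(85.25, 113.61))$acceptable[2])
})

test_that("precision report separates intra-, inter-day and pooled RSDs", {
  intra <- data.frame(analyte = "a", area = rep(100, 6))
  inter <- data.frame(analyte = "a", day = rep(1:3, each = 6),
                      area = rep(100, 18))
  rep <- precision_report(intra, inter)
  expect_equal(rep$intraday_rsd, 0)
  expect_equal(rep$interday_rsd, 0)
  expect_true(rep$pass)

  # inflating one day's areas hits the interday term hardest
  set.seed(2)
  areas <- 100 * (1 + stats::rnorm(18, 0, 0.01))
  inter2 <- data.frame(analyte = "a", day = rep(1:3, each = 6),
                       area = ifelse(rep(1:3, each = 6) == 2,
                                     2 * areas, areas))
  rep2 <- precision_report(data.frame(analyte = "a", area = areas[1:6]),
                           inter2)
  expect_gt(rep2$interday_rsd, rep2$intraday_rsd)
  expect_false(rep2$pass)
})

test_that("simulated 3% CV areas produce ~3% intraday RSD on average", {
  set.seed(31)
  n_rep <- 200
  rsds <- replicate(n_rep, rsd(100 * pmax(0, 1 + stats::rnorm(6, 0, 0.03))))
  # E[sample SD]/mean underestimates the CV slightly at n = 6 (c4 factor)
  c4 <- sqrt(2 / 5) * gamma(3) / gamma(2.5)
  mc_se <- stats::sd(rsds) / sqrt(n_rep)
  expect_lt(abs(mean(rsds) - 3 * c4), 3 * mc_se)
})

test_that("stability and repeatability reports validate structure and limits", {
  st <- data.frame(analyte = "a", hour = seq(0, 12, 2), area = rep(500, 7))
  expect_equal(stability_report(st)$rsd_pct, 0)
  expect_true(stability_report(st)$pass)
  st3 <- data.frame(analyte = "a", hour = c(0, 2, 4), area = c(9, 10, 11))
  expect_equal(stability_report(st3)$rsd_pct, 10, tolerance = 1e-12)
  expect_false(stability_report(st3, limit = 5)$pass)
  expect_error(stability_report(data.frame(analyte = "a", hour = c(2, 0, 4),
                                           area = 1:3)), "increasing")
  expect_error(stability_report(data.frame(analyte = "a", hour = c(0, 0, 4),
                                           area = 1:3)), "unique")

  rp <- data.frame(analyte = "a", prep = 1:6, area = rep(7, 6))
  expect_equal(repeatability_report(rp)$rsd_pct, 0)
  rp2 <- data.frame(analyte = "a", prep = 1:3, area = c(9, 10, 11) * 3)
  expect_equal(repeatability_report(rp2)$rsd_pct, 10, tolerance = 1e-12)
})

test_that("robustness across conditions separates RCF and RRT stability", {
  p <- ref_fixture$panel
  cfg <- noise_free_config(true_curves = zero_intercept_curves())
  base <- generate_calibration_batch(cfg)

  # identical batches: everything is perfectly robust
  conds <- list(list(label = "c1", peaks = base),
                list(label = "c2", peaks = base))
  rep0 <- robustness_report(conds, p)
  expect_equal(rep0$rcf_rsd, rep(0, 7), tolerance = 1e-10)
  expect_equal(rep0$rrt_rsd, rep(0, 7), tolerance = 1e-10)
  expect_true(all(rep0$rcf_pass))
  expect_true(all(rep0$rrt_class == "RRT-sufficient"))

  # early-eluter RT shifts across columns break RRT but not the RCFs
  early <- c(goitrin = 1, ephedrine = 1, pseudoephedrine = 1)
  conds2 <- generate_robustness_set(cfg, list(
    list(label = "col_A", rt_mult = 0.75 * early, response_scale = 1.0),
    list(label = "col_B", rt_mult = 1, response_scale = 1.2),
    list(label = "col_C", rt_mult = 1.3 * early, response_scale = 0.9)))
  rep2 <- robustness_report(conds2, p)
  shifted <- rep2$analyte %in% names(early)
  expect_true(all(rep2$rrt_rsd[shifted] > 5))
  expect_true(all(rep2$rrt_class[shifted] ==
                    "RRT-insufficient - require m/z confirmation"))
  expect_true(all(rep2$rrt_rsd[!shifted] < 5))
  expect_true(all(rep2$rcf_rsd < 5))  # uniform response scaling cancels

  # permutation invariance of the classifications
  rep2r <- robustness_report(rev(conds2), p)
  expect_equal(rep2r[order(rep2r$analyte), ], rep2[order(rep2$analyte), ],
               ignore_attr = TRUE)

  # hand-checked two-condition dispersion: RCFs 1.9 vs 2.1 -> RSD 7.07%
  expect_equal(rsd(c(1.9, 2.1)), 100 * sqrt(0.02) / 2, tolerance = 1e-12)
})

test_that("method comparison pairs grids, tests variances and issues verdicts", {
  esm <- data.frame(sample_id = sprintf("S%d", 1:6), analyte = "chlorogenic_acid",
                    conc_mg_ml = c(2.02, 2.07, 2.10, 1.99, 2.09, 1.98))

  # identical result sets: zero SMDs, F = 1, p = 1
  cmp <- compare_methods(esm, esm)
  expect_equal(cmp$rows$smd, rep(0, 6))
  expect_equal(cmp$by_analyte$f_statistic, 1)
  expect_equal(cmp$by_analyte$p_value, 1)
  expect_identical(cmp$verdict, "consistent")

  # a uniform 2.6% offset stays consistent
  qams <- transform(esm, conc_mg_ml = conc_mg_ml * 0.974)
  cmp2 <- compare_methods(esm, qams, smd_limit = 10)
  expect_equal(max(cmp2$rows$smd), 2.6, tolerance = 1e-9)
  expect_identical(cmp2$by_analyte$verdict, "consistent")

  # a method with 10x the spread fails the F test
  set.seed(9)
  base <- 2 + stats::rnorm(12, 0, 0.02)
  esm3 <- data.frame(sample_id = sprintf("S%d", 1:12), analyte = "a",
                     conc_mg_ml = base)
  qams3 <- transform(esm3, conc_mg_ml = 2 + (base - 2) * 10)
  cmp3 <- compare_methods(esm3, qams3, smd_limit = 100)
  expect_gt(cmp3$by_analyte$f_statistic, 50)
  expect_lt(cmp3$by_analyte$p_value, 0.05)
  expect_identical(cmp3$verdict, "inconsistent")

  # the optional paired t-test is exposed as an interpretation
  cmp4 <- compare_methods(esm, qams, paired_t = TRUE)
  expect_true(cmp4$by_analyte$t_p < 0.05)

  expect_error(compare_methods(esm, esm[-1, ]), "do not match")
})
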