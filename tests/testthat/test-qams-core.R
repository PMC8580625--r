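mk_series <- function(conc, area, runs = sprintf("L%02d", seq_along(conc))) {
  data.frame(run_id = runs, area = area, nominal_conc_ng_ml = conc,
             stringsAsFactors = FALSE)
}

test_that("AVG correction factor averages per-run response-factor ratios", {
  k <- mk_series(c(1, 2), c(10, 18))
  s <- mk_series(c(1, 2), c(5, 10))
  got <- rcf_avg(k, s)
  expect_equal(got$mean, 1.9, tolerance = 1e-12)
  expect_equal(got$sd, sqrt(0.02), tolerance = 1e-12)  # sample SD of 2.0, 1.8
  expect_equal(got$n, 2)

  self <- rcf_avg(k, k)
  expect_equal(self$mean, 1)
  expect_equal(self$sd, 0)

  # proportional (zero-intercept) responses give the exact slope ratio, sd 0
  conc_k <- c(1, 2, 4, 8); conc_s <- c(0.5, 1, 2, 4)
  got <- rcf_avg(mk_series(conc_k, 7449.48 * conc_k),
                 mk_series(conc_s, 616.17 * conc_s))
  expect_equal(got$mean, 7449.48 / 616.17, tolerance = 1e-12)
  expect_equal(got$sd, 0, tolerance = 1e-10)

  expect_error(rcf_avg(mk_series(1, 10, "a"), mk_series(1, 5, "b")),
               "no runs shared")
  expect_error(rcf_avg(k, mk_series(c(1, 2), c(0, 10))), "zero IRS area")
})

test_that("LRG correction factor is the slope ratio", {
  expect_equal(round(rcf_lrg(7449.48, 616.17), 2), 12.09)
  expect_equal(round(rcf_lrg(84605.00, 616.17), 2), 137.31)
  expect_equal(rcf_lrg(616.17, 616.17), 1)
  expect_error(rcf_lrg(10, 0), "zero")
})

test_that("LRG factors satisfy reciprocity and transitivity exactly", {
  slopes <- ref_fixture$curves$slope
  for (i in seq_along(slopes))
    for (j in seq_along(slopes))
      expect_equal(rcf_lrg(slopes[i], slopes[j]) *
                     rcf_lrg(slopes[j], slopes[i]), 1, tolerance = 1e-12)
  for (q in seq_along(slopes))
    expect_equal(rcf_lrg(slopes[1], slopes[q]) * rcf_lrg(slopes[q], slopes[8]),
                 rcf_lrg(slopes[1], slopes[8]), tolerance = 1e-12)
})

test_that("relative retention time is the plain RT ratio", {
  expect_equal(round(relative_retention(1.54, 6.16), 2), 0.25)
  expect_equal(round(relative_retention(5.49, 6.16), 2), 0.89)
  expect_equal(relative_retention(6.16, 6.16), 1)
  expect_error(relative_retention(-1, 6.16), "positive")
  expect_error(relative_retention(1.54, 0), "positive")
})

test_that("single-marker quantification follows the two printed formulas", {
  # AVG path: identity configuration returns the IRS concentration
  expect_equal(quantify_qams_avg(10, 10, 10, 1, 1), working_to_prep(10, 1))
  # direct substitution: (1/2) * 10 * 40/10 = 20 working ng/mL
  expect_equal(quantify_qams_avg(40, 10, 10, 2, 1), working_to_prep(20, 1))
  expect_error(quantify_qams_avg(40, 10, 0, 2, 1), "positive")

  # LRG path
  expect_equal(quantify_qams_lrg(7, 1, 1, 1), working_to_prep(7, 1))
  expect_equal(quantify_qams_lrg(616.17 * 12.09 * 50, 616.17, 12.09, 1),
               working_to_prep(50, 1), tolerance = 1e-12)
  expect_error(quantify_qams_lrg(7, 0, 1, 1), "zero")

  # dilution factor and unit conversion go through the one documented place
  expect_equal(quantify_qams_avg(10, 94, 10, 1, 5000), 0.47)
})

test_that("standard method difference uses the absolute convention", {
  expect_equal(smd(2, 2), 0)
  expect_equal(smd(2.0, 1.9), 5.0, tolerance = 1e-12)
  expect_equal(smd(1.0, 1.1), 10.0, tolerance = 1e-12)   # sign folded
  expect_equal(smd(1.0, 1.1, signed = TRUE), -10.0, tolerance = 1e-12)
  expect_error(smd(0, 1), "positive")
  # scale invariance
  set.seed(5)
  a <- stats::runif(10, 0.1, 5); b <- stats::runif(10, 0.1, 5)
  expect_equal(smd(3.7 * a, 3.7 * b), smd(a, b), tolerance = 1e-12)
})

test_that("zero-intercept noise-free data collapse ESM, AVG and LRG", {
  p <- ref_fixture$panel
  cfg <- noise_free_config(true_curves = zero_intercept_curves())
  cal <- generate_calibration_batch(cfg)
  curves <- fit_calibration(cal, p)
  tab <- rcf_table(cal, curves, p)
  expect_equal(tab$avg_mean, tab$lrg, tolerance = 1e-12)
  expect_equal(tab$avg_sd[tab$analyte != p$irs] /
                 tab$avg_mean[tab$analyte != p$irs],
               rep(0, 7), tolerance = 1e-12)
  smp <- generate_sample_batch(cfg)
  esm <- quantify_samples(smp$peaks, p, curves, method = "ESM")
  lrg <- quantify_samples(smp$peaks, p, curves, tab, method = "QAMS_LRG")
  avg <- quantify_samples(rbind(smp$peaks, cal), p, curves, tab,
                          method = "QAMS_AVG")
  avg <- avg[match(paste(esm$sample_id, esm$analyte),
                   paste(avg$sample_id, avg$analyte)), ]
  expect_equal(lrg$conc_mg_ml, esm$conc_mg_ml, tolerance = 1e-10)
  expect_equal(avg$conc_mg_ml, esm$conc_mg_ml, tolerance = 1e-10)
})

test_that("the RCF/RRT table pins the IRS row at exactly 1", {
  cfg <- noise_free_config()
  cal <- generate_calibration_batch(cfg)
  curves <- fit_calibration(cal, ref_fixture$panel)
  tab <- rcf_table(cal, curves, ref_fixture$panel)
  irs_row <- tab[tab$analyte == "baicalein", ]
  expect_equal(unlist(irs_row[, c("avg_mean", "lrg", "rrt")]),
               c(avg_mean = 1, lrg = 1, rrt = 1))
  expect_equal(tab$analyte, ref_fixture$panel$analytes$name)
})

test_that("peaks are positioned by RRT, with m/z rescue for unstable analytes", {
  p <- ref_fixture$panel
  rt <- ref_fixture$retention_min
  observed <- data.frame(
    peak_id = names(rt),
    rt_min = unname(rt),
    precursor_mz = p$analytes$precursor_mz[match(names(rt),
                                                 p$analytes$name)],
    product_mz = p$analytes$product_mz[match(names(rt), p$analytes$name)],
    stringsAsFactors = FALSE)
  pos <- position_peaks(observed, p, irs_rt = rt[["baicalein"]])
  expect_equal(nrow(pos$assigned), 8)
  expect_equal(sort(pos$assigned$analyte), sort(p$analytes$name))
  expect_identical(pos$assigned$analyte, pos$assigned$peak_id)
  expect_equal(nrow(pos$ambiguous), 0)

  # a 30% retention shift (column change) breaks RRT-only positioning
  shifted <- observed
  shifted$rt_min[shifted$peak_id == "goitrin"] <- rt[["goitrin"]] * 1.3
  pos2 <- position_peaks(shifted, p, irs_rt = rt[["baicalein"]])
  expect_true("goitrin" %in% pos2$missing)
  expect_true("goitrin" %in% pos2$unassigned$peak_id)

  # widened window plus mandatory m/z confirmation recovers it
  pos3 <- position_peaks(shifted, p, irs_rt = rt[["baicalein"]],
                         unstable = "goitrin")
  expect_true("goitrin" %in% pos3$assigned$analyte)
  expect_equal(length(pos3$missing), 0)

  expect_warning(res <- position_peaks(observed[0, ], p, irs_rt = 6.16),
                 "empty")
  expect_equal(nrow(res$assigned), 0)
  expect_equal(res$missing, p$analytes$name)
})

test_that("IRS screening ranks candidates and flags corrupted responses", {
  p <- ref_fixture$panel
  cfg <- noise_free_config(true_curves = zero_intercept_curves())
  cal <- generate_calibration_batch(cfg)
  curves <- fit_calibration(cal, p)
  chk <- generate_calibration_batch(cfg, n_replicates = 2,
                                    run_prefix = "chk")
  sel <- select_irs(cal, curves, chk, p)
  expect_true(all(sel$summary$eligible))
  expect_equal(sel$summary$max_smd, rep(0, nrow(sel$summary)),
               tolerance = 1e-9)

  # corrupt one analyte's areas x10 at one level: every screen that relies
  # on it degrades, and as a candidate IRS it scores strictly worst
  bad <- cal
  pick <- bad$analyte == "amygdalin" & grepl("_L05_", bad$run_id)
  bad$area[pick] <- bad$area[pick] * 10
  curves_bad <- fit_calibration(bad, p)
  sel_bad <- select_irs(bad, curves_bad, chk, p)
  avg <- sel_bad$summary[sel_bad$summary$estimator == "AVG", ]
  expect_gt(avg$mean_smd[avg$candidate == "amygdalin"],
            max(avg$mean_smd[avg$candidate != "amygdalin"]))
})
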