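test_that("identical configurations generate bit-identical datasets", {
  cfg <- generator_config(seed = 99)
  expect_identical(generate_calibration_batch(cfg),
                   generate_calibration_batch(cfg))
  expect_identical(generate_sample_batch(cfg), generate_sample_batch(cfg))
  expect_identical(generate_validation_batches(cfg),
                   generate_validation_batches(cfg))
  # a different seed changes the data
  cfg2 <- generator_config(seed = 100)
  expect_false(identical(generate_calibration_batch(cfg),
                         generate_calibration_batch(cfg2)))
  # the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_calibration_batch(cfg))
  expect_identical(stats::runif(1), before)
})

test_that("dilution ladders are 2-fold, top-anchored, with the low anchored", {
  cfg <- noise_free_config()
  cal <- generate_calibration_batch(cfg, n_replicates = 1)
  for (a in c("goitrin", "baicalein", "baicalin")) {
    lv <- sort(unique(cal$nominal_conc_ng_ml[cal$analyte == a]))
    ana <- ref_fixture$panel$analytes
    expect_equal(length(lv), 8)
    expect_equal(min(lv), ana$calib_low[ana$name == a])
    expect_equal(max(lv), ana$calib_high[ana$name == a])
    expect_equal(lv[-1][-1] / lv[-1][-7], rep(2, 6))  # 2-fold above the anchor
  }
  # glycyrrhizinate's low coincides with high/2^6 and is deduplicated
  lv <- sort(unique(cal$nominal_conc_ng_ml[cal$analyte == "glycyrrhizinate"]))
  expect_equal(lv, 480 / 2^(6:0))
})

test_that("noise-free batches lie exactly on the true response lines", {
  cfg <- noise_free_config()
  cal <- generate_calibration_batch(cfg)
  tc <- cfg$true_curves
  idx <- match(cal$analyte, tc$analyte)
  expect_equal(cal$area,
               tc$slope[idx] * cal$nominal_conc_ng_ml + tc$intercept[idx],
               tolerance = 1e-12)
  expect_equal(cal$rt_min,
               ref_fixture$panel$analytes$expected_rt_min[
                 match(cal$analyte, ref_fixture$panel$analytes$name)],
               tolerance = 1e-12)
})

test_that("empirical area CV at the top level converges to the configured CV", {
  cfg <- generator_config(area_cv = 0.03, seed = 17)
  cal <- generate_calibration_batch(cfg, n_replicates = 400)
  b0 <- cal[cal$analyte == "baicalein", ]
  top <- b0[b0$nominal_conc_ng_ml == max(b0$nominal_conc_ng_ml), ]
  expect_equal(stats::sd(top$area) / mean(top$area), 0.03, tolerance = 0.15)

  # variance-proportional-to-x mode: SD grows like sqrt(conc)
  cfgx <- generator_config(area_cv = 0.03, noise_model = "prop_x", seed = 18)
  calx <- generate_calibration_batch(cfgx, n_replicates = 400)
  b <- calx[calx$analyte == "baicalein", ]
  sds <- tapply(b$area, b$nominal_conc_ng_ml, stats::sd)
  conc <- as.numeric(names(sds))
  fit <- stats::lm(log(as.numeric(sds)) ~ log(conc))
  expect_equal(unname(stats::coef(fit)[2]), 0.5, tolerance = 0.1)
})

test_that("sample batches carry ground truth that the pipeline can score", {
  cfg <- noise_free_config()
  smp <- generate_sample_batch(cfg)
  expect_equal(nrow(smp$truth), 6 * 8)
  expect_equal(sort(unique(smp$peaks$run_id)), sprintf("S%02d", 1:6))
  expect_true(all(is.na(smp$peaks$nominal_conc_ng_ml)))
  # the published contents seed the default truth for the published analytes
  expect_equal(smp$truth$true_conc_mg_ml[smp$truth$analyte == "baicalein"],
               c(0.47, 0.44, 0.45, 0.42, 0.45, 0.43))
})

test_that("validation batches follow the configured replicate design", {
  cfg <- generator_config(area_cv = 0.03, seed = 5)
  v <- generate_validation_batches(cfg)
  expect_equal(as.integer(table(v$intraday$analyte)), rep(6L, 8))
  expect_equal(as.integer(table(v$interday$analyte)), rep(18L, 8))
  expect_equal(unique(v$stability$hour), seq(0, 12, 2))
  expect_equal(max(v$repeatability$prep), 6)
  expect_equal(as.integer(table(v$recovery$level)), rep(5L * 8, 3))
  # the reports consume them directly
  expect_s3_class(precision_report(v$intraday, v$interday), "data.frame")
  expect_true(all(stability_report(v$stability, limit = 15)$pass))
  rec <- recovery_report(data.frame(analyte = v$recovery$analyte,
                                    level = v$recovery$level,
                                    found = v$recovery$found,
                                    original = v$recovery$original,
                                    spiked = v$recovery$spiked))
  expect_true(mean(rec$acceptable) > 0.9)
})
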