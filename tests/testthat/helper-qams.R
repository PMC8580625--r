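# shared fixtures: the published panel/curves and common generator setups
ref_fixture <- pneumonia_reference()

zero_intercept_curves <- function() {
  cur <- ref_fixture$curves[, c("analyte", "slope", "intercept")]
  cur$intercept <- 0
  cur
}

noise_free_config <- function(...) {
  generator_config(area_cv = 0, rt_jitter_cv = 0, ...)
}

# small random peak table for round-trip properties
random_peak_table <- function(n = 12) {
  analytes <- sample(ref_fixture$panel$analytes$name, n, replace = TRUE)
  role <- sample(c("standard", "sample", "spiked"), n, replace = TRUE)
  data.frame(
    analyte = analytes,
    run_id = sprintf("r%03d", seq_len(n)),
    role = role,
    rt_min = round(stats::runif(n, 0.5, 8), 4),
    area = round(stats::runif(n, 0, 1e6), 3),
    nominal_conc_ng_ml = ifelse(role == "sample", NA_real_,
                                round(stats::runif(n, 0.01, 1000), 5)),
    stringsAsFactors = FALSE)
}
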