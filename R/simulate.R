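# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic study generator
#'
#' Bundles everything the generator needs to emulate a complete
#' single-marker study: the panel, the true response lines, the noise
#' regime, the true preparation contents, and the replicate design of the
#' validation experiments. Identical configurations (including the seed)
#' produce bit-identical datasets.
#'
#' Defaults emulate the eight-constituent pneumonia-mixture study: the
#' published calibration lines as truth, 3% multiplicative area CV (a
#' typical LC-MS/MS repeatability), 0.5% retention-time jitter, six samples
#' at the published contents (assumed mid-range values for the four
#' unpublished analytes), an 8-level 2-fold dilution ladder with the
#' calibration low anchored as the bottom level, and 3 replicate injections
#' per level.
#'
#' @param panel An [analyte_panel()]; default [pneumonia_panel()].
#' @param true_curves Data frame `analyte, slope, intercept`: the true
#'   response lines; default the published curves for the default panel.
#' @param area_cv Fractional coefficient of variation of peak areas
#'   (default 0.03).
#' @param rt_jitter_cv Fractional CV of retention times (default 0.005).
#' @param noise_model `"cv"` (default): multiplicative truncated-normal
#'   noise, SD proportional to the mean area (constant CV, the common
#'   empirical LC-MS regime). `"prop_x"`: variance proportional to
#'   concentration, the regime under which 1/x weighting is exactly optimal;
#'   scaled so the CV at the top calibration level equals `area_cv`.
#' @param true_sample_conc Named vector (recycled over samples) or
#'   `n_samples x n_analytes` matrix of true preparation contents, mg/mL.
#' @param n_samples Number of preparation samples (default 6).
#' @param n_levels Calibration levels per analyte (default 8).
#' @param n_cal_replicates Replicate injections per calibration level
#'   (default 3).
#' @param seed Integer seed; derived streams use small fixed offsets so the
#'   calibration, sample, check and validation batches differ while staying
#'   reproducible.
#' @param design Replicate design of the validation experiments (see
#'   defaults in the usage).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(panel = pneumonia_panel(),
                             true_curves = NULL,
                             area_cv = 0.03,
                             rt_jitter_cv = 0.005,
                             noise_model = c("cv", "prop_x"),
                             true_sample_conc = NULL,
                             n_samples = 6,
                             n_levels = 8,
                             n_cal_replicates = 3,
                             seed = 1,
                             design = list(intraday = 6, interday_days = 3,
                                           interday_inj = 6,
                                           stability_hours = seq(0, 12, 2),
                                           repeatability = 6,
                                           recovery_levels = c(low = 0.5,
                                                               medium = 1.0,
                                                               high = 1.5),
                                           recovery_replicates = 5)) {
  stopifnot(inherits(panel, "analyte_panel"))
  noise_model <- match.arg(noise_model)
  if (!is.numeric(area_cv) || area_cv < 0)
    stop("'area_cv' must be >= 0", call. = FALSE)
  if (!is.numeric(rt_jitter_cv) || rt_jitter_cv < 0)
    stop("'rt_jitter_cv' must be >= 0", call. = FALSE)
  nm <- panel$analytes$name
  if (is.null(true_curves)) {
    ref <- pneumonia_reference()$curves
    if (!all(nm %in% ref$analyte))
      stop("no default true curves for this panel; supply 'true_curves'",
           call. = FALSE)
    true_curves <- ref[match(nm, ref$analyte),
                       c("analyte", "slope", "intercept")]
  }
  if (!all(nm %in% true_curves$analyte))
    stop("'true_curves' must cover every panel analyte", call. = FALSE)
  if (is.null(true_sample_conc)) {
    ref <- pneumonia_reference()
    pub <- ref$contents[!is.na(ref$contents$esm_mg_ml), ]
    true_sample_conc <- sapply(nm, function(a) {
      v <- pub$esm_mg_ml[pub$analyte == a]
      if (length(v)) v[seq_len(min(n_samples, length(v)))][
        rep_len(seq_len(min(n_samples, length(v))), n_samples)]
      else rep(unname(ref$assumed_contents[a]), n_samples)
    })
    if (is.null(dim(true_sample_conc)))
      true_sample_conc <- matrix(true_sample_conc, nrow = n_samples,
                                 dimnames = list(NULL, nm))
  }
  if (is.null(dim(true_sample_conc))) {
    if (is.null(names(true_sample_conc)) ||
        !all(nm %in% names(true_sample_conc)))
      stop("'true_sample_conc' must be named by analyte", call. = FALSE)
    true_sample_conc <- matrix(rep(true_sample_conc[nm], each = n_samples),
                               nrow = n_samples, dimnames = list(NULL, nm))
  }
  if (nrow(true_sample_conc) != n_samples ||
      !all(nm %in% colnames(true_sample_conc)))
    stop("'true_sample_conc' matrix must be n_samples x panel analytes",
         call. = FALSE)
  if (any(true_sample_conc <= 0))
    stop("true sample contents must be positive", call. = FALSE)
  seed <- as.integer(seed)
  structure(list(panel = panel,
                 true_curves = true_curves[match(nm, true_curves$analyte), ],
                 area_cv = area_cv, rt_jitter_cv = rt_jitter_cv,
                 noise_model = noise_model,
                 true_sample_conc = true_sample_conc[, nm, drop = FALSE],
                 n_samples = n_samples, n_levels = n_levels,
                 n_cal_replicates = n_cal_replicates, seed = seed,
                 design = design),
            class = "generator_config")
}

# 2-fold dilution ladder anchored at the top of the range, with the
# calibration low appended as the bottom level (dropped if coincident)
dilution_ladder <- function(low, high, n) {
  raw <- high / 2^((n - 2):0)
  raw <- raw[raw > low * (1 + 1e-9)]
  c(low, raw)
}

# area noise around the true line; truncated at zero
noisy_area <- function(mu, conc, cfg, top_mu, top_conc) {
  if (cfg$area_cv == 0) return(mu)
  sd <- switch(cfg$noise_model,
               cv = cfg$area_cv * mu,
               prop_x = cfg$area_cv * top_mu * sqrt(conc / top_conc))
  pmax(0, mu + stats::rnorm(length(mu), 0, sd))
}

jitter_rt <- function(rt, cfg, n = length(rt)) {
  if (cfg$rt_jitter_cv == 0) return(rep_len(rt, n))
  pmax(1e-6, rep_len(rt, n) * (1 + stats::rnorm(n, 0, cfg$rt_jitter_cv)))
}

#' Generate a mixed-standard calibration batch
#'
#' Emulates a mixed-standard dilution series: every run is one dilution of a
#' mixed stock, so all analytes share run identifiers (which is what lets
#' [rcf_avg()] pair them). Each analyte's levels follow the configuration's
#' 2-fold ladder over its own calibration range; analytes whose ladder is
#' shorter (their range spans fewer doublings) are absent from the lowest
#' runs, as they would be below range there. Mean areas lie exactly on the
#' true response line; noise and retention-time jitter follow the
#' configuration.
#'
#' @param config A [generator_config()].
#' @param seed Seed for this batch (default `config$seed`).
#' @param n_replicates Replicate injections per level (default from config).
#' @param run_prefix Prefix of the generated run identifiers (default
#'   `"cal"`).
#' @return A peak-table data frame (`standard` rows only).
#' @export
generate_calibration_batch <- function(config, seed = config$seed,
                                       n_replicates = config$n_cal_replicates,
                                       run_prefix = "cal") {
  stopifnot(inherits(config, "generator_config"))
  ana <- config$panel$analytes
  n <- config$n_levels
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(ana))) {
      lv <- dilution_ladder(ana$calib_low[i], ana$calib_high[i], n)
      lev_idx <- (n - length(lv) + 1L):n  # align ladders from the top
      conc <- rep(lv, each = n_replicates)
      level <- rep(lev_idx, each = n_replicates)
      repl <- rep(seq_len(n_replicates), times = length(lv))
      mu <- config$true_curves$slope[i] * conc +
        config$true_curves$intercept[i]
      out[[i]] <- data.frame(
        analyte = ana$name[i],
        run_id = sprintf("%s_L%02d_r%02d", run_prefix, level, repl),
        role = "standard",
        rt_min = jitter_rt(ana$expected_rt_min[i], config, length(conc)),
        area = noisy_area(mu, conc, config,
                          top_mu = config$true_curves$slope[i] * max(lv) +
                            config$true_curves$intercept[i],
                          top_conc = max(lv)),
        nominal_conc_ng_ml = conc, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate a batch of preparation samples with ground truth
#'
#' Each sample's true content (mg/mL in the undiluted preparation) is
#' converted to the working concentration through the panel dilution
#' ([prep_to_working()]); areas come from the same response/noise model as
#' the calibration batch. The ground truth is returned alongside so recovery
#' of the pipeline can be scored.
#'
#' @param config A [generator_config()].
#' @param seed Seed for this batch (default `config$seed + 1`).
#' @return List: `peaks` (peak table, `sample` rows, run ids `S01...`),
#'   `truth` (data frame `sample_id, analyte, true_conc_mg_ml`).
#' @export
generate_sample_batch <- function(config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "generator_config"))
  ana <- config$panel$analytes
  tr <- config$true_sample_conc
  with_seed(seed, {
    peaks <- list(); truth <- list()
    for (i in seq_len(nrow(ana))) {
      a <- ana$name[i]
      working <- prep_to_working(tr[, a], config$panel$dilution)
      mu <- config$true_curves$slope[i] * working +
        config$true_curves$intercept[i]
      top_c <- ana$calib_high[i]
      peaks[[i]] <- data.frame(
        analyte = a, run_id = sprintf("S%02d", seq_len(config$n_samples)),
        role = "sample",
        rt_min = jitter_rt(ana$expected_rt_min[i], config,
                           config$n_samples),
        area = noisy_area(mu, working, config,
                          top_mu = config$true_curves$slope[i] * top_c +
                            config$true_curves$intercept[i],
                          top_conc = top_c),
        nominal_conc_ng_ml = NA_real_, stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        sample_id = sprintf("S%02d", seq_len(config$n_samples)),
        analyte = a, true_conc_mg_ml = tr[, a], stringsAsFactors = FALSE)
    }
    list(peaks = do.call(rbind, peaks), truth = do.call(rbind, truth))
  })
}

#' Generate calibration batches under perturbed chromatographic conditions
#'
#' Builds one complete calibration batch per condition for robustness
#' studies. Retention times are shifted by per-analyte multipliers (large
#' shifts of early eluters emulate what flow-rate and column-geometry
#' changes do in practice) and responses are scaled per condition. A uniform
#' response scale leaves every relative correction factor unchanged — the
#' ratio cancels — so RCF robustness is the expected outcome unless an
#' analyte-specific perturbation is requested.
#'
#' @param config A [generator_config()].
#' @param conditions List of condition specs: each a list with `label`
#'   (text), `rt_mult` (scalar or named per-analyte multiplier, default 1)
#'   and `response_scale` (scalar or named per-analyte multiplier applied to
#'   slope and intercept, default 1).
#' @param seed Base seed (default `config$seed + 10`; condition i uses
#'   `seed + i`).
#' @return List of conditions in the layout [robustness_report()] consumes:
#'   each a list with `label` and `peaks`.
#' @export
generate_robustness_set <- function(config, conditions,
                                    seed = config$seed + 10L) {
  stopifnot(inherits(config, "generator_config"))
  nm <- config$panel$analytes$name
  expand <- function(x, default = 1) {
    if (is.null(x)) return(stats::setNames(rep(default, length(nm)), nm))
    if (length(x) == 1L && is.null(names(x)))
      return(stats::setNames(rep(x, length(nm)), nm))
    out <- stats::setNames(rep(default, length(nm)), nm)
    out[names(x)] <- x
    out
  }
  lapply(seq_along(conditions), function(i) {
    cs <- conditions[[i]]
    rt_mult <- expand(cs$rt_mult)
    resp <- expand(cs$response_scale)
    pan <- config$panel
    pan$analytes$expected_rt_min <- pan$analytes$expected_rt_min * rt_mult[nm]
    tc <- config$true_curves
    tc$slope <- tc$slope * resp[nm]
    tc$intercept <- tc$intercept * resp[nm]
    cfg_i <- config
    cfg_i$panel <- pan
    cfg_i$true_curves <- tc
    list(label = if (is.null(cs$label)) paste0("condition_", i) else cs$label,
         peaks = generate_calibration_batch(cfg_i, seed = seed + i,
                                            run_prefix = sprintf("c%02d", i)))
  })
}

#' Generate the validation-experiment datasets
#'
#' Emulates the replicate designs of bioanalytical validation: intraday
#' precision (replicate injections of one mixed standard in one day),
#' interday precision (daily batches on consecutive days), autosampler
#' stability (timed re-injections of one sample solution), repeatability
#' (independent sample preparations), and spike recovery (standard addition
#' at low/medium/high levels). Areas use the configuration's response and
#' noise model at a mid-ladder concentration; recovery simulates measurement
#' noise on the found amount.
#'
#' @param config A [generator_config()].
#' @param seed Seed (default `config$seed + 3`).
#' @return List of data frames: `intraday` (`analyte, area`), `interday`
#'   (`analyte, day, area`), `stability` (`analyte, hour, area`),
#'   `repeatability` (`analyte, prep, area`), `recovery` (`analyte, level,
#'   replicate, original, spiked, found` in ng).
#' @export
generate_validation_batches <- function(config, seed = config$seed + 3L) {
  stopifnot(inherits(config, "generator_config"))
  ana <- config$panel$analytes
  d <- config$design
  mid_conc <- function(i) {
    lv <- dilution_ladder(ana$calib_low[i], ana$calib_high[i],
                          config$n_levels)
    lv[ceiling(length(lv) / 2)]
  }
  area_at <- function(i, conc, n) {
    mu <- config$true_curves$slope[i] * conc + config$true_curves$intercept[i]
    noisy_area(rep(mu, n), rep(conc, n), config,
               top_mu = config$true_curves$slope[i] * ana$calib_high[i] +
                 config$true_curves$intercept[i],
               top_conc = ana$calib_high[i])
  }
  with_seed(seed, {
    intraday <- interday <- stability <- repeatability <- recov <- list()
    for (i in seq_len(nrow(ana))) {
      a <- ana$name[i]; cm <- mid_conc(i)
      intraday[[i]] <- data.frame(analyte = a,
                                  area = area_at(i, cm, d$intraday),
                                  stringsAsFactors = FALSE)
      interday[[i]] <- data.frame(
        analyte = a,
        day = rep(seq_len(d$interday_days), each = d$interday_inj),
        area = area_at(i, cm, d$interday_days * d$interday_inj),
        stringsAsFactors = FALSE)
      stability[[i]] <- data.frame(analyte = a, hour = d$stability_hours,
                                   area = area_at(i, cm,
                                                  length(d$stability_hours)),
                                   stringsAsFactors = FALSE)
      repeatability[[i]] <- data.frame(
        analyte = a, prep = seq_len(d$repeatability),
        area = area_at(i, cm, d$repeatability), stringsAsFactors = FALSE)
      # standard addition: original = working amount of the sample in 1 mL
      original <- unname(prep_to_working(config$true_sample_conc[1, a],
                                         config$panel$dilution))
      for (lev in names(d$recovery_levels)) {
        spiked <- unname(d$recovery_levels[[lev]]) * original
        found_true <- original + spiked
        found <- if (config$area_cv == 0) rep(found_true,
                                              d$recovery_replicates)
          else pmax(0, found_true *
                      (1 + stats::rnorm(d$recovery_replicates, 0,
                                        config$area_cv)))
        recov[[length(recov) + 1L]] <- data.frame(
          analyte = a, level = lev,
          replicate = seq_len(d$recovery_replicates),
          original = original, spiked = spiked, found = found,
          stringsAsFactors = FALSE)
      }
    }
    list(intraday = do.call(rbind, intraday),
         interday = do.call(rbind, interday),
         stability = do.call(rbind, stability),
         repeatability = do.call(rbind, repeatability),
         recovery = do.call(rbind, recov))
  })
}
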