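#' Relative correction factor by the averaging (AVG) estimator
#'
#' Within the linear range the response of analyte k is A_k = f_k * C_k, so
#' each injection of a mixed standard yields a response factor
#' f_k = A_k / C_k. The relative correction factor of k against the internal
#' reference standard s is the ratio of response factors observed in the
#' same run,
#' `f_ks = (A_k / C_k) / (A_s / C_s)`.
#' The AVG estimator computes this ratio for every run the two analytes
#' share (matched by `run_id`, as in a mixed-standard dilution series) and
#' returns its arithmetic mean and sample standard deviation across runs —
#' the "mean +/- SD" presentation. The alternative of averaging f_k and f_s
#' separately before dividing yields no dispersion estimate and is not used.
#'
#' @param series_k Standard-role peak rows of the analyte: a data frame with
#'   columns `run_id`, `area`, `nominal_conc_ng_ml` (a peak-table subset).
#' @param series_s The same for the internal reference standard.
#' @return List: `mean`, `sd` (sample SD; NA when only one matched run),
#'   `n` matched runs, `ratios` (named by run_id).
#' @export
rcf_avg <- function(series_k, series_s) {
  need <- c("run_id", "area", "nominal_conc_ng_ml")
  for (nm in c("series_k", "series_s")) {
    s <- get(nm)
    if (!is.data.frame(s) || !all(need %in% names(s)))
      stop("'", nm, "' must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
  }
  runs <- intersect(series_k$run_id, series_s$run_id)
  if (!length(runs))
    stop("no runs shared between analyte and IRS series", call. = FALSE)
  ik <- match(runs, series_k$run_id)
  is <- match(runs, series_s$run_id)
  if (any(series_s$area[is] == 0))
    stop("zero IRS area in run '",
         runs[which(series_s$area[is] == 0)[1]], "'", call. = FALSE)
  if (any(series_k$nominal_conc_ng_ml[ik] <= 0) ||
      any(series_s$nominal_conc_ng_ml[is] <= 0))
    stop("nominal concentrations must be positive", call. = FALSE)
  fk <- series_k$area[ik] / series_k$nominal_conc_ng_ml[ik]
  fs <- series_s$area[is] / series_s$nominal_conc_ng_ml[is]
  ratios <- stats::setNames(fk / fs, runs)
  list(mean = mean(ratios),
       sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
       n = length(ratios), ratios = ratios)
}

#' Relative correction factor by the linear-regression (LRG) estimator
#'
#' The LRG estimator is the ratio of calibration-curve slopes,
#' `f_ks = a_k / a_s`. It uses the whole weighted fit of each dilution
#' series rather than per-level ratios, which makes it less sensitive to a
#' single deviant level than the AVG estimator.
#'
#' @param curve_k Calibration slope of the analyte (numeric), or a
#'   `qams_curve`.
#' @param curve_s The same for the internal reference standard.
#' @return The relative correction factor `a_k / a_s` (full precision;
#'   round only for reporting).
#' @examples
#' rcf_lrg(7449.48, 616.17)   # 12.09 at 2 dp
#' @export
rcf_lrg <- function(curve_k, curve_s) {
  a_k <- if (inherits(curve_k, "qams_curve")) curve_k$slope else curve_k
  a_s <- if (inherits(curve_s, "qams_curve")) curve_s$slope else curve_s
  if (!is.numeric(a_k) || !is.numeric(a_s))
    stop("slopes must be numeric", call. = FALSE)
  if (any(a_s == 0)) stop("IRS slope is zero", call. = FALSE)
  a_k / a_s
}

#' Relative retention time
#'
#' `t_ks = t_k / t_s`: the analyte's retention time as a fraction of the
#' internal reference standard's. Used to position peaks when no reference
#' substance for the analyte is at hand.
#'
#' @param t_k,t_s Retention times in minutes, both positive. Vectorised over
#'   `t_k`.
#' @return `t_k / t_s`, dimensionless.
#' @examples
#' relative_retention(1.54, 6.16)   # 0.25
#' @export
relative_retention <- function(t_k, t_s) {
  if (any(t_k <= 0) || any(t_s <= 0))
    stop("retention times must be positive", call. = FALSE)
  t_k / t_s
}

#' Single-marker quantification, AVG path
#'
#' Quantifies an analyte from its sample peak area using only the internal
#' reference standard's contemporaneous injection:
#' `C_K = n * (1/f_ks) * C_s * A_K / A_s`,
#' where `n` is the dilution factor, `C_s`/`A_s` the nominal concentration
#' and area of an IRS standard injected in the same batch, and `A_K` the
#' analyte's sample area. The result is converted to mg/mL in the undiluted
#' preparation ([working_to_prep()]).
#'
#' @param area Sample peak area(s) `A_K`.
#' @param irs_conc IRS standard nominal concentration `C_s`, ng/mL.
#' @param irs_area IRS standard peak area `A_s` (> 0).
#' @param f_ks Relative correction factor (> 0), e.g. from [rcf_avg()].
#' @param dilution Dilution factor `n`, or an [analyte_panel()].
#' @return Preparation concentration(s), mg/mL.
#' @export
quantify_qams_avg <- function(area, irs_conc, irs_area, f_ks, dilution) {
  if (any(irs_area <= 0)) stop("IRS area must be positive", call. = FALSE)
  if (any(f_ks <= 0)) stop("f_ks must be positive", call. = FALSE)
  working <- (1 / f_ks) * irs_conc * area / irs_area
  working_to_prep(working, dilution)
}

#' Single-marker quantification, LRG path
#'
#' `C_K = n * (1/f_ks) * A_K / a_s`, where `a_s` is the IRS calibration
#' slope. Note the equation deliberately carries no intercept: with
#' `f_ks = a_k / a_s` it reduces to `n * A_K / a_k`, so in noise-free data
#' the only discrepancy against the external-standard path is the analyte's
#' own neglected intercept.
#'
#' @param area Sample peak area(s) `A_K`.
#' @param irs_slope IRS calibration slope `a_s` (non-zero), or a
#'   `qams_curve`.
#' @param f_ks Relative correction factor (> 0), e.g. from [rcf_lrg()].
#' @param dilution Dilution factor `n`, or an [analyte_panel()].
#' @return Preparation concentration(s), mg/mL.
#' @export
quantify_qams_lrg <- function(area, irs_slope, f_ks, dilution) {
  if (inherits(irs_slope, "qams_curve")) irs_slope <- irs_slope$slope
  if (any(irs_slope == 0)) stop("IRS slope is zero", call. = FALSE)
  if (any(f_ks <= 0)) stop("f_ks must be positive", call. = FALSE)
  working <- area / (f_ks * irs_slope)
  working_to_prep(working, dilution)
}

#' Contemporaneous IRS reference injection
#'
#' The AVG quantification path (see [quantify_qams_avg()]) needs a same-batch
#' injection of the IRS reference at known concentration. By default the top
#' calibration level of the IRS is used, with the area averaged over its
#' replicate injections (best signal-to-noise).
#'
#' @param peaks Peak-table data frame containing IRS `standard` rows.
#' @param panel An [analyte_panel()] (names the IRS), or the IRS name.
#' @param level `"top"` (default), `"bottom"`, or a numeric nominal
#'   concentration present in the table.
#' @return List with `conc` (ng/mL) and `area`.
#' @export
irs_reference <- function(peaks, panel, level = "top") {
  irs <- if (inherits(panel, "analyte_panel")) panel$irs else panel
  std <- peaks[peaks$role == "standard" & peaks$analyte == irs, ]
  if (!nrow(std)) stop("no IRS standard injections found", call. = FALSE)
  conc <- if (identical(level, "top")) max(std$nominal_conc_ng_ml)
          else if (identical(level, "bottom")) min(std$nominal_conc_ng_ml)
          else level
  sel <- std[std$nominal_conc_ng_ml == conc, ]
  if (!nrow(sel))
    stop("no IRS standard at concentration ", conc, call. = FALSE)
  list(conc = conc, area = mean(sel$area))
}

#' Relative correction factor and RRT table
#'
#' Builds the per-analyte summary of both RCF estimators and the relative
#' retention time against the IRS, from a calibration batch: for each
#' analyte, AVG mean +/- SD (per-run response-factor ratios), the LRG slope
#' ratio, and the RRT (mean standard-run retention time over the IRS's).
#' For the IRS itself all three values are exactly 1. All values are kept at
#' full precision; round only when reporting.
#'
#' @param peaks Peak-table data frame with the calibration batch
#'   (`standard` rows for every panel analyte).
#' @param curves `qams_curves` from [fit_calibration()].
#' @param panel An [analyte_panel()].
#' @return Data frame `analyte, avg_mean, avg_sd, lrg, rrt` in panel order.
#' @export
rcf_table <- function(peaks, curves, panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  peaks <- validate_peak_table(peaks, panel)
  std <- peaks[peaks$role == "standard", ]
  irs <- panel$irs
  s_rows <- std[std$analyte == irs, ]
  if (!nrow(s_rows)) stop("no IRS standards in batch", call. = FALSE)
  a_s <- curves$slope[match(irs, curves$analyte)]
  if (is.na(a_s)) stop("no IRS calibration curve", call. = FALSE)
  t_s <- mean(s_rows$rt_min)
  rows <- lapply(panel$analytes$name, function(a) {
    if (a == irs)
      return(data.frame(analyte = a, avg_mean = 1, avg_sd = 0, lrg = 1,
                        rrt = 1, stringsAsFactors = FALSE))
    k_rows <- std[std$analyte == a, ]
    if (!nrow(k_rows)) stop("no standards for '", a, "'", call. = FALSE)
    avg <- rcf_avg(k_rows, s_rows)
    a_k <- curves$slope[match(a, curves$analyte)]
    if (is.na(a_k)) stop("no calibration curve for '", a, "'", call. = FALSE)
    data.frame(analyte = a, avg_mean = avg$mean, avg_sd = avg$sd,
               lrg = rcf_lrg(a_k, a_s),
               rrt = relative_retention(mean(k_rows$rt_min), t_s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standard method difference (SMD)
#'
#' Percent deviation of a QAMS-derived concentration from the
#' external-standard concentration:
#' `SMD = |C_ES - C_QAMS| / C_ES * 100`.
#' The absolute value is the reported convention; set `signed = TRUE` for
#' the raw signed deviation (positive when QAMS under-reads), useful for
#' bias diagnostics. SMD is scale-invariant, so it may be computed in
#' working or preparation units interchangeably.
#'
#' @param c_es External-standard concentration(s), > 0.
#' @param c_qams QAMS concentration(s), same units.
#' @param signed If `TRUE`, return the signed deviation.
#' @return Percent deviation(s).
#' @export
smd <- function(c_es, c_qams, signed = FALSE) {
  if (any(c_es <= 0))
    stop("external-standard concentration must be positive", call. = FALSE)
  d <- (c_es - c_qams) / c_es * 100
  if (signed) d else abs(d)
}

#' Position chromatographic peaks by RRT and transition identity
#'
#' With only the IRS reference substance at hand, analyte peaks are located
#' by their relative retention time combined with the identity of the MRM
#' transition. A candidate peak is assigned to analyte k when its RRT
#' (`rt / irs_rt`) lies within `rrt_tol` (relative) of the expected `t_ks`
#' AND, if the peak carries m/z values, its precursor and product m/z match
#' the panel transition within `mz_tol`. For analytes flagged RRT-unstable
#' (retention drifts strongly with flow rate or column, typically early
#' eluters) the m/z match is mandatory and the RRT window widens to
#' `rrt_tol_unstable`.
#'
#' @param observed Data frame of candidate peaks: columns `rt_min` and
#'   optionally `peak_id`, `precursor_mz`, `product_mz`.
#' @param panel An [analyte_panel()].
#' @param irs_rt Retention time of the directly identified IRS peak, min.
#' @param rrt_table Named numeric vector of expected `t_ks` per analyte
#'   (e.g. the `rrt` column of [rcf_table()]); defaults to
#'   `expected_rt_min / IRS expected RT` from the panel.
#' @param rrt_tol Relative RRT tolerance (default 0.05).
#' @param mz_tol m/z tolerance in Da (default 0.5, unit-resolution triple
#'   quadrupole).
#' @param unstable Character vector of RRT-unstable analyte names.
#' @param rrt_tol_unstable Widened RRT tolerance for unstable analytes
#'   (default 0.35, sized for retention shifts of the order seen across
#'   column geometries).
#' @return List with data frames `assigned` (`peak_id, analyte, rrt,
#'   rrt_dev`), `ambiguous` (peaks matching several analytes), and
#'   `unassigned` (peaks matching none); plus `missing`, the analytes with
#'   no assigned peak.
#' @export
position_peaks <- function(observed, panel, irs_rt, rrt_table = NULL,
                           rrt_tol = 0.05, mz_tol = 0.5,
                           unstable = character(), rrt_tol_unstable = 0.35) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (!is.numeric(irs_rt) || length(irs_rt) != 1L || irs_rt <= 0)
    stop("no valid IRS retention time supplied", call. = FALSE)
  ana <- panel$analytes
  if (is.null(rrt_table))
    rrt_table <- stats::setNames(
      ana$expected_rt_min / ana$expected_rt_min[ana$name == panel$irs],
      ana$name)
  empty <- data.frame(peak_id = character(), analyte = character(),
                      rrt = numeric(), rrt_dev = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(observed) || !nrow(observed)) {
    warning("empty peak list: nothing to position")
    return(list(assigned = empty, ambiguous = empty, unassigned = empty,
                missing = ana$name))
  }
  if (is.null(observed$peak_id))
    observed$peak_id <- sprintf("peak_%02d", seq_len(nrow(observed)))
  has_mz <- all(c("precursor_mz", "product_mz") %in% names(observed))
  rows <- list()
  for (i in seq_len(nrow(observed))) {
    rrt <- observed$rt_min[i] / irs_rt
    for (a in ana$name) {
      tks <- rrt_table[[a]]
      if (is.null(tks) || is.na(tks)) next
      tol <- if (a %in% unstable) rrt_tol_unstable else rrt_tol
      dev <- abs(rrt - tks) / tks
      rrt_ok <- dev <= tol
      mz_ok <- if (has_mz) {
        j <- match(a, ana$name)
        abs(observed$precursor_mz[i] - ana$precursor_mz[j]) <= mz_tol &&
          abs(observed$product_mz[i] - ana$product_mz[j]) <= mz_tol
      } else NA
      ok <- if (a %in% unstable) {
        # m/z confirmation is mandatory for RRT-unstable analytes
        isTRUE(mz_ok) && rrt_ok
      } else {
        rrt_ok && !isFALSE(mz_ok)
      }
      if (ok)
        rows[[length(rows) + 1L]] <-
          data.frame(peak_id = observed$peak_id[i], analyte = a, rrt = rrt,
                     rrt_dev = dev, stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else empty
  n_match <- table(factor(matches$peak_id, levels = observed$peak_id))
  uniq <- names(n_match)[n_match == 1L]
  assigned <- matches[matches$peak_id %in% uniq, ]
  ambiguous <- matches[!matches$peak_id %in% uniq, ]
  unassigned_ids <- names(n_match)[n_match == 0L]
  unassigned <- data.frame(
    peak_id = unassigned_ids,
    analyte = rep(NA_character_, length(unassigned_ids)),
    rrt = observed$rt_min[match(unassigned_ids, observed$peak_id)] / irs_rt,
    rrt_dev = rep(NA_real_, length(unassigned_ids)),
    stringsAsFactors = FALSE)
  list(assigned = assigned, ambiguous = ambiguous, unassigned = unassigned,
       missing = setdiff(ana$name, assigned$analyte))
}

#' Quantify sample peaks by ESM or either QAMS path
#'
#' Convenience wrapper running one quantification method over every
#' `sample`-role row of a peak table, producing the tidy result layout
#' shared by the comparison tools.
#'
#' @param peaks Peak-table data frame (samples plus, for the AVG path, the
#'   batch's IRS standard injections unless `irs_standard` is supplied).
#' @param panel An [analyte_panel()].
#' @param curves `qams_curves` from [fit_calibration()].
#' @param rcf RCF table from [rcf_table()] (ignored for ESM).
#' @param method `"ESM"`, `"QAMS_AVG"` or `"QAMS_LRG"`.
#' @param irs_standard Optional list `(conc, area)` of the contemporaneous
#'   IRS injection; default [irs_reference()] on `peaks`.
#' @return Data frame `sample_id, analyte, method, conc_mg_ml, flag`.
#' @export
quantify_samples <- function(peaks, panel, curves, rcf = NULL,
                             method = c("ESM", "QAMS_AVG", "QAMS_LRG"),
                             irs_standard = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "analyte_panel"))
  if (method == "ESM") return(quantify_esm(peaks, curves, panel))
  if (is.null(rcf)) stop("QAMS methods need an RCF table", call. = FALSE)
  peaks <- validate_peak_table(peaks, panel)
  smp <- peaks[peaks$role == "sample", ]
  if (!nrow(smp)) stop("no sample-role rows to quantify", call. = FALSE)
  f <- if (method == "QAMS_AVG") rcf$avg_mean else rcf$lrg
  f_ks <- f[match(smp$analyte, rcf$analyte)]
  if (anyNA(f_ks))
    stop("no RCF for analyte(s): ",
         paste(unique(smp$analyte[is.na(f_ks)]), collapse = ", "),
         call. = FALSE)
  if (method == "QAMS_AVG") {
    if (is.null(irs_standard)) irs_standard <- irs_reference(peaks, panel)
    conc <- quantify_qams_avg(smp$area, irs_standard$conc,
                              irs_standard$area, f_ks, panel)
  } else {
    a_s <- curves$slope[match(panel$irs, curves$analyte)]
    if (is.na(a_s)) stop("no IRS calibration curve", call. = FALSE)
    conc <- quantify_qams_lrg(smp$area, a_s, f_ks, panel)
  }
  working <- prep_to_working(conc, panel)
  pidx <- match(smp$analyte, panel$analytes$name)
  data.frame(sample_id = smp$run_id, analyte = smp$analyte, method = method,
             conc_mg_ml = conc,
             flag = flag_conc(working, panel$analytes$calib_low[pidx],
                              panel$analytes$calib_high[pidx]),
             stringsAsFactors = FALSE)
}

#' Screen every analyte as a candidate internal reference standard
#'
#' Any panel analyte can in principle serve as the IRS. For each candidate
#' the screen derives RCFs from the calibration batch (both estimators),
#' quantifies every other analyte in mixed-standard check solutions of known
#' composition through the QAMS paths, and scores the deviation from the
#' known concentrations as an SMD. Replicate determinations of the same
#' analyte are averaged (mean of per-run concentration ratios) before the
#' deviation is taken, so the per-analyte SMD reflects systematic deviation,
#' not injection noise. Candidates whose worst per-analyte SMD stays below
#' `threshold` are marked eligible; ranking is by mean SMD ascending (ties
#' alphabetical). The final choice remains the analyst's: cost, stability
#' and availability are not computable.
#'
#' @param cal_peaks Calibration batch peak table (standards for all
#'   analytes).
#' @param curves `qams_curves` fitted on `cal_peaks`.
#' @param check_peaks Peak table of mixed-standard check solutions:
#'   `standard`-role rows whose `nominal_conc_ng_ml` is the known truth.
#' @param panel An [analyte_panel()].
#' @param threshold Eligibility limit on the per-candidate max SMD, percent
#'   (default 5).
#' @return List: `summary` (data frame `candidate, estimator, max_smd,
#'   mean_smd, eligible, rank` — rank within estimator), `detail`
#'   (`candidate, estimator, analyte, smd`).
#' @export
select_irs <- function(cal_peaks, curves, check_peaks, panel, threshold = 5) {
  stopifnot(inherits(panel, "analyte_panel"))
  cal_peaks <- validate_peak_table(cal_peaks, panel)
  check_peaks <- validate_peak_table(check_peaks, panel)
  cal_std <- cal_peaks[cal_peaks$role == "standard", ]
  chk <- check_peaks[check_peaks$role == "standard", ]
  analytes <- panel$analytes$name
  if (!all(analytes %in% curves$analyte))
    stop("missing calibration curve for: ",
         paste(setdiff(analytes, curves$analyte), collapse = ", "),
         call. = FALSE)
  detail <- list()
  for (cand in analytes) {
    s_cal <- cal_std[cal_std$analyte == cand, ]
    a_s <- curves$slope[match(cand, curves$analyte)]
    s_chk <- chk[chk$analyte == cand, ]
    for (a in setdiff(analytes, cand)) {
      k_cal <- cal_std[cal_std$analyte == a, ]
      f_avg <- rcf_avg(k_cal, s_cal)$mean
      f_lrg <- rcf_lrg(curves$slope[match(a, curves$analyte)], a_s)
      k_chk <- chk[chk$analyte == a, ]
      runs <- intersect(k_chk$run_id, s_chk$run_id)
      if (!length(runs))
        stop("no shared check runs for '", a, "' and '", cand, "'",
             call. = FALSE)
      ik <- match(runs, k_chk$run_id); is <- match(runs, s_chk$run_id)
      truth <- k_chk$nominal_conc_ng_ml[ik]
      # AVG path: IRS truth + area from the same check run
      c_avg <- (1 / f_avg) * s_chk$nominal_conc_ng_ml[is] *
        k_chk$area[ik] / s_chk$area[is]
      c_lrg <- k_chk$area[ik] / (f_lrg * a_s)
      detail[[length(detail) + 1L]] <- data.frame(
        candidate = cand, estimator = c("AVG", "LRG"), analyte = a,
        smd = c(smd(1, mean(c_avg / truth)), smd(1, mean(c_lrg / truth))),
        stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  summ <- do.call(rbind, lapply(split(detail,
                                      detail[c("candidate", "estimator")]),
    function(d) data.frame(candidate = d$candidate[1],
                           estimator = d$estimator[1],
                           max_smd = max(d$smd), mean_smd = mean(d$smd),
                           stringsAsFactors = FALSE)))
  summ$eligible <- summ$max_smd < threshold
  # rank by mean SMD ascending within estimator, ties alphabetical
  summ <- summ[order(summ$estimator, summ$mean_smd, summ$candidate), ]
  summ$rank <- stats::ave(summ$mean_smd, summ$estimator,
                          FUN = seq_along)
  rownames(summ) <- NULL
  list(summary = summ, detail = detail)
}
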