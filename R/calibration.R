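#' Weighted least-squares calibration line
#'
#' Fits `area = slope * conc + intercept` by weighted least squares. The
#' default weighting is 1/x (weight = 1/concentration), the common
#' bioanalytical choice when response variance grows with concentration.
#' The solution is the exact closed form (via `stats::lm`); nothing is
#' fitted iteratively. Replicate injections at a level enter as separate
#' weighted points.
#'
#' The reported correlation `r` is the weighted Pearson correlation
#' (weighted covariance over weighted standard deviations), consistent with
#' the fit; the ordinary unweighted Pearson `r` is also returned. The two
#' coincide when all weights are equal.
#'
#' @param conc Nominal concentrations, ng/mL (>= 3 distinct positive values).
#' @param area Integrated peak areas (same length as `conc`).
#' @param weighting `"1/x"` (default), `"none"`, or `"1/x2"`.
#' @return A list of class `qams_curve`: `slope`, `intercept`, `r`
#'   (weighted), `r_unweighted`, `n_points`, `weighting`.
#' @examples
#' fit_weighted_line(c(1, 2, 4), c(3, 5, 9))   # exact line y = 2x + 1
#' @export
fit_weighted_line <- function(conc, area, weighting = c("1/x", "none", "1/x2")) {
  weighting <- match.arg(weighting)
  if (length(conc) != length(area))
    stop("'conc' and 'area' must have the same length", call. = FALSE)
  if (!all(is.finite(conc)) || !all(is.finite(area)))
    stop("concentrations and areas must be finite", call. = FALSE)
  if (weighting != "none" && any(conc <= 0))
    stop("1/x-type weighting requires positive concentrations", call. = FALSE)
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  w <- switch(weighting,
              "1/x" = 1 / conc,
              "none" = rep(1, length(conc)),
              "1/x2" = 1 / conc^2)
  fit <- stats::lm(area ~ conc, weights = w)
  cf <- stats::coef(fit)
  # weighted Pearson r about the weighted means
  mx <- sum(w * conc) / sum(w)
  my <- sum(w * area) / sum(w)
  sxy <- sum(w * (conc - mx) * (area - my))
  sxx <- sum(w * (conc - mx)^2)
  syy <- sum(w * (area - my)^2)
  r_w <- if (syy == 0) 1 else sxy / sqrt(sxx * syy)
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         r = r_w, r_unweighted = stats::cor(conc, area),
         n_points = length(conc), weighting = weighting),
    class = "qams_curve"
  )
}

#' @export
print.qams_curve <- function(x, ...) {
  cat(sprintf("calibration line: y = %.6g x + %.6g  (r = %.6f, n = %d, w = %s)\n",
              x$slope, x$intercept, x$r, x$n_points, x$weighting))
  invisible(x)
}

#' Fit calibration curves for a whole panel
#'
#' Extracts the `standard`-role rows of a peak table and fits one weighted
#' calibration line per analyte. The output mirrors the usual linear
#' regression summary table of a validated assay: one row per analyte with
#' slope, intercept, correlation and point count.
#'
#' @param peaks Peak-table data frame (see [peak-table]).
#' @param panel Optional [analyte_panel()]; if given, curves are fitted for
#'   (and restricted to) the panel's analytes, in panel order.
#' @inheritParams fit_weighted_line
#' @return A data frame of class `qams_curves`: columns `analyte, slope,
#'   intercept, r, r_unweighted, n_points`.
#' @export
fit_calibration <- function(peaks, panel = NULL,
                            weighting = c("1/x", "none", "1/x2")) {
  weighting <- match.arg(weighting)
  peaks <- validate_peak_table(peaks, panel)
  std <- peaks[peaks$role == "standard", ]
  if (!nrow(std)) stop("no standard-role rows in peak table", call. = FALSE)
  analytes <- if (is.null(panel)) unique(std$analyte) else panel$analytes$name
  rows <- lapply(analytes, function(a) {
    s <- std[std$analyte == a, ]
    if (nrow(s) < 3L)
      stop("analyte '", a, "' has fewer than 3 calibration points",
           call. = FALSE)
    fit <- fit_weighted_line(s$nominal_conc_ng_ml, s$area, weighting)
    data.frame(analyte = a, slope = fit$slope, intercept = fit$intercept,
               r = fit$r, r_unweighted = fit$r_unweighted,
               n_points = fit$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qams_curves", "data.frame")
  out
}

#' Linearity check
#'
#' Flags calibration curves whose correlation coefficient falls at or below
#' the acceptance threshold (default r > 0.9990).
#'
#' @param curves A `qams_curves` data frame from [fit_calibration()], or a
#'   single `qams_curve`.
#' @param threshold Minimum acceptable correlation (exclusive).
#' @return Data frame `analyte, r, threshold, margin, pass`; `margin` is
#'   `r - threshold`.
#' @export
check_linearity <- function(curves, threshold = 0.9990) {
  if (inherits(curves, "qams_curve"))
    curves <- data.frame(analyte = NA_character_, r = curves$r)
  data.frame(analyte = curves$analyte, r = curves$r, threshold = threshold,
             margin = curves$r - threshold, pass = curves$r > threshold,
             stringsAsFactors = FALSE)
}

#' Back-calculate a working concentration from a calibration line
#'
#' @param area Peak area(s).
#' @param slope,intercept Calibration line coefficients; `slope` must be
#'   non-zero.
#' @return Working concentration(s), ng/mL (may be negative; callers flag,
#'   never clamp).
#' @export
invert_curve <- function(area, slope, intercept) {
  if (any(slope == 0)) stop("calibration slope is zero", call. = FALSE)
  (area - intercept) / slope
}

# flag a back-calculated working concentration against a calibration range;
# low/high may be per-element vectors
flag_conc <- function(conc_ng_ml, low = NA_real_, high = NA_real_) {
  n <- length(conc_ng_ml)
  low <- rep_len(low, n)
  high <- rep_len(high, n)
  flag <- rep("ok", n)
  flag[conc_ng_ml <= 0] <- "nonpositive"
  sel <- flag == "ok" & !is.na(low) & conc_ng_ml < low
  flag[sel] <- "below_range"
  sel <- flag == "ok" & !is.na(high) & conc_ng_ml > high
  flag[sel] <- "above_range"
  flag
}

#' External-standard quantification (ESM)
#'
#' Quantifies `sample`-role peaks against each analyte's own calibration
#' curve: working concentration `(area - intercept) / slope`, then converted
#' to mg/mL in the undiluted preparation via [working_to_prep()]. Negative
#' or out-of-range back-calculations are flagged, never clamped.
#'
#' @param peaks Peak-table data frame; only `sample` rows are quantified.
#' @param curves `qams_curves` from [fit_calibration()].
#' @param panel An [analyte_panel()] (supplies dilution and calibration
#'   ranges), or a bare dilution factor.
#' @return Data frame `sample_id, analyte, method, conc_mg_ml, flag` with
#'   `method = "ESM"`.
#' @export
quantify_esm <- function(peaks, curves, panel) {
  peaks <- validate_peak_table(peaks)
  smp <- peaks[peaks$role == "sample", ]
  if (!nrow(smp)) stop("no sample-role rows to quantify", call. = FALSE)
  dilution <- if (inherits(panel, "analyte_panel")) panel$dilution else panel
  idx <- match(smp$analyte, curves$analyte)
  if (anyNA(idx))
    stop("no calibration curve for analyte(s): ",
         paste(unique(smp$analyte[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  working <- invert_curve(smp$area, curves$slope[idx], curves$intercept[idx])
  if (inherits(panel, "analyte_panel")) {
    pidx <- match(smp$analyte, panel$analytes$name)
    flag <- flag_conc(working, panel$analytes$calib_low[pidx],
                      panel$analytes$calib_high[pidx])
  } else {
    flag <- flag_conc(working)
  }
  data.frame(sample_id = smp$run_id, analyte = smp$analyte, method = "ESM",
             conc_mg_ml = working_to_prep(working, dilution), flag = flag,
             stringsAsFactors = FALSE)
}
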