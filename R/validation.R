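#' Relative standard deviation
#'
#' Sample standard deviation over the mean, in percent — the universal
#' dispersion metric of bioanalytical validation. Invariant to uniform
#' rescaling of the values.
#'
#' @param values Numeric vector (>= 2 values, positive mean).
#' @return RSD in percent.
#' @examples
#' rsd(c(9, 10, 11))   # 10
#' @export
rsd <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values for an RSD", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("RSD requires a positive mean", call. = FALSE)
  stats::sd(values) / m * 100
}

#' Spike recovery
#'
#' Standard-addition accuracy: `(found - original) / spiked * 100`.
#'
#' @param found Amount found in the spiked sample (ng). Vectorised.
#' @param original Amount in the unspiked sample (ng).
#' @param spiked Amount added (ng, > 0).
#' @return Recovery in percent.
#' @examples
#' recovery(15, 10, 5)   # 100
#' @export
recovery <- function(found, original, spiked) {
  if (any(spiked <= 0))
    stop("spiked amount must be positive", call. = FALSE)
  (found - original) / spiked * 100
}

#' Recovery report with acceptance band
#'
#' @param samples Data frame with columns `analyte`, `level`
#'   (low/medium/high), `found`, `original`, `spiked` (ng).
#' @param band Acceptable recovery range in percent (default 85–115).
#' @return Input plus `recovery_pct` and `acceptable` columns.
#' @export
recovery_report <- function(samples, band = c(85, 115)) {
  need <- c("analyte", "level", "found", "original", "spiked")
  if (!all(need %in% names(samples)))
    stop("recovery table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  samples$recovery_pct <- recovery(samples$found, samples$original,
                                   samples$spiked)
  samples$acceptable <- samples$recovery_pct >= band[1] &
    samples$recovery_pct <= band[2]
  samples
}

#' Intra- and interday precision
#'
#' Intraday precision is the RSD over replicate injections of one mixed
#' standard solution within a day (design default: six); interday precision
#' is the RSD over the daily mean areas across consecutive days (default:
#' three). A pooled RSD over all injections is also emitted for
#' transparency.
#'
#' @param intraday Data frame `analyte, area`: the single-day replicate
#'   injections.
#' @param interday Data frame `analyte, day, area`: the daily batches.
#' @param limit Acceptance limit in percent (default 5).
#' @return Data frame `analyte, intraday_rsd, interday_rsd, pooled_rsd,
#'   limit_pct, pass`.
#' @export
precision_report <- function(intraday, interday, limit = 5) {
  if (!all(c("analyte", "area") %in% names(intraday)))
    stop("'intraday' needs columns analyte, area", call. = FALSE)
  if (!all(c("analyte", "day", "area") %in% names(interday)))
    stop("'interday' needs columns analyte, day, area", call. = FALSE)
  analytes <- unique(c(intraday$analyte, interday$analyte))
  rows <- lapply(analytes, function(a) {
    intra <- intraday$area[intraday$analyte == a]
    inter <- interday[interday$analyte == a, ]
    if (length(intra) < 2L || !nrow(inter))
      stop("missing replicates for '", a, "'", call. = FALSE)
    daily_means <- tapply(inter$area, inter$day, mean)
    if (length(daily_means) < 2L)
      stop("interday design for '", a, "' has fewer than 2 days",
           call. = FALSE)
    data.frame(analyte = a,
               intraday_rsd = rsd(intra),
               interday_rsd = rsd(as.numeric(daily_means)),
               pooled_rsd = rsd(inter$area),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$limit_pct <- limit
  out$pass <- out$intraday_rsd < limit & out$interday_rsd < limit
  out
}

#' Autosampler stability
#'
#' RSD of the peak areas of each analyte across the timed re-injections of
#' one sample solution (design default: 0–12 h every 2 h).
#'
#' @param timepoints Data frame `analyte, hour, area`; hours must be unique
#'   and increasing per analyte.
#' @param limit Acceptance limit in percent (default 5).
#' @return Data frame `analyte, rsd_pct, n_timepoints, limit_pct, pass`.
#' @export
stability_report <- function(timepoints, limit = 5) {
  if (!all(c("analyte", "hour", "area") %in% names(timepoints)))
    stop("'timepoints' needs columns analyte, hour, area", call. = FALSE)
  rows <- lapply(unique(timepoints$analyte), function(a) {
    d <- timepoints[timepoints$analyte == a, ]
    if (nrow(d) < 2L)
      stop("fewer than 2 timepoints for '", a, "'", call. = FALSE)
    if (anyDuplicated(d$hour) || is.unsorted(d$hour))
      stop("timepoints for '", a, "' must be unique and increasing",
           call. = FALSE)
    data.frame(analyte = a, rsd_pct = rsd(d$area), n_timepoints = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$limit_pct <- limit
  out$pass <- out$rsd_pct < limit
  out
}

#' Repeatability across independent sample preparations
#'
#' RSD of the peak areas of each analyte across independently prepared
#' sample solutions (design default: six preparations).
#'
#' @param preparations Data frame `analyte, prep, area`.
#' @param limit Acceptance limit in percent (default 6).
#' @return Data frame `analyte, rsd_pct, n_preps, limit_pct, pass`.
#' @export
repeatability_report <- function(preparations, limit = 6) {
  if (!all(c("analyte", "prep", "area") %in% names(preparations)))
    stop("'preparations' needs columns analyte, prep, area", call. = FALSE)
  rows <- lapply(unique(preparations$analyte), function(a) {
    d <- preparations[preparations$analyte == a, ]
    if (nrow(d) < 2L)
      stop("fewer than 2 preparations for '", a, "'", call. = FALSE)
    data.frame(analyte = a, rsd_pct = rsd(d$area), n_preps = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$limit_pct <- limit
  out$pass <- out$rsd_pct < limit
  out
}

#' Robustness of RCFs and RRT across chromatographic conditions
#'
#' Recomputes the AVG relative correction factors and the relative retention
#' times under every condition (flow rate, column temperature, column
#' geometry, ...) and summarises their dispersion as an RSD per analyte.
#' RCFs passing `rcf_limit` are fit for quantification under condition
#' changes; analytes whose RRT RSD exceeds `rrt_limit` are classified
#' "RRT-insufficient — require m/z confirmation" (their peaks cannot be
#' positioned by RRT alone) and should be passed as `unstable` to
#' [position_peaks()]. Classifications do not depend on the order of the
#' conditions.
#'
#' @param conditions List of conditions, each a list with `label` (text) and
#'   `peaks` (a complete calibration batch acquired under that condition).
#' @param panel An [analyte_panel()] (same panel across all conditions).
#' @param rcf_limit,rrt_limit RSD limits in percent (defaults 5 and 5).
#' @return Data frame `analyte, rcf_rsd, rcf_pass, rrt_rsd, rrt_class` for
#'   the non-IRS analytes.
#' @export
robustness_report <- function(conditions, panel, rcf_limit = 5,
                              rrt_limit = 5) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (length(conditions) < 2L)
    stop("need at least 2 conditions", call. = FALSE)
  per_cond <- lapply(conditions, function(cond) {
    if (is.null(cond$peaks))
      stop("each condition needs a 'peaks' element", call. = FALSE)
    pk <- validate_peak_table(cond$peaks, panel)
    std <- pk[pk$role == "standard", ]
    if (!setequal(unique(std$analyte), panel$analytes$name))
      stop("condition '", cond$label,
           "' does not cover the full panel", call. = FALSE)
    curves <- fit_calibration(pk, panel)
    rcf_table(pk, curves, panel)
  })
  others <- setdiff(panel$analytes$name, panel$irs)
  rows <- lapply(others, function(a) {
    rcfs <- vapply(per_cond, function(tb) tb$avg_mean[tb$analyte == a],
                   numeric(1))
    rrts <- vapply(per_cond, function(tb) tb$rrt[tb$analyte == a],
                   numeric(1))
    data.frame(analyte = a, rcf_rsd = rsd(rcfs), rrt_rsd = rsd(rrts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rcf_pass <- out$rcf_rsd < rcf_limit
  out$rrt_class <- ifelse(out$rrt_rsd <= rrt_limit, "RRT-sufficient",
                          "RRT-insufficient - require m/z confirmation")
  out[, c("analyte", "rcf_rsd", "rcf_pass", "rrt_rsd", "rrt_class")]
}

# two-sample variance-ratio F test, larger variance in the numerator,
# two-sided p
variance_ratio_test <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx >= vy) {
    f <- if (vy == 0) ifelse(vx == 0, 1, Inf) else vx / vy
    df1 <- length(x) - 1L; df2 <- length(y) - 1L
  } else {
    f <- vy / vx
    df1 <- length(y) - 1L; df2 <- length(x) - 1L
  }
  p <- if (is.infinite(f)) 0 else min(1, 2 * stats::pf(f, df1, df2,
                                                       lower.tail = FALSE))
  list(f = f, p = p, df1 = df1, df2 = df2)
}

#' Compare external-standard and QAMS quantification
#'
#' Pairs the two result sets on sample x analyte, computes the per-row
#' standard method difference ([smd()]), and tests per analyte whether the
#' two methods disperse alike with a two-sample variance-ratio F test
#' (larger variance in the numerator, two-sided p). A one-way ANOVA across
#' methods and an optional paired t-test on the means are reported as
#' complementary readings. The per-analyte verdict is "consistent" when the
#' F-test p-value exceeds `alpha` and the largest SMD stays below
#' `smd_limit`.
#'
#' @param esm,qams Quantification results in the layout of
#'   [quantify_samples()] (`sample_id, analyte, conc_mg_ml`), covering the
#'   same sample x analyte grid.
#' @param smd_limit Largest tolerated SMD in percent (default 10).
#' @param alpha Significance level for the F test (default 0.05).
#' @param paired_t If `TRUE`, add a paired t-test p-value per analyte — an
#'   interpretation of "significance of means", not part of the primary
#'   F-test reading.
#' @return List: `rows` (per sample x analyte: `analyte, sample_id, c_es,
#'   c_qams, smd`), `by_analyte` (`analyte, f_statistic, p_value, anova_p,
#'   [t_p,] max_smd, mean_smd, verdict`), `verdict` (overall).
#' @export
compare_methods <- function(esm, qams, smd_limit = 10, alpha = 0.05,
                            paired_t = FALSE) {
  need <- c("sample_id", "analyte", "conc_mg_ml")
  if (!all(need %in% names(esm)) || !all(need %in% names(qams)))
    stop("result sets need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key_e <- paste(esm$sample_id, esm$analyte, sep = "\r")
  key_q <- paste(qams$sample_id, qams$analyte, sep = "\r")
  if (!setequal(key_e, key_q) || anyDuplicated(key_e) || anyDuplicated(key_q))
    stop("sample x analyte grids of the two methods do not match",
         call. = FALSE)
  idx <- match(key_e, key_q)
  rows <- data.frame(analyte = esm$analyte, sample_id = esm$sample_id,
                     c_es = esm$conc_mg_ml, c_qams = qams$conc_mg_ml[idx],
                     stringsAsFactors = FALSE)
  rows$smd <- smd(rows$c_es, rows$c_qams)
  by_a <- lapply(split(rows, rows$analyte), function(d) {
    ft <- variance_ratio_test(d$c_es, d$c_qams)
    both <- data.frame(conc = c(d$c_es, d$c_qams),
                       method = rep(c("ESM", "QAMS"), each = nrow(d)))
    anova_p <- if (nrow(d) > 1L)
      stats::anova(stats::lm(conc ~ method, data = both))[["Pr(>F)"]][1]
    else NA_real_
    out <- data.frame(analyte = d$analyte[1], f_statistic = ft$f,
                      p_value = ft$p, anova_p = anova_p,
                      max_smd = max(d$smd), mean_smd = mean(d$smd),
                      stringsAsFactors = FALSE)
    if (paired_t)
      out$t_p <- if (nrow(d) > 1L && stats::sd(d$c_es - d$c_qams) > 0)
        stats::t.test(d$c_es, d$c_qams, paired = TRUE)$p.value else 1
    out$verdict <- if (ft$p > alpha && out$max_smd < smd_limit)
      "consistent" else "inconsistent"
    out
  })
  by_analyte <- do.call(rbind, by_a)
  rownames(by_analyte) <- NULL
  list(rows = rows, by_analyte = by_analyte,
       verdict = if (all(by_analyte$verdict == "consistent"))
         "consistent" else "inconsistent")
}
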