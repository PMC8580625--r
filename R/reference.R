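#' The eight-constituent pneumonia-mixture panel
#'
#' The built-in example panel: eight index constituents of a hospital
#' pneumonia mixture (a multi-herb preparation) assayed by UPLC-MS/MS in
#' MRM mode, with baicalein as the internal reference standard and a 5000x
#' dilution of the preparation before injection. Retention times and
#' calibration ranges are the published assay values; the MRM transition
#' m/z values are nominal, literature-typical transitions carried as
#' configuration metadata for positioning demonstrations (the instrument's
#' optimised transitions are not part of this package). Ephedrine and
#' pseudoephedrine are diastereomers sharing a transition, so retention is
#' what separates them.
#'
#' Analyte names use comma-free identifiers: `goitrin` stands for
#' (R,S)-goitrin, `glycyrrhizinate` for ammonium glycyrrhizinate,
#' `pseudoephedrine`/`ephedrine` for the hydrochlorides.
#'
#' @return An [analyte_panel()] of eight analytes in elution order.
#' @export
pneumonia_panel <- function() {
  analyte_panel(rbind(
    analyte("goitrin",          130.1,  88.1, 1.54, 0.098,  100),
    analyte("ephedrine",        166.1, 148.1, 2.47, 0.032,  260),
    analyte("pseudoephedrine",  166.1, 148.1, 2.85, 0.056,  460),
    analyte("chlorogenic_acid", 355.1, 163.1, 3.96, 0.20,   840),
    analyte("amygdalin",        458.2, 296.1, 4.08, 1.56,  1600),
    analyte("baicalin",         447.1, 271.1, 5.49, 0.29,  2400),
    analyte("baicalein",        271.1, 123.0, 6.16, 1.82,   465),
    analyte("glycyrrhizinate",  823.4, 453.3, 6.86, 7.5,    480)
  ), irs = "baicalein", dilution = 5000)
}

#' Published reference values for the pneumonia-mixture assay
#'
#' The printed results of the validated eight-constituent assay, transcribed
#' for use as test oracles and generator truth: the weighted calibration
#' equations and correlation coefficients, the retention times, the relative
#' correction factors (both estimators) and relative retention times against
#' baicalein, and the determined contents of the preparation. No computation
#' happens here.
#'
#' The published RRT for glycyrrhizinate is 1.12 while the printed retention
#' times give 6.86 / 6.16 = 1.1136 (1.11 at 2 dp) — a rounding inconsistency
#' in the source, so full-precision retention-time ratios are authoritative
#' in this package and that single cell is not forced to agree.
#'
#' Published contents cover baicalein (external-standard only, as the IRS)
#' plus goitrin, amygdalin and chlorogenic acid; `assumed_contents` carries
#' plausible mid-range values for the remaining four analytes, used only as
#' synthetic-data defaults and clearly not measured values.
#'
#' @return A list: `panel` ([pneumonia_panel()]), `curves` (data frame
#'   `analyte, slope, intercept, r`), `retention_min` (named vector),
#'   `rcf` (data frame `analyte, avg_mean, avg_sd, lrg, rrt` against
#'   baicalein), `contents` (data frame `sample, analyte, esm_mg_ml,
#'   avg_mg_ml, smd_avg, lrg_mg_ml, smd_lrg`), `assumed_contents`
#'   (named vector, mg/mL, synthetic defaults).
#' @export
pneumonia_reference <- function() {
  curves <- data.frame(
    analyte = c("goitrin", "amygdalin", "chlorogenic_acid",
                "pseudoephedrine", "ephedrine", "glycyrrhizinate",
                "baicalein", "baicalin"),
    slope = c(7449.48, 380.53, 1152.30, 84605.00, 41945.40, 74.41,
              616.17, 888.61),
    intercept = c(168.691, 6102.67, 239.22, 7019.50, 3473.01, 73.66,
                  -146.83, 23186.00),
    r = c(0.9997, 0.9992, 0.9995, 0.9990, 0.9990, 0.9993, 0.9996, 0.9995),
    stringsAsFactors = FALSE)
  retention_min <- c(goitrin = 1.54, ephedrine = 2.47,
                     pseudoephedrine = 2.85, chlorogenic_acid = 3.96,
                     amygdalin = 4.08, baicalin = 5.49, baicalein = 6.16,
                     glycyrrhizinate = 6.86)
  rcf <- data.frame(
    analyte = c("goitrin", "amygdalin", "chlorogenic_acid",
                "pseudoephedrine", "ephedrine", "glycyrrhizinate",
                "baicalin"),
    avg_mean = c(12.98, 0.68, 1.98, 148.62, 73.69, 0.12, 1.60),
    avg_sd = c(0.86, 0.05, 0.10, 7.51, 1.82, 0.01, 0.10),
    lrg = c(12.09, 0.62, 1.87, 137.31, 68.07, 0.12, 1.44),
    rrt = c(0.25, 0.66, 0.64, 0.46, 0.40, 1.12, 0.89),
    stringsAsFactors = FALSE)
  esm <- list(
    baicalein = c(0.47, 0.44, 0.45, 0.42, 0.45, 0.43),
    goitrin = c(0.0045, 0.0040, 0.0040, 0.0040, 0.0045, 0.0040),
    amygdalin = c(7.41, 7.46, 7.45, 7.20, 7.31, 7.17),
    chlorogenic_acid = c(2.02, 2.07, 2.10, 1.99, 2.09, 1.98))
  contents <- rbind(
    data.frame(sample = 1:6, analyte = "baicalein",
               esm_mg_ml = esm$baicalein, avg_mg_ml = NA_real_,
               smd_avg = NA_real_, lrg_mg_ml = NA_real_,
               smd_lrg = NA_real_, stringsAsFactors = FALSE),
    data.frame(sample = 1:6, analyte = "goitrin", esm_mg_ml = esm$goitrin,
               avg_mg_ml = c(0.0043, 0.0042, 0.0041, 0.0042, 0.0044, 0.0040),
               smd_avg = c(3.81, 4.59, 3.41, 4.37, 1.65, 0.36),
               lrg_mg_ml = c(0.0045, 0.0044, 0.0043, 0.0044, 0.0046, 0.0042),
               smd_lrg = c(0.27, 9.02, 7.79, 8.80, 2.52, 4.61),
               stringsAsFactors = FALSE),
    data.frame(sample = 1:6, analyte = "amygdalin", esm_mg_ml = esm$amygdalin,
               avg_mg_ml = c(7.05, 7.10, 7.09, 6.85, 6.96, 6.82),
               smd_avg = c(4.89, 4.90, 4.90, 4.86, 4.89, 4.86),
               lrg_mg_ml = c(7.46, 7.51, 7.50, 7.25, 7.37, 7.22),
               smd_lrg = c(0.69, 0.68, 0.68, 0.72, 0.69, 0.72),
               stringsAsFactors = FALSE),
    data.frame(sample = 1:6, analyte = "chlorogenic_acid",
               esm_mg_ml = esm$chlorogenic_acid,
               avg_mg_ml = c(1.97, 2.02, 2.04, 1.94, 2.03, 1.93),
               smd_avg = c(2.68, 2.67, 2.67, 2.66, 2.67, 2.66),
               lrg_mg_ml = c(2.02, 2.08, 2.10, 2.00, 2.09, 1.99),
               smd_lrg = c(0.04, 0.06, 0.06, 0.06, 0.05, 0.06),
               stringsAsFactors = FALSE))
  # synthetic-data defaults for the four analytes whose contents are not
  # published: chosen so the 5000x-diluted working concentration sits
  # mid-calibration-range
  assumed_contents <- c(pseudoephedrine = 0.25, ephedrine = 0.15,
                        glycyrrhizinate = 1.0, baicalin = 5.0)
  list(panel = pneumonia_panel(), curves = curves,
       retention_min = retention_min, rcf = rcf, contents = contents,
       assumed_contents = assumed_contents)
}
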