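#' Define one analyte of an MRM panel
#'
#' An analyte is identified by its name, its MRM transition (precursor and
#' product m/z), its expected retention time under the nominal
#' chromatographic conditions, and the concentration range over which its
#' calibration curve is established.
#'
#' @param name Analyte name (non-empty character scalar).
#' @param precursor_mz Precursor ion m/z in Da; must exceed `product_mz`.
#' @param product_mz Product ion m/z in Da; must be positive.
#' @param expected_rt_min Expected retention time in minutes.
#' @param calib_low,calib_high Calibration range in ng/mL, `0 < low < high`.
#' @return A one-row data frame with the six fields above.
#' @examples
#' analyte("baicalein", 271.1, 123.0, 6.16, 1.82, 465)
#' @export
analyte <- function(name, precursor_mz, product_mz, expected_rt_min,
                    calib_low, calib_high) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty character scalar", call. = FALSE)
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", what, "' must be a finite numeric scalar for analyte '",
           name, "'", call. = FALSE)
    as.numeric(x)
  }
  precursor_mz <- num1(precursor_mz, "precursor_mz")
  product_mz <- num1(product_mz, "product_mz")
  expected_rt_min <- num1(expected_rt_min, "expected_rt_min")
  calib_low <- num1(calib_low, "calib_low")
  calib_high <- num1(calib_high, "calib_high")
  if (!(precursor_mz > product_mz && product_mz > 0))
    stop("transition for '", name,
         "' must satisfy precursor_mz > product_mz > 0", call. = FALSE)
  if (expected_rt_min <= 0)
    stop("expected_rt_min for '", name, "' must be positive", call. = FALSE)
  if (!(calib_low > 0 && calib_low < calib_high))
    stop("calibration range for '", name,
         "' must satisfy 0 < calib_low < calib_high", call. = FALSE)
  data.frame(name = name, precursor_mz = precursor_mz,
             product_mz = product_mz, expected_rt_min = expected_rt_min,
             calib_low = calib_low, calib_high = calib_high,
             stringsAsFactors = FALSE)
}

#' Assemble an analyte panel
#'
#' A panel is an ordered set of analytes together with the internal
#' reference standard (IRS) — the single constituent for which a physical
#' reference substance is carried through routine analysis — and the
#' dilution factor applied to the preparation before injection.
#'
#' @param analytes A data frame of analyte definitions, typically built by
#'   `rbind()`-ing calls to [analyte()].
#' @param irs Name of the internal reference standard; must be one of the
#'   panel's analytes.
#' @param dilution Dilution factor of the preparation (>= 1; default 1).
#' @return An object of class `analyte_panel`: a list with elements
#'   `analytes` (data frame), `irs` (character) and `dilution` (numeric).
#' @seealso [pneumonia_panel()] for the built-in eight-constituent example.
#' @export
analyte_panel <- function(analytes, irs, dilution = 1) {
  required <- c("name", "precursor_mz", "product_mz", "expected_rt_min",
                "calib_low", "calib_high")
  if (!is.data.frame(analytes) || !all(required %in% names(analytes)))
    stop("'analytes' must be a data frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (nrow(analytes) < 1L)
    stop("panel must contain at least one analyte", call. = FALSE)
  if (anyDuplicated(analytes$name))
    stop("analyte names must be unique", call. = FALSE)
  if (any(!nzchar(analytes$name)))
    stop("analyte names must be non-empty", call. = FALSE)
  # re-validate each row so panels built by hand get the same checks
  for (i in seq_len(nrow(analytes)))
    do.call(analyte, as.list(analytes[i, required]))
  if (!is.character(irs) || length(irs) != 1L || !(irs %in% analytes$name))
    stop("IRS '", irs, "' is not among the panel analytes", call. = FALSE)
  if (!is.numeric(dilution) || length(dilution) != 1L ||
      !is.finite(dilution) || dilution < 1)
    stop("'dilution' must be a single finite number >= 1", call. = FALSE)
  structure(
    list(analytes = analytes[, required], irs = irs,
         dilution = as.numeric(dilution)),
    class = "analyte_panel"
  )
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat("MRM analyte panel:", nrow(x$analytes), "analytes\n")
  cat("  IRS:", x$irs, "  dilution factor:", format(x$dilution), "\n")
  print(x$analytes, row.names = FALSE)
  invisible(x)
}

# one documented place for the ng/mL (working solution) <-> mg/mL
# (undiluted preparation) conversion: mg/mL = ng/mL * dilution * 1e-6

#' Convert working-solution to preparation concentration
#'
#' Working solutions are measured in ng/mL at the instrument; contents of
#' the undiluted preparation are reported in mg/mL. The conversion is
#' `mg/mL = ng/mL * dilution * 1e-6` and is applied here and nowhere else,
#' so the 10^6 unit step cannot silently appear twice.
#'
#' @param conc_ng_ml Working concentration(s), ng/mL.
#' @param dilution Dilution factor (scalar >= 1) or an `analyte_panel`.
#' @return Preparation concentration(s), mg/mL.
#' @export
working_to_prep <- function(conc_ng_ml, dilution) {
  if (inherits(dilution, "analyte_panel")) dilution <- dilution$dilution
  conc_ng_ml * dilution * 1e-6
}

#' @rdname working_to_prep
#' @param conc_mg_ml Preparation concentration(s), mg/mL.
#' @export
prep_to_working <- function(conc_mg_ml, dilution) {
  if (inherits(dilution, "analyte_panel")) dilution <- dilution$dilution
  conc_mg_ml / dilution * 1e6
}
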