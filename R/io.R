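#' @title Peak tables
#' @description
#' The exchange format for integrated MRM peaks is a plain CSV with columns
#' `analyte, run_id, role, rt_min, area, nominal_conc_ng_ml`:
#' one row per integrated peak. `role` is one of `standard`, `sample`,
#' `spiked`; `nominal_conc_ng_ml` is the nominal working concentration for
#' standards and empty (NA) for samples. Replicate injections are kept as
#' individual rows, never pre-averaged.
#' @name peak-table
NULL

PEAK_COLUMNS <- c("analyte", "run_id", "role", "rt_min", "area",
                  "nominal_conc_ng_ml")
PEAK_ROLES <- c("standard", "sample", "spiked")

#' Validate a peak table
#'
#' Checks the column set, roles, and the physical invariants
#' (`area >= 0`, `rt_min > 0`, nominal concentrations positive where given),
#' reporting the offending row number. Optionally rejects analytes not in a
#' panel.
#'
#' @param peaks A data frame in the peak-table layout (see [peak-table]).
#' @param panel Optional [analyte_panel()]; if given, unknown analytes are an
#'   error.
#' @return `peaks`, invisibly, with `role` normalised to character.
#' @export
validate_peak_table <- function(peaks, panel = NULL) {
  if (!is.data.frame(peaks))
    stop("peak table must be a data frame", call. = FALSE)
  missing_cols <- setdiff(PEAK_COLUMNS, names(peaks))
  if (length(missing_cols))
    stop("peak table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- names(peaks)[duplicated(names(peaks))]
  if (any(dup %in% PEAK_COLUMNS))
    stop("peak table has duplicate column(s): ",
         paste(intersect(dup, PEAK_COLUMNS), collapse = ", "), call. = FALSE)
  peaks$role <- as.character(peaks$role)
  bad_role <- which(!peaks$role %in% PEAK_ROLES)
  if (length(bad_role))
    stop("invalid role '", peaks$role[bad_role[1]], "' in row ",
         bad_role[1], " (must be one of ",
         paste(PEAK_ROLES, collapse = "/"), ")", call. = FALSE)
  bad <- which(!is.finite(peaks$area) | peaks$area < 0)
  if (length(bad))
    stop("negative or non-finite area in row ", bad[1], call. = FALSE)
  bad <- which(!is.finite(peaks$rt_min) | peaks$rt_min <= 0)
  if (length(bad))
    stop("non-positive or non-finite retention time in row ", bad[1],
         call. = FALSE)
  conc <- peaks$nominal_conc_ng_ml
  bad <- which(!is.na(conc) & (!is.finite(conc) | conc <= 0))
  if (length(bad))
    stop("non-positive nominal concentration in row ", bad[1], call. = FALSE)
  bad <- which(peaks$role == "standard" & is.na(conc))
  if (length(bad))
    stop("standard without nominal concentration in row ", bad[1],
         call. = FALSE)
  if (!is.null(panel)) {
    unknown <- setdiff(unique(peaks$analyte), panel$analytes$name)
    if (length(unknown))
      stop("unknown analyte(s) not in panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(peaks)
}

#' Read and write peak tables
#'
#' `read_peak_table()` reads the CSV layout described in [peak-table],
#' validates it, and returns a data frame; `write_peak_table()` writes one.
#' Numbers use decimal points (locale-independent); scientific notation is
#' accepted on input.
#'
#' @param path File path.
#' @param panel Optional [analyte_panel()] used to reject unknown analytes.
#' @return `read_peak_table()`: a validated peak-table data frame, row order
#'   preserved. `write_peak_table()`: `path`, invisibly.
#' @export
read_peak_table <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(analyte = "character",
                                          run_id = "character",
                                          role = "character"))
  missing_cols <- setdiff(PEAK_COLUMNS, names(peaks))
  if (length(missing_cols))
    stop("'", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  peaks <- peaks[, PEAK_COLUMNS]
  for (col in c("rt_min", "area", "nominal_conc_ng_ml"))
    peaks[[col]] <- as.numeric(peaks[[col]])
  validate_peak_table(peaks, panel)
  peaks
}

#' @rdname read_peak_table
#' @param peaks Peak-table data frame.
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- validate_peak_table(peaks)
  utils::write.csv(peaks[, PEAK_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read and write panel configurations
#'
#' The panel configuration is a YAML document with keys `analytes` (a list
#' of maps with `name`, `precursor_mz`, `product_mz`, `expected_rt_min`,
#' `calib_low`, `calib_high`), `irs`, and optionally `dilution`
#' (defaults to 1 when omitted).
#'
#' @param path File path.
#' @return `read_panel_config()`: an [analyte_panel()].
#'   `write_panel_config()`: `path`, invisibly.
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$analytes) || !length(cfg$analytes))
    stop("panel config has no 'analytes' entry", call. = FALSE)
  rows <- lapply(cfg$analytes, function(a) {
    need <- c("name", "precursor_mz", "product_mz", "expected_rt_min",
              "calib_low", "calib_high")
    miss <- setdiff(need, names(a))
    if (length(miss))
      stop("analyte entry missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    do.call(analyte, a[need])
  })
  if (is.null(cfg$irs))
    stop("panel config has no 'irs' entry", call. = FALSE)
  dilution <- if (is.null(cfg$dilution)) 1 else cfg$dilution
  analyte_panel(do.call(rbind, rows), irs = cfg$irs, dilution = dilution)
}

#' @rdname read_panel_config
#' @param panel An [analyte_panel()].
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "analyte_panel"))
  cfg <- list(
    analytes = lapply(seq_len(nrow(panel$analytes)), function(i)
      as.list(panel$analytes[i, ])),
    irs = panel$irs,
    dilution = panel$dilution
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
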