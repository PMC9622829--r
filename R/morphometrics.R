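#' Calibrate a pixel length against a reference object
#'
#' Converts a pixel distance measured on a still frame to centimetres via
#' a reference object of known true length visible in the same image
#' (e.g. an observer's diving fin). The conversion is a pure ratio, so it
#' is invariant to rescaling both pixel measurements together.
#'
#' @param pixel_len measured pixel length(s) of the subject (`> 0`).
#' @param ref_pixel_len pixel length of the reference object (`> 0`).
#' @param ref_cm true length of the reference object in cm (`> 0`).
#' @return Length(s) in cm: `pixel_len * ref_cm / ref_pixel_len`.
#' @export
calibrate_length <- function(pixel_len, ref_pixel_len, ref_cm) {
  if (any(pixel_len <= 0) || any(ref_pixel_len <= 0) || any(ref_cm <= 0))
    stop("all lengths must be positive", call. = FALSE)
  pixel_len * ref_cm / ref_pixel_len
}

#' Convert eye-fork length to body weight
#'
#' Allometric length-weight conversion for striped marlin:
#' `weight_kg = a * EFL_cm^b` with published coefficients
#' `a = 0.00000133263` and `b = 3.41344` (eye-fork length in cm).
#'
#' @param efl_cm eye-fork length(s) in cm (`>= 0`).
#' @param a,b allometric coefficients.
#' @return Weight(s) in kg (full precision; round to 1 decimal for
#'   reporting).
#' @export
#' @examples
#' round(efl_to_weight(c(125.3, 180.9)), 1)  # 19.3  67.7
efl_to_weight <- function(efl_cm, a = 0.00000133263, b = 3.41344) {
  if (any(efl_cm < 0)) stop("EFL must be non-negative", call. = FALSE)
  a * efl_cm^b
}

#' Read a morphometrics measurement table
#'
#' Expected columns: `individual`, `frame`, `pixel_len`, `ref_pixel_len`,
#' `ref_cm` - one row per repeated still-frame measurement.
#'
#' @param path path to the CSV file.
#' @param sep field separator.
#' @return The measurement data.frame with an added `efl_cm` column.
#' @export
read_morphometrics <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("individual", "pixel_len", "ref_pixel_len", "ref_cm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("morphometrics table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$efl_cm <- calibrate_length(tab$pixel_len, tab$ref_pixel_len,
                                 tab$ref_cm)
  tab
}

#' Aggregate repeated length measurements into sizes and weights
#'
#' Per individual, averages the calibrated eye-fork lengths over the
#' repeated measurements and converts the mean EFL to weight once (rather
#' than averaging per-frame weights, so the reported weight round-trips
#' the reported length). Also returns a cohort summary.
#'
#' @param measurements data.frame as returned by [read_morphometrics()]
#'   (columns `individual` and `efl_cm`; or pixel columns from which
#'   `efl_cm` is computed).
#' @param a,b allometric coefficients passed to [efl_to_weight()].
#' @return A list of class `"morph_summary"`: `individuals` (data.frame
#'   `individual`, `n_measurements`, `efl_mean_cm`, `efl_sd_cm`,
#'   `weight_kg`) and `cohort` (list with `n`, `efl_mean_cm`, `efl_sd_cm`,
#'   `efl_range_cm`, `weight_mean_kg`, `weight_sd_kg`, `weight_range_kg`,
#'   `mean_within_sd_cm` - the mean over individuals of the SD of their
#'   repeated measurements).
#' @export
aggregate_measurements <- function(measurements, a = 0.00000133263,
                                   b = 3.41344) {
  if (is.null(measurements$efl_cm))
    measurements$efl_cm <- calibrate_length(measurements$pixel_len,
                                            measurements$ref_pixel_len,
                                            measurements$ref_cm)
  sp <- split(measurements$efl_cm, measurements$individual)
  ind <- data.frame(
    individual = names(sp),
    n_measurements = lengths(sp),
    efl_mean_cm = vapply(sp, mean, numeric(1L)),
    efl_sd_cm = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) else 0, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  ind$weight_kg <- efl_to_weight(ind$efl_mean_cm, a, b)
  cohort <- list(
    n = nrow(ind),
    efl_mean_cm = mean(ind$efl_mean_cm),
    efl_sd_cm = if (nrow(ind) > 1L) stats::sd(ind$efl_mean_cm) else 0,
    efl_range_cm = range(ind$efl_mean_cm),
    weight_mean_kg = mean(ind$weight_kg),
    weight_sd_kg = if (nrow(ind) > 1L) stats::sd(ind$weight_kg) else 0,
    weight_range_kg = range(ind$weight_kg),
    mean_within_sd_cm = mean(ind$efl_sd_cm))
  structure(list(individuals = ind, cohort = cohort),
            class = "morph_summary")
}

#' @export
print.morph_summary <- function(x, ...) {
  co <- x$cohort
  cat(sprintf(
    "Sized %d individuals: EFL %.1f +/- %.1f cm (range %.1f-%.1f)\n",
    co$n, co$efl_mean_cm, co$efl_sd_cm, co$efl_range_cm[1L],
    co$efl_range_cm[2L]))
  cat(sprintf("weight %.1f +/- %.1f kg (range %.1f-%.1f)\n",
              co$weight_mean_kg, co$weight_sd_kg, co$weight_range_kg[1L],
              co$weight_range_kg[2L]))
  invisible(x)
}
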