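# Typed containers for the three measurement kinds. Plain lists with light
# S3 classes; grids are physical values (nm, s, mM), matrices are
# wavelength x column.

#' Titration spectrum series
#'
#' @param wavelengths_nm ascending wavelength grid, nm.
#' @param concentrations_mM ascending, nonnegative; first entry is the
#'   reference (typically 0 mM).
#' @param absorbance matrix `[wavelength x concentration]`.
#' @param anion optional label.
#' @return object of class `spectrum_series`.
#' @export
spectrum_series <- function(wavelengths_nm, concentrations_mM, absorbance,
                            anion = NULL) {
  check_ascending(wavelengths_nm, "wavelengths_nm")
  check_ascending(concentrations_mM, "concentrations_mM", nonnegative = TRUE)
  absorbance <- as.matrix(absorbance)
  if (!is.numeric(absorbance) || any(!is.finite(absorbance))) {
    fail_field("absorbance", "must be a finite numeric matrix")
  }
  if (nrow(absorbance) != length(wavelengths_nm) ||
      ncol(absorbance) != length(concentrations_mM)) {
    fail_field("absorbance", "dimensions must match the wavelength and concentration grids")
  }
  dimnames(absorbance) <- list(NULL, NULL)
  structure(
    list(wavelengths_nm = wavelengths_nm,
         concentrations_mM = concentrations_mM,
         absorbance = absorbance, anion = anion),
    class = "spectrum_series"
  )
}

#' Transient absorption dataset
#'
#' A flash-photolysis delta-absorbance matrix over a wavelength x time grid.
#'
#' @param wavelengths_nm ascending wavelength grid, nm.
#' @param times_s strictly ascending positive time grid, seconds.
#' @param deltaA matrix `[wavelength x time]`, dimensionless.
#' @return object of class `transient_dataset`.
#' @export
transient_dataset <- function(wavelengths_nm, times_s, deltaA) {
  check_ascending(wavelengths_nm, "wavelengths_nm")
  check_ascending(times_s, "times_s", positive = TRUE)
  deltaA <- as.matrix(deltaA)
  if (!is.numeric(deltaA) || any(!is.finite(deltaA))) {
    fail_field("deltaA", "must be a finite numeric matrix (no missing cells)")
  }
  if (nrow(deltaA) != length(wavelengths_nm) ||
      ncol(deltaA) != length(times_s)) {
    fail_field("deltaA", "dimensions must match the wavelength and time grids")
  }
  dimnames(deltaA) <- list(NULL, NULL)
  structure(
    list(wavelengths_nm = wavelengths_nm, times_s = times_s, deltaA = deltaA),
    class = "transient_dataset"
  )
}

#' Light-induced pH trace
#'
#' @param times_s ascending sampling times, seconds.
#' @param pH pH readings, same length.
#' @param light_on_s,light_off_s illumination window, inside the time range.
#' @return object of class `ph_trace`.
#' @export
ph_trace <- function(times_s, pH, light_on_s, light_off_s) {
  check_ascending(times_s, "times_s", strictly = TRUE, nonnegative = TRUE)
  if (!is.numeric(pH) || length(pH) != length(times_s) || any(!is.finite(pH))) {
    fail_field("pH", "must be finite and match times_s")
  }
  check_scalar(light_on_s, "light_on_s", nonnegative = TRUE)
  check_scalar(light_off_s, "light_off_s", positive = TRUE)
  if (!(light_on_s < light_off_s && light_off_s <= max(times_s) &&
        light_on_s >= min(times_s))) {
    fail_field("light_on_s", "illumination window must lie inside the trace")
  }
  structure(
    list(times_s = times_s, pH = pH,
         light_on_s = light_on_s, light_off_s = light_off_s),
    class = "ph_trace"
  )
}

#' Mutant activity panel
#'
#' Long-format replicate table of initial-slope activities with expression
#' levels, as produced by [gen_mutant_panel()] or read from CSV.
#'
#' @param data data.frame with columns `mutant`, `anion`, `replicate`,
#'   `slope`, `expression`.
#' @return object of class `mutant_panel` (a data.frame).
#' @export
mutant_panel <- function(data) {
  need <- c("mutant", "anion", "replicate", "slope", "expression")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    fail_field("data", paste("must be a data.frame with columns",
                             paste(need, collapse = ", ")))
  }
  if (!"WT" %in% data$mutant) fail_field("mutant", "panel must include 'WT'")
  if (any(!is.finite(data$expression)) || any(data$expression <= 0)) {
    fail_field("expression", "must be finite and > 0")
  }
  structure(as.data.frame(data), class = c("mutant_panel", "data.frame"))
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("Titration series: %d wavelengths (%g-%g nm), %d concentrations (%g-%g mM)%s\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), length(x$concentrations_mM),
              min(x$concentrations_mM), max(x$concentrations_mM),
              if (is.null(x$anion)) "" else paste0(", anion ", x$anion)))
  invisible(x)
}

#' @export
print.transient_dataset <- function(x, ...) {
  cat(sprintf("Transient dataset: %d wavelengths (%g-%g nm) x %d times (%.2g-%.2g s)\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), length(x$times_s), min(x$times_s),
              max(x$times_s)))
  invisible(x)
}
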