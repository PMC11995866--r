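#' Gaussian spectral band model
#'
#' Visible absorption bands of retinal proteins are modeled as Gaussians in
#' wavelength space: a center (`lambda_max_nm`), a width (Gaussian sigma,
#' nm) and a dimensionless peak absorbance.
#'
#' @param lambda_max_nm band maximum, nm; must lie in 300--800 nm.
#' @param width_nm Gaussian sigma, nm; > 0.
#' @param amplitude peak absorbance, dimensionless; >= 0.
#' @return an object of class `spectral_band`.
#' @examples
#' b <- spectral_band(545, 35, 1)
#' band_profile(b, seq(400, 700, 10))
#' @export
spectral_band <- function(lambda_max_nm, width_nm, amplitude = 1) {
  check_scalar(lambda_max_nm, "lambda_max_nm")
  if (lambda_max_nm < 300 || lambda_max_nm > 800) {
    fail_field("lambda_max_nm", "must lie within 300..800 nm")
  }
  check_scalar(width_nm, "width_nm", positive = TRUE)
  check_scalar(amplitude, "amplitude", nonnegative = TRUE)
  structure(
    list(lambda_max_nm = lambda_max_nm, width_nm = width_nm,
         amplitude = amplitude),
    class = "spectral_band"
  )
}

#' Evaluate a Gaussian band on a wavelength grid
#'
#' @param band a [spectral_band()].
#' @param wavelengths_nm numeric wavelength grid, nm.
#' @return absorbance values, same length as `wavelengths_nm`.
#' @export
band_profile <- function(band, wavelengths_nm) {
  stopifnot(inherits(band, "spectral_band"))
  band$amplitude *
    exp(-((wavelengths_nm - band$lambda_max_nm)^2) / (2 * band$width_nm^2))
}

as_band <- function(x, field) {
  if (inherits(x, "spectral_band")) return(x)
  if (is.list(x) && all(c("lambda_max_nm", "width_nm") %in% names(x))) {
    return(spectral_band(x$lambda_max_nm, x$width_nm,
                         if (is.null(x$amplitude)) 1 else x$amplitude))
  }
  fail_field(field, "must be a spectral_band or a list with lambda_max_nm/width_nm/amplitude")
}

#' @export
print.spectral_band <- function(x, ...) {
  cat(sprintf("Gaussian band: lambda_max %.1f nm, sigma %.1f nm, amplitude %.3g\n",
              x$lambda_max_nm, x$width_nm, x$amplitude))
  invisible(x)
}
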