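#' Hyperbolic (single-site) binding isotherm
#'
#' Fractional absorbance change for one anion binding site,
#' \deqn{\Delta A(x) = V_{max} \, x / (K_d + x)}
#' with the amplitude conventionally fixed at 1 so the fitted plateau is the
#' unit of the normalized titration curve.
#'
#' @param x anion concentration, mM (vector, >= 0).
#' @param Kd_mM dissociation constant, mM (> 0).
#' @param Vmax saturating amplitude (default 1).
#' @return fractional change, same length as `x`.
#' @export
isotherm_one_site <- function(x, Kd_mM, Vmax = 1) {
  check_scalar(Kd_mM, "Kd_mM", positive = TRUE)
  Vmax * x / (Kd_mM + x)
}

#' Two-site (double combined) binding isotherm
#'
#' Sum of two hyperbolic sites with amplitudes constrained to add to `Vtot`
#' (1 by default):
#' \deqn{\Delta A(x) = V_{max,1} \frac{x}{K_{d1}+x} +
#'       (V_{tot}-V_{max,1}) \frac{x}{K_{d2}+x}}
#'
#' @param x anion concentration, mM.
#' @param Kd1_mM,Kd2_mM dissociation constants of the high- and low-affinity
#'   site, mM (> 0).
#' @param Vmax1 amplitude of the first site, in `[0, Vtot]`.
#' @param Vtot total amplitude (default 1).
#' @return fractional change, same length as `x`.
#' @export
isotherm_two_site <- function(x, Kd1_mM, Kd2_mM, Vmax1, Vtot = 1) {
  check_scalar(Kd1_mM, "Kd1_mM", positive = TRUE)
  check_scalar(Kd2_mM, "Kd2_mM", positive = TRUE)
  check_scalar(Vmax1, "Vmax1")
  if (Vmax1 < 0 || Vmax1 > Vtot) fail_field("Vmax1", "must lie in [0, Vtot]")
  Vmax1 * x / (Kd1_mM + x) + (Vtot - Vmax1) * x / (Kd2_mM + x)
}

# Scenario-driven bound fraction used by the titration generator.
isotherm_fraction <- function(scenario, x) {
  if (scenario$model_kind == "one_site") {
    isotherm_one_site(x, scenario$Kd_mM)
  } else {
    isotherm_two_site(x, scenario$Kd1_mM, scenario$Kd2_mM, scenario$Vmax1)
  }
}
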