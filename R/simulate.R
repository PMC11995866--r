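# Seeded synthetic-data generators. Each generator is bit-reproducible for a
# given scenario + seed and leaves the caller's RNG stream untouched.

#' Generate a synthetic anion titration series
#'
#' At concentration `c` the spectrum is the isotherm-weighted mixture
#' `(1 - f(c)) * unbound + f(c) * bound` of the two scenario bands, plus
#' homoscedastic Gaussian noise on every cell (including the reference
#' spectrum). `f` is the one- or two-site isotherm of the scenario.
#'
#' @param scenario a [titration_scenario()].
#' @return a [spectrum_series()].
#' @examples
#' sc <- titration_scenario(
#'   model_kind = "one_site", Kd_mM = 0.5,
#'   unbound_band = spectral_band(545, 35), bound_band = spectral_band(535, 35),
#'   noise_sigma = 0, seed = 1
#' )
#' series <- gen_titration(sc)
#' @export
gen_titration <- function(scenario) {
  stopifnot(inherits(scenario, "titration_scenario"))
  wl <- scenario$wavelengths_nm
  conc <- scenario$concentrations_mM
  f <- isotherm_fraction(scenario, conc)
  unbound <- band_profile(scenario$unbound_band, wl)
  bound <- band_profile(scenario$bound_band, wl)
  clean <- outer(unbound, 1 - f) + outer(bound, f)
  noisy <- with_seed(scenario$seed, {
    clean + scenario$noise_sigma * matrix(stats::rnorm(length(clean)),
                                          nrow = nrow(clean))
  })
  spectrum_series(wl, conc, noisy, anion = scenario$anion)
}

#' Generate a synthetic transient absorption matrix
#'
#' The noiseless signal is the sequential-chain forward model
#' `deltaA(lambda, t) = sum_j SADS_j(lambda) c_j(t)` with concentrations from
#' the Bateman solution ([bateman_concentrations()]); each intermediate's
#' SADS is its positive band minus its bleach band. Gaussian noise is added
#' per cell.
#'
#' @param scenario a [photocycle_scenario()].
#' @return a [transient_dataset()].
#' @export
gen_transient <- function(scenario) {
  stopifnot(inherits(scenario, "photocycle_scenario"))
  wl <- scenario$wavelengths_nm
  tt <- scenario$times_s
  if (anyDuplicated(tt) || is.unsorted(tt)) {
    fail_field("times_s", "must be sorted without duplicates")
  }
  sads <- scenario_sads_matrix(scenario)
  scheme <- sequential_scheme(scenario$labels, scenario$tau_s)
  clean <- forward_model(scheme, sads, wl, tt)$deltaA
  noisy <- with_seed(scenario$seed, {
    clean + scenario$noise_sigma * matrix(stats::rnorm(length(clean)),
                                          nrow = nrow(clean))
  })
  transient_dataset(wl, tt, noisy)
}

#' Ground-truth SADS matrix of a photocycle scenario
#'
#' @param scenario a [photocycle_scenario()].
#' @return matrix `[wavelength x species]` of species-associated difference
#'   spectra (positive band minus bleach band).
#' @export
scenario_sads_matrix <- function(scenario) {
  wl <- scenario$wavelengths_nm
  vapply(scenario$sads, function(s) {
    band_profile(s$positive, wl) - band_profile(s$bleach, wl)
  }, numeric(length(wl)))
}

#' Generate a synthetic light-induced pH trace
#'
#' Baseline drift before light-on; drift plus a linear rise of
#' `true_slope_pH_s` during illumination; after light-off the light-induced
#' offset relaxes exponentially (time constant `relax_tau_s`) back to the
#' drift line. Gaussian noise is added to every sample.
#'
#' @param scenario a [transport_scenario()].
#' @return a [ph_trace()].
#' @export
gen_ph_trace <- function(scenario) {
  stopifnot(inherits(scenario, "transport_scenario"))
  tt <- seq(0, scenario$duration_s, by = scenario$sample_interval_s)
  on <- scenario$light_on_s
  off <- scenario$light_off_s
  base <- scenario$drift_slope_pH_s * tt
  light <- scenario$true_slope_pH_s * pmin(pmax(tt - on, 0), off - on)
  after <- tt > off
  light[after] <- scenario$true_slope_pH_s * (off - on) *
    exp(-(tt[after] - off) / scenario$relax_tau_s)
  clean <- 7 + base + light
  noisy <- with_seed(scenario$seed,
                     clean + stats::rnorm(length(clean), sd = scenario$noise_sigma))
  ph_trace(tt, noisy, on, off)
}

#' Generate a synthetic mutant activity panel
#'
#' For each mutant, anion and replicate, a slope is drawn around the true
#' activity with fractional SD `replicate_cv` (Gaussian), paired with the
#' mutant's expression level. Replicates emulate independent cell
#' preparations.
#'
#' @param scenario a [panel_scenario()].
#' @return a [mutant_panel()] data.frame with columns `mutant`, `anion`,
#'   `replicate`, `slope`, `expression`.
#' @export
gen_mutant_panel <- function(scenario) {
  stopifnot(inherits(scenario, "panel_scenario"))
  m <- length(scenario$mutant_names)
  n <- scenario$n_replicates
  grid <- expand.grid(replicate = seq_len(n),
                      anion = c("Cl", "SO4"),
                      mutant_idx = seq_len(m),
                      stringsAsFactors = FALSE)
  truth <- ifelse(grid$anion == "Cl",
                  scenario$true_activity_cl[grid$mutant_idx],
                  scenario$true_activity_so4[grid$mutant_idx])
  slopes <- with_seed(scenario$seed, {
    truth * (1 + scenario$replicate_cv * stats::rnorm(nrow(grid)))
  })
  out <- data.frame(
    mutant = scenario$mutant_names[grid$mutant_idx],
    anion = grid$anion,
    replicate = grid$replicate,
    slope = slopes,
    expression = scenario$expression[grid$mutant_idx],
    stringsAsFactors = FALSE
  )
  mutant_panel(out[order(grid$mutant_idx, grid$anion, grid$replicate), ])
}
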