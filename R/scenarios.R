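# Scenario constructors: validated parameter bundles with known ground truth,
# consumed by the synthetic-data generators. A catalog of default scenarios
# modeled on the wild-type and mutant measurements ships as YAML files under
# inst/extdata/scenarios/.

#' Titration scenario
#'
#' Ground-truth description of an anion titration: two Gaussian absorption
#' bands (anion-free and anion-bound pigment) mixed by a one- or two-site
#' binding isotherm, observed on a wavelength grid with homoscedastic
#' Gaussian noise.
#'
#' @param model_kind `"one_site"` or `"two_site"`.
#' @param Kd_mM dissociation constant (one-site), mM.
#' @param Kd1_mM,Kd2_mM,Vmax1 two-site parameters; `Vmax1` in (0, 1).
#' @param shift_direction `"blue"` or `"red"`: direction of the anion-induced
#'   band shift (bound relative to unbound).
#' @param unbound_band,bound_band [spectral_band()] objects (or lists with
#'   `lambda_max_nm`, `width_nm`, `amplitude`).
#' @param concentrations_mM strictly ascending, nonnegative anion
#'   concentrations; the first (typically 0) is the reference.
#' @param wavelengths_nm ascending wavelength grid, nm.
#' @param noise_sigma per-cell Gaussian noise SD, absorbance units; >= 0.
#' @param seed integer RNG seed.
#' @param anion optional label (e.g. `"Cl"`, `"SO4"`).
#' @return object of class `titration_scenario`.
#' @export
titration_scenario <- function(model_kind = c("one_site", "two_site"),
                               Kd_mM = NULL,
                               Kd1_mM = NULL, Kd2_mM = NULL, Vmax1 = NULL,
                               shift_direction = c("blue", "red"),
                               unbound_band,
                               bound_band,
                               concentrations_mM = c(0, log_grid(0.01, 1000, 16)),
                               wavelengths_nm = seq(400, 700, by = 2),
                               noise_sigma = 0.02,
                               seed = 1L,
                               anion = NULL) {
  model_kind <- match.arg(model_kind)
  shift_direction <- match.arg(shift_direction)
  if (model_kind == "one_site") {
    check_scalar(Kd_mM, "Kd_mM", positive = TRUE)
  } else {
    check_scalar(Kd1_mM, "Kd1_mM", positive = TRUE)
    check_scalar(Kd2_mM, "Kd2_mM", positive = TRUE)
    check_scalar(Vmax1, "Vmax1")
    if (Vmax1 <= 0 || Vmax1 >= 1) fail_field("Vmax1", "must lie in (0, 1)")
  }
  unbound_band <- as_band(unbound_band, "unbound_band")
  bound_band <- as_band(bound_band, "bound_band")
  check_ascending(concentrations_mM, "concentrations_mM", nonnegative = TRUE)
  check_ascending(wavelengths_nm, "wavelengths_nm")
  check_scalar(noise_sigma, "noise_sigma", nonnegative = TRUE)
  structure(
    list(model_kind = model_kind, Kd_mM = Kd_mM, Kd1_mM = Kd1_mM,
         Kd2_mM = Kd2_mM, Vmax1 = Vmax1, shift_direction = shift_direction,
         unbound_band = unbound_band, bound_band = bound_band,
         concentrations_mM = concentrations_mM,
         wavelengths_nm = wavelengths_nm, noise_sigma = noise_sigma,
         seed = seed, anion = anion),
    class = "titration_scenario"
  )
}

#' Photocycle scenario
#'
#' Ground truth for a flash-photolysis experiment: an irreversible sequential
#' chain of intermediates with given decay time constants, each intermediate
#' carrying a difference spectrum (positive intermediate band minus ground
#' state bleach band), sampled on a wavelength x time grid with Gaussian
#' noise.
#'
#' @param tau_s decay time constants, seconds, one per intermediate (> 0).
#' @param sads list, one element per intermediate, each a list with
#'   `positive` and `bleach` band specifications ([spectral_band()] or list).
#'   Zero-amplitude bands model intermediates that do not accumulate.
#' @param labels intermediate names in chain order (default `K`, `L`, `O`
#'   for three species, `S1..` otherwise).
#' @param wavelengths_nm wavelength grid (default 420--710 nm at 10 nm).
#' @param times_s strictly ascending positive time grid (default 60
#'   log-spaced points over 1e-5--4 s).
#' @param noise_sigma per-cell Gaussian noise SD, delta-absorbance units.
#' @param seed integer RNG seed.
#' @return object of class `photocycle_scenario`.
#' @export
photocycle_scenario <- function(tau_s, sads, labels = NULL,
                                wavelengths_nm = seq(420, 710, by = 10),
                                times_s = log_grid(1e-5, 4, 60),
                                noise_sigma = 0.01,
                                seed = 1L) {
  check_ascending(tau_s, "tau_s", strictly = FALSE, positive = TRUE)
  if (!is.list(sads) || length(sads) != length(tau_s)) {
    fail_field("sads", "must be a list with one difference-band pair per tau")
  }
  sads <- lapply(seq_along(sads), function(j) {
    s <- sads[[j]]
    if (!is.list(s) || !all(c("positive", "bleach") %in% names(s))) {
      fail_field("sads", sprintf("element %d must have 'positive' and 'bleach' bands", j))
    }
    list(positive = as_band(s$positive, "sads$positive"),
         bleach = as_band(s$bleach, "sads$bleach"))
  })
  if (is.null(labels)) {
    labels <- if (length(tau_s) == 3) c("K", "L", "O") else
      paste0("S", seq_along(tau_s))
  }
  if (length(labels) != length(tau_s)) {
    fail_field("labels", "must match the number of time constants")
  }
  check_ascending(wavelengths_nm, "wavelengths_nm")
  check_ascending(times_s, "times_s", positive = TRUE)
  check_scalar(noise_sigma, "noise_sigma", nonnegative = TRUE)
  structure(
    list(tau_s = tau_s, sads = sads, labels = labels,
         wavelengths_nm = wavelengths_nm, times_s = times_s,
         noise_sigma = noise_sigma, seed = seed),
    class = "photocycle_scenario"
  )
}

#' Transport scenario
#'
#' Ground truth for a light-induced extracellular pH trace: linear baseline
#' drift, a linear pH rise of `true_slope_pH_s` while the light is on, and a
#' single-exponential relaxation back to the drift line after light-off.
#'
#' @param true_slope_pH_s pH change rate during illumination, pH/s.
#' @param drift_slope_pH_s baseline drift, pH/s.
#' @param light_on_s,light_off_s illumination window, seconds.
#' @param duration_s total trace length, seconds.
#' @param sample_interval_s sampling interval, seconds (> 0).
#' @param noise_sigma Gaussian noise SD, pH units.
#' @param relax_tau_s post-illumination relaxation time constant, seconds.
#' @param seed integer RNG seed.
#' @return object of class `transport_scenario`.
#' @export
transport_scenario <- function(true_slope_pH_s = 5e-4,
                               drift_slope_pH_s = 0,
                               light_on_s = 60, light_off_s = 120,
                               duration_s = 180, sample_interval_s = 1,
                               noise_sigma = 2e-4, relax_tau_s = 30,
                               seed = 1L) {
  check_scalar(true_slope_pH_s, "true_slope_pH_s")
  check_scalar(drift_slope_pH_s, "drift_slope_pH_s")
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(light_on_s, "light_on_s", nonnegative = TRUE)
  check_scalar(light_off_s, "light_off_s", positive = TRUE)
  if (!(light_on_s < light_off_s && light_off_s <= duration_s)) {
    fail_field("light_on_s", "events must satisfy 0 <= light_on < light_off <= duration")
  }
  check_scalar(sample_interval_s, "sample_interval_s", positive = TRUE)
  check_scalar(noise_sigma, "noise_sigma", nonnegative = TRUE)
  check_scalar(relax_tau_s, "relax_tau_s", positive = TRUE)
  structure(
    list(true_slope_pH_s = true_slope_pH_s,
         drift_slope_pH_s = drift_slope_pH_s,
         light_on_s = light_on_s, light_off_s = light_off_s,
         duration_s = duration_s, sample_interval_s = sample_interval_s,
         noise_sigma = noise_sigma, relax_tau_s = relax_tau_s, seed = seed),
    class = "transport_scenario"
  )
}

#' Mutant panel scenario
#'
#' Ground truth for a mutant activity panel: per-mutant true initial-slope
#' activities in chloride and sulfate media, relative expression levels
#' (WT = 1), replicate count and a fractional replicate noise (CV).
#'
#' @param mutant_names character vector; must contain `"WT"`.
#' @param true_activity_cl,true_activity_so4 per-mutant true slopes, pH/s.
#' @param expression per-mutant relative expression, > 0 (WT = 1).
#' @param n_replicates replicates per mutant and anion (>= 3).
#' @param replicate_cv fractional replicate-to-replicate noise, >= 0.
#' @param seed integer RNG seed.
#' @return object of class `panel_scenario`.
#' @export
panel_scenario <- function(mutant_names, true_activity_cl, true_activity_so4,
                           expression, n_replicates = 4, replicate_cv = 0.1,
                           seed = 1L) {
  if (!is.character(mutant_names) || length(mutant_names) < 1L) {
    fail_field("mutant_names", "must be a character vector")
  }
  if (!"WT" %in% mutant_names) fail_field("mutant_names", "must include 'WT'")
  if (anyDuplicated(mutant_names)) fail_field("mutant_names", "must be unique")
  m <- length(mutant_names)
  for (nm in c("true_activity_cl", "true_activity_so4", "expression")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != m || any(!is.finite(v))) {
      fail_field(nm, sprintf("must be a finite numeric vector of length %d", m))
    }
  }
  if (any(expression <= 0)) fail_field("expression", "must be > 0")
  check_scalar(n_replicates, "n_replicates", positive = TRUE)
  if (n_replicates < 3) fail_field("n_replicates", "must be >= 3")
  check_scalar(replicate_cv, "replicate_cv", nonnegative = TRUE)
  structure(
    list(mutant_names = mutant_names,
         true_activity_cl = true_activity_cl,
         true_activity_so4 = true_activity_so4,
         expression = expression,
         n_replicates = as.integer(n_replicates),
         replicate_cv = replicate_cv, seed = seed),
    class = "panel_scenario"
  )
}

scenario_dir <- function() {
  system.file("extdata", "scenarios", package = "halopump", mustWork = TRUE)
}

#' List the shipped scenario catalog
#'
#' @return character vector of scenario names usable with [scenario()].
#' @export
scenario_catalog <- function() {
  sub("\\.yaml$", "", list.files(scenario_dir(), pattern = "\\.yaml$"))
}

#' Load a named scenario from the shipped catalog
#'
#' Catalog entries carry parameters modeled on the wild-type and mutant
#' measurements (dissociation constants, photocycle time constants, band
#' positions); band maxima are approximate. `seed` and other fields can be
#' overridden.
#'
#' @param name catalog name, see [scenario_catalog()].
#' @param ... field overrides (e.g. `seed = 7`, `noise_sigma = 0`).
#' @return a validated scenario object.
#' @examples
#' \dontrun{
#' sc <- scenario("WT-Cl", seed = 3)
#' }
#' @export
scenario <- function(name, ...) {
  path <- file.path(scenario_dir(), paste0(name, ".yaml"))
  if (!file.exists(path)) {
    stop(sprintf("unknown scenario '%s'; see scenario_catalog()", name),
         call. = FALSE)
  }
  sc <- read_scenario(path)
  overrides <- list(...)
  if (length(overrides)) sc <- do.call(scenario_modify, c(list(sc), overrides))
  sc
}

#' Modify scenario fields with re-validation
#'
#' @param sc a scenario object.
#' @param ... named field replacements.
#' @return a re-validated scenario of the same class.
#' @export
scenario_modify <- function(sc, ...) {
  overrides <- list(...)
  if (!length(overrides)) return(sc)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("scenario overrides must be named", call. = FALSE)
  }
  fields <- unclass(sc)
  unknown <- setdiff(names(overrides), names(fields))
  if (length(unknown)) {
    fail_field(unknown[1], "unknown scenario field")
  }
  fields[names(overrides)] <- overrides
  rebuild_scenario(class(sc)[1], fields)
}

rebuild_scenario <- function(cls, fields) {
  switch(cls,
    titration_scenario = do.call(titration_scenario, fields),
    photocycle_scenario = do.call(photocycle_scenario, fields),
    transport_scenario = do.call(transport_scenario, fields),
    panel_scenario = do.call(panel_scenario, fields),
    stop(sprintf("unknown scenario class '%s'", cls), call. = FALSE)
  )
}

band_to_list <- function(b) {
  list(lambda_max_nm = b$lambda_max_nm, width_nm = b$width_nm,
       amplitude = b$amplitude)
}

#' Write a scenario to a YAML config file
#'
#' The file round-trips losslessly through [read_scenario()].
#'
#' @param sc scenario object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  cls <- class(sc)[1]
  fields <- unclass(sc)
  if (cls == "titration_scenario") {
    fields$unbound_band <- band_to_list(fields$unbound_band)
    fields$bound_band <- band_to_list(fields$bound_band)
    fields <- fields[!vapply(fields, is.null, logical(1))]
  }
  if (cls == "photocycle_scenario") {
    fields$sads <- lapply(fields$sads, function(s) {
      list(positive = band_to_list(s$positive), bleach = band_to_list(s$bleach))
    })
  }
  yaml::write_yaml(c(list(kind = cls), fields), path, precision = 15)
  invisible(path)
}

#' Read a scenario config file
#'
#' Unknown keys are rejected; the scenario is rebuilt through its validating
#' constructor.
#'
#' @param path YAML file written by [write_scenario()] (or by hand in the
#'   same layout, with a `kind` key naming the scenario class).
#' @return a validated scenario object.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$kind)) fail_field("kind", "missing in scenario file")
  cls <- raw$kind
  raw$kind <- NULL
  proto <- switch(cls,
    titration_scenario = names(formals(titration_scenario)),
    photocycle_scenario = names(formals(photocycle_scenario)),
    transport_scenario = names(formals(transport_scenario)),
    panel_scenario = names(formals(panel_scenario)),
    stop(sprintf("unknown scenario kind '%s'", cls), call. = FALSE)
  )
  unknown <- setdiff(names(raw), proto)
  if (length(unknown)) fail_field(unknown[1], "unknown scenario field")
  # YAML reads numeric vectors as unnamed lists; flatten those (named
  # mappings such as bands stay lists)
  numify <- function(x) {
    if (is.list(x) && is.null(names(x)) && length(x) &&
        all(vapply(x, is.numeric, logical(1)))) unlist(x) else x
  }
  raw <- lapply(raw, numify)
  if (cls == "panel_scenario" && is.list(raw$mutant_names)) {
    raw$mutant_names <- unlist(raw$mutant_names)
  }
  rebuild_scenario(cls, raw)
}
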