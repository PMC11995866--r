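test_that("generators are bit-identical under a repeated seed", {
  sc <- quick_titration(noise_sigma = 0.02, seed = 123)
  expect_identical(gen_titration(sc), gen_titration(sc))
  pc <- quick_photocycle(noise_sigma = 0.01, seed = 123)
  expect_identical(gen_transient(pc), gen_transient(pc))
  ts <- transport_scenario(noise_sigma = 2e-4, seed = 123)
  expect_identical(gen_ph_trace(ts), gen_ph_trace(ts))
  ps <- quick_panel(c(1, 0.5, 0.2), seed = 123)
  expect_identical(gen_mutant_panel(ps), gen_mutant_panel(ps))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(gen_titration(quick_titration(noise_sigma = 0.02, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("noiseless titration spectra are the exact isotherm mixture", {
  sc <- quick_titration(Kd_mM = 0.5, noise_sigma = 0)
  series <- gen_titration(sc)
  unbound <- band_profile(sc$unbound_band, sc$wavelengths_nm)
  bound <- band_profile(sc$bound_band, sc$wavelengths_nm)
  # at c = 0 the spectrum is the unbound band exactly
  expect_equal(series$absorbance[, 1], unbound, tolerance = 1e-14)
  # at c = Kd the mixture fraction is 1/2: spectrum is the band midpoint
  j <- which.min(abs(sc$concentrations_mM - 0.5))
  f <- sc$concentrations_mM[j] / (0.5 + sc$concentrations_mM[j])
  expect_equal(series$absorbance[, j], (1 - f) * unbound + f * bound,
               tolerance = 1e-14)
})

test_that("empirical noise SD matches the requested sigma within 5%", {
  sc <- quick_titration(noise_sigma = 0.02, seed = 31)
  clean <- gen_titration(scenario_modify(sc, noise_sigma = 0))
  noisy <- gen_titration(sc)
  resid <- noisy$absorbance - clean$absorbance
  expect_gt(length(resid), 1e3)
  expect_equal(stats::sd(resid), 0.02, tolerance = 0.05)
  # transient generator, > 1e4 cells
  pc <- quick_photocycle(noise_sigma = 0.01, seed = 31,
                         times_s = log_grid(1e-5, 4, 400))
  resid2 <- gen_transient(pc)$deltaA -
    gen_transient(scenario_modify(pc, noise_sigma = 0))$deltaA
  expect_gt(length(resid2), 1e4)
  expect_equal(stats::sd(resid2), 0.01, tolerance = 0.05)
})

test_that("noiseless blue-shift difference spectra have the expected lobe order", {
  series <- gen_titration(quick_titration(noise_sigma = 0, shift = "blue"))
  d <- difference_spectra(series)
  wl <- series$wavelengths_nm
  for (j in 2:ncol(d)) {
    expect_lt(wl[which.max(d[, j])], wl[which.min(d[, j])])
  }
})

test_that("transient generator reduces to noise for zero amplitudes and to a
           single exponential for one species", {
  pc0 <- quick_photocycle(tau_s = c(1e-3, 1e-2), amps = c(0, 0),
                          noise_sigma = 0)
  pc0$sads <- lapply(pc0$sads, function(s) {
    s$bleach <- spectral_band(560, 30, 0); s
  })
  pc0 <- scenario_modify(pc0, sads = pc0$sads)
  expect_true(all(gen_transient(pc0)$deltaA == 0))

  pc1 <- quick_photocycle(tau_s = 1, amps = 0.7, noise_sigma = 0)
  d1 <- gen_transient(pc1)
  sads <- scenario_sads_matrix(pc1)
  expect_equal(d1$deltaA, sads %*% t(exp(-outer(d1$times_s, 1))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("invalid scenarios are refused with the field named", {
  expect_error(quick_titration(Kd_mM = -1), "Kd_mM")
  expect_error(quick_titration(noise_sigma = -0.1), "noise_sigma")
  expect_error(titration_scenario(
    model_kind = "two_site", Kd1_mM = 1, Kd2_mM = 2, Vmax1 = 1.5,
    unbound_band = spectral_band(545, 35), bound_band = spectral_band(535, 35)
  ), "Vmax1")
  expect_error(quick_photocycle(tau_s = c(1e-3, -1)), "tau_s")
  expect_error(photocycle_scenario(tau_s = 1, sads = list()), "sads")
  expect_error(transport_scenario(light_on_s = 100, light_off_s = 50),
               "light_on_s")
  expect_error(panel_scenario(c("A", "B"), c(1, 1), c(1, 1), c(1, 1)), "WT")
  expect_error(quick_panel(c(1, 1), n_rep = 2), "n_replicates")
})

test_that("pH traces have the planted slopes and events", {
  sc <- transport_scenario(true_slope_pH_s = 5e-4, drift_slope_pH_s = 0,
                           noise_sigma = 0)
  tr <- gen_ph_trace(sc)
  win <- tr$times_s >= 60 & tr$times_s <= 70
  slope <- stats::coef(stats::lm(tr$pH[win] ~ tr$times_s[win]))[2]
  expect_equal(unname(slope), 5e-4, tolerance = 1e-12)
  # zero transport: flat drift-only trace
  sc0 <- transport_scenario(true_slope_pH_s = 0, drift_slope_pH_s = -1e-4,
                            noise_sigma = 0)
  tr0 <- gen_ph_trace(sc0)
  expect_equal(tr0$pH, 7 - 1e-4 * tr0$times_s, tolerance = 1e-12)
  # drift correction oracle: OLS on the noiseless trace recovers the planted
  # light slope after subtracting the pre-illumination drift
  scd <- transport_scenario(true_slope_pH_s = 5e-4, drift_slope_pH_s = -1e-4,
                            noise_sigma = 0)
  act <- initial_slope(gen_ph_trace(scd))
  expect_equal(act$slope, 5e-4, tolerance = 1e-10)
  expect_equal(act$drift, -1e-4, tolerance = 1e-12)
})

test_that("mutant panels reproduce their truth at zero replicate noise", {
  sc <- quick_panel(c(1, 0.65, 0.33), c(1, 0.08, 0.30), cv = 0)
  panel <- gen_mutant_panel(sc)
  wt_cl <- panel$slope[panel$mutant == "WT" & panel$anion == "Cl"]
  expect_true(all(wt_cl == 5e-4))
  m2_so4 <- panel$slope[panel$mutant == "M2" & panel$anion == "SO4"]
  expect_true(all(m2_so4 == 5e-4 * 0.30))
  # perfectly proportional planted activities give Pearson R = 1 downstream
  scp <- quick_panel(c(1, 0.6, 0.3, 0.1), c(1, 0.6, 0.3, 0.1) * 0.5, cv = 0)
  expect_equal(correlate_anions(gen_mutant_panel(scp))$R, 1, tolerance = 1e-12)
})
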