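test_that("difference spectra subtract the reference column exactly", {
  series <- gen_titration(quick_titration(noise_sigma = 0))
  d <- difference_spectra(series)
  expect_true(all(d[, 1] == 0))
  # identical spectra in every column give all-zero differences
  flat <- spectrum_series(series$wavelengths_nm, series$concentrations_mM,
                          matrix(series$absorbance[, 1],
                                 nrow(series$absorbance),
                                 ncol(series$absorbance)))
  expect_true(all(difference_spectra(flat) == 0))
})

test_that("anion-induced shifts are classified by lobe order", {
  blue <- gen_titration(scenario("WT-Cl", seed = 1))
  expect_identical(classify_shift(difference_spectra(blue),
                                  blue$wavelengths_nm), "blue")
  red <- gen_titration(scenario("WT-SO4", seed = 1))
  expect_identical(classify_shift(difference_spectra(red),
                                  red$wavelengths_nm), "red")
  # a pure-noise series carries no shift
  flat_sc <- quick_titration(noise_sigma = 0.02, seed = 8)
  flat_sc <- scenario_modify(flat_sc, bound_band = flat_sc$unbound_band)
  noise <- gen_titration(flat_sc)
  expect_identical(classify_shift(difference_spectra(noise),
                                  noise$wavelengths_nm), "none")
})

test_that("two-state series have a common crossing, three-state mixtures do not", {
  series <- gen_titration(quick_titration(noise_sigma = 0))
  d <- difference_spectra(series)
  wl <- series$wavelengths_nm
  iso <- find_isosbestic(d, wl, window_nm = c(520, 560))
  expect_false(is.na(iso))
  expect_lt(max(abs(d[which(wl == iso), -1])), 0.05 * max(abs(d)))
  # third state absorbing across the crossing region, growing out of step
  # with the binding fraction: no wavelength stays pinned at zero
  b3 <- band_profile(spectral_band(545, 30, 0.4), wl)
  frac3 <- seq(0, 0.5, length.out = ncol(d))
  mixed <- series$absorbance + outer(b3, frac3)
  d3 <- difference_spectra(spectrum_series(wl, series$concentrations_mM, mixed))
  expect_true(is.na(find_isosbestic(d3, wl, window_nm = c(480, 560))))
  expect_error(find_isosbestic(d, wl, window_nm = c(300, 900)), "window_nm")
})

test_that("noiseless curve extraction reproduces the isotherm to 1e-10", {
  sc <- quick_titration(Kd_mM = 0.5, noise_sigma = 0)
  curve <- extract_curve(gen_titration(sc))
  expect_equal(curve$deltaA,
               isotherm_one_site(curve$concentrations_mM, 0.5),
               tolerance = 1e-10)
  expect_identical(curve$deltaA[1], 0)
  # flat series: nothing to titrate
  flat <- scenario_modify(sc, bound_band = sc$unbound_band)
  expect_error(extract_curve(gen_titration(flat)), "no titratable signal")
})

test_that("the constrained one-site fit is exact on exact data", {
  x <- c(0, log_grid(0.01, 100, 12))
  curve <- titration_curve(x, isotherm_one_site(x, 0.5))
  fit <- fit_one_site(curve)
  expect_equal(fit$Kd_mM, 0.5, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
})

test_that("the one-site fit equals a 1e4-point grid-search oracle", {
  set.seed(21)
  x <- c(0, log_grid(0.01, 1000, 16))
  grid <- log_grid(1e-4, 1e5, 1e4)
  step <- log(grid[2] / grid[1])
  for (rep in 1:10) {
    kd <- exp(stats::runif(1, log(0.05), log(50)))
    y <- isotherm_one_site(x, kd) + stats::rnorm(length(x), sd = 0.03)
    fit <- fit_one_site(titration_curve(x, y))
    rss_grid <- vapply(grid, function(k) sum((y - x / (k + x))^2), numeric(1))
    kd_grid <- grid[which.min(rss_grid)]
    expect_equal(log(fit$Kd_mM), log(kd_grid), tolerance = 2 * step)
    expect_lte(fit$rss, min(rss_grid) + 1e-12)
  }
})

test_that("the two-site fit recovers exact parameters to 1e-6", {
  x <- c(0, log_grid(0.001, 1000, 20))
  curve <- titration_curve(x, isotherm_two_site(x, 0.1, 10, 0.6))
  fit <- fit_two_site(curve)
  expect_equal(fit$Kd1_mM, 0.1, tolerance = 1e-6)
  expect_equal(fit$Kd2_mM, 10, tolerance = 1e-6)
  expect_equal(fit$Vmax1, 0.6, tolerance = 1e-6)
  expect_equal(fit$scale, 1, tolerance = 1e-6)
  expect_lte(fit$Kd1_mM, fit$Kd2_mM)
})

test_that("the two-site model reduces to one-site at equal Kds", {
  x <- c(0, log_grid(1e-3, 1e4, 50))
  expect_equal(isotherm_two_site(x, 2.5, 2.5, 0.37),
               isotherm_one_site(x, 2.5), tolerance = 1e-12)
})

test_that("both isotherms half-saturate at their Kd and rise monotonically", {
  expect_identical(isotherm_one_site(0.59, 0.59), 0.5)
  expect_identical(isotherm_two_site(0.7, 0.7, 5, 1), 0.5)
  x <- log_grid(1e-4, 1e5, 200)
  for (f in list(function(z) isotherm_one_site(z, 0.59),
                 function(z) isotherm_two_site(z, 0.094, 2.2, 0.6))) {
    y <- f(x)
    expect_true(all(diff(y) > 0))
    expect_identical(f(0), 0)
    expect_equal(f(1e12), 1, tolerance = 1e-6)
  }
})

test_that("model selection prefers the true model class", {
  # one-site truth
  curve1 <- extract_curve(gen_titration(quick_titration(Kd_mM = 0.6,
                                                        noise_sigma = 0)))
  expect_identical(select_model(curve1)$model_kind, "one_site")
  # well-separated two-site truth at realistic noise, majority over seeds
  picks <- vapply(1:10, function(s) {
    curve <- extract_curve(gen_titration(quick_two_site(noise_sigma = 0.02,
                                                        seed = s)))
    select_model(curve)$model_kind
  }, character(1))
  expect_gte(mean(picks == "two_site"), 0.8)
  # a 4-point curve cannot support the two-site fit
  x4 <- c(0, 0.1, 1, 10)
  curve4 <- titration_curve(x4, isotherm_one_site(x4, 0.5))
  expect_warning(sel <- select_model(curve4), "one-site")
  expect_identical(sel$model_kind, "one_site")
  # one-site data fitted as two-site never wins the AICc comparison
  aicc_votes <- vapply(1:10, function(s) {
    curve <- extract_curve(gen_titration(quick_titration(
      Kd_mM = 0.6, noise_sigma = 0.02, seed = s)))
    fit_two_site(curve)$aicc > fit_one_site(curve)$aicc - 2
  }, logical(1))
  expect_gte(mean(aicc_votes), 0.8)
})

test_that("fit preconditions name the offending field", {
  x <- c(0, 0.1, 1)
  expect_error(fit_one_site(titration_curve(x, isotherm_one_site(x, 1))),
               "concentrations_mM")
  x5 <- c(0, 0.1, 1, 10)
  expect_error(fit_two_site(titration_curve(x5, isotherm_one_site(x5, 1))),
               "concentrations_mM")
})
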