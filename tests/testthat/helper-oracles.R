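# Independent oracles and compact scenario builders used across the suite.

tmp_file <- function(name) {
  d <- tempfile("hp")
  dir.create(d)
  file.path(d, name)
}

tmp_dir <- function(name) {
  d <- file.path(tempfile("hp"), name)
  dir.create(d, recursive = TRUE)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classical RK4 integration of the irreversible sequential chain
# dc1/dt = -c1/tau1; dcj/dt = c_{j-1}/tau_{j-1} - c_j/tau_j.
# Deliberately independent of the package's closed-form Bateman solution.
rk4_concentrations <- function(tau_s, times_s, n_sub = 400) {
  n <- length(tau_s)
  k <- 1 / tau_s
  deriv <- function(c) {
    inflow <- c(0, k[-n] * c[-n])
    inflow - k * c
  }
  out <- matrix(NA_real_, n, length(times_s))
  state <- c(1, rep(0, n - 1))
  t_cur <- 0
  for (j in seq_along(times_s)) {
    target <- times_s[j]
    steps <- max(1L, ceiling((target - t_cur) / (min(tau_s) / 20)))
    steps <- min(steps, n_sub * 50L)
    h <- (target - t_cur) / steps
    if (h > 0) {
      for (s in seq_len(steps)) {
        k1 <- deriv(state)
        k2 <- deriv(state + h / 2 * k1)
        k3 <- deriv(state + h / 2 * k2)
        k4 <- deriv(state + h * k3)
        state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t_cur <- target
    }
    out[, j] <- state
  }
  out
}

# Small, fast titration scenario (coarser wavelength grid than the catalog).
quick_titration <- function(Kd_mM = 0.5, noise_sigma = 0, seed = 1,
                            shift = "blue", n_conc = 16,
                            c_range = c(0.01, 1000), ...) {
  bound_max <- if (shift == "blue") 535 else 560
  titration_scenario(
    model_kind = "one_site", Kd_mM = Kd_mM, shift_direction = shift,
    unbound_band = spectral_band(545, 35, 1),
    bound_band = spectral_band(bound_max, 35, 1),
    concentrations_mM = c(0, log_grid(c_range[1], c_range[2], n_conc)),
    wavelengths_nm = seq(420, 680, by = 4),
    noise_sigma = noise_sigma, seed = seed, ...
  )
}

quick_two_site <- function(Kd1_mM = 0.1, Kd2_mM = 10, Vmax1 = 0.6,
                           noise_sigma = 0, seed = 1) {
  titration_scenario(
    model_kind = "two_site", Kd1_mM = Kd1_mM, Kd2_mM = Kd2_mM, Vmax1 = Vmax1,
    shift_direction = "blue",
    unbound_band = spectral_band(545, 35, 1),
    bound_band = spectral_band(535, 35, 1),
    concentrations_mM = c(0, log_grid(0.001, 1000, 20)),
    noise_sigma = noise_sigma, seed = seed
  )
}

# Small photocycle scenario: 2 or 3 species, coarse grids.
quick_photocycle <- function(tau_s = c(1e-3, 1e-2, 1e-1),
                             amps = c(0.8, 0.9, 0.55),
                             noise_sigma = 0, seed = 1,
                             times_s = log_grid(1e-5, 4, 60)) {
  peaks <- c(600, 460, 620)[seq_along(tau_s)]
  sads <- lapply(seq_along(tau_s), function(j) {
    list(positive = spectral_band(peaks[j], 30, amps[j]),
         bleach = spectral_band(560, 30, 1))
  })
  photocycle_scenario(tau_s = tau_s, sads = sads,
                      labels = paste0("S", seq_along(tau_s)),
                      times_s = times_s,
                      noise_sigma = noise_sigma, seed = seed)
}

# Simple balanced mutant panel around a WT slope.
quick_panel <- function(rel_cl, rel_so4 = rel_cl, expression = NULL,
                        cv = 0.1, n_rep = 4, seed = 1, wt_slope = 5e-4) {
  m <- length(rel_cl)
  names_m <- c("WT", paste0("M", seq_len(m - 1)))
  if (is.null(expression)) expression <- rep(1, m)
  panel_scenario(names_m, wt_slope * rel_cl, wt_slope * rel_so4,
                 expression, n_replicates = n_rep, replicate_cv = cv,
                 seed = seed)
}
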