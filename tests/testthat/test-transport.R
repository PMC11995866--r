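test_that("the slope estimator is exact on noiseless piecewise-linear traces", {
  sc <- transport_scenario(true_slope_pH_s = 5e-4, drift_slope_pH_s = -1e-4,
                           noise_sigma = 0)
  act <- initial_slope(gen_ph_trace(sc))
  expect_equal(act$slope, 5e-4, tolerance = 1e-12)
  expect_equal(act$drift, -1e-4, tolerance = 1e-12)
  expect_equal(act$raw_slope, 4e-4, tolerance = 1e-12)
  # uncorrected mode reports the raw window slope
  raw <- initial_slope(gen_ph_trace(sc), drift_correct = FALSE)
  expect_equal(raw$slope, 4e-4, tolerance = 1e-12)
  # alkalization positive, acidification negative
  neg <- transport_scenario(true_slope_pH_s = -3e-4, noise_sigma = 0)
  expect_equal(initial_slope(gen_ph_trace(neg))$slope, -3e-4,
               tolerance = 1e-12)
})

test_that("slope windows are validated and truncated at light-off", {
  sc <- transport_scenario(noise_sigma = 0, light_on_s = 60, light_off_s = 65,
                           duration_s = 120)
  expect_warning(act <- initial_slope(gen_ph_trace(sc)), "truncated")
  expect_equal(act$window_s, 5)
  short <- transport_scenario(noise_sigma = 0, light_on_s = 10,
                              light_off_s = 60, duration_s = 120)
  expect_error(initial_slope(gen_ph_trace(short)), "30 s")
  sparse <- transport_scenario(noise_sigma = 0, sample_interval_s = 5)
  expect_error(initial_slope(gen_ph_trace(sparse), window_s = 10), "window")
})

test_that("noisy slopes stay within 10% at the assay's noise level", {
  slopes <- vapply(1:20, function(s) {
    sc <- transport_scenario(true_slope_pH_s = 5e-4, noise_sigma = 2e-4,
                             seed = s)
    initial_slope(gen_ph_trace(sc))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) / 5e-4 - 1), 0.10)
})

test_that("expression normalization rescales activities as expected", {
  sc <- quick_panel(c(1, 1, 0.2), expression = c(1, 0.5, 1), cv = 0)
  norm <- normalize_panel(gen_mutant_panel(sc))
  m1 <- norm[norm$mutant == "M1" & norm$anion == "Cl", ]
  # expression one-half doubles the normalized slope: back to WT level
  expect_equal(m1$relative_to_wt, 1 / 0.5, tolerance = 1e-12)
  expect_equal(norm$relative_to_wt[norm$mutant == "WT"], c(1, 1))
  # K33A-like mutant: half expression, WT-level intrinsic activity
  sck <- quick_panel(c(1, 0.5), expression = c(1, 0.5), cv = 0)
  normk <- normalize_panel(gen_mutant_panel(sck))
  expect_equal(normk$relative_to_wt[normk$mutant == "M1"], c(1, 1),
               tolerance = 1e-12)
  # scale equivariance: multiplying all expressions by k divides activities by k
  panel <- gen_mutant_panel(quick_panel(c(1, 0.6, 0.3), cv = 0.05))
  panel2 <- panel
  panel2$expression <- panel2$expression * 3
  expect_equal(normalize_panel(panel2)$mean, normalize_panel(panel)$mean / 3,
               tolerance = 1e-12)
})

test_that("many-to-one comparison flags a strong loss of activity", {
  sc <- quick_panel(c(1, 1, 0.1), cv = 0.1, seed = 5)
  set.seed(1)
  res <- compare_to_wt(gen_mutant_panel(sc), "Cl", n_perm = 499)
  expect_setequal(res$mutant, c("M1", "M2"))
  expect_true(res$significant[res$mutant == "M2"])
  expect_false(res$significant[res$mutant == "M1"])
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
})

test_that("a single mutant reduces to an unadjusted two-sample permutation test", {
  sc <- quick_panel(c(1, 0.4), cv = 0.1, seed = 3)
  panel <- gen_mutant_panel(sc)
  set.seed(9)
  res <- compare_to_wt(panel, "Cl", n_perm = 999)
  # manual unadjusted permutation test with the same statistic
  sub <- panel[panel$anion == "Cl", ]
  v <- sub$slope / sub$expression
  g <- sub$mutant
  tstat <- function(vv, gg) {
    a <- vv[gg == "WT"]; b <- vv[gg != "WT"]
    sp <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    abs(mean(b) - mean(a)) / sqrt(sp * (1 / length(a) + 1 / length(b)))
  }
  obs <- tstat(v, g)
  set.seed(9)
  null <- replicate(999, tstat(sample(v), g))
  p_manual <- (1 + sum(null >= obs)) / 1000
  expect_equal(res$p_adj, p_manual, tolerance = 1e-12)
})

test_that("mutants with too few replicates are skipped with a warning", {
  panel <- gen_mutant_panel(quick_panel(c(1, 0.5, 0.2), cv = 0.1))
  panel <- panel[!(panel$mutant == "M1" & panel$replicate > 2), ]
  set.seed(2)
  expect_warning(res <- compare_to_wt(panel, "Cl", n_perm = 199), "M1")
  expect_false("M1" %in% res$mutant)
})

test_that("cross-anion correlation behaves like Pearson's R", {
  prop <- gen_mutant_panel(quick_panel(c(1, 0.7, 0.4, 0.1),
                                       c(1, 0.7, 0.4, 0.1) * 0.6, cv = 0))
  expect_equal(correlate_anions(prop)$R, 1, tolerance = 1e-12)
  anti <- gen_mutant_panel(quick_panel(c(0.1, 0.4, 0.7, 1),
                                       c(1, 0.7, 0.4, 0.1), cv = 0))
  expect_equal(correlate_anions(anti)$R, -1, tolerance = 1e-12)
  # invariance under affine rescaling of one axis
  panel <- gen_mutant_panel(quick_panel(c(1, 0.8, 0.5, 0.2, 0.1), cv = 0.1))
  base <- correlate_anions(panel)$R
  panel2 <- panel
  sel <- panel2$anion == "SO4"
  panel2$slope[sel] <- 3 * panel2$slope[sel] + 2e-4 * panel2$expression[sel]
  expect_equal(correlate_anions(panel2)$R, base, tolerance = 1e-10)
  # degenerate input: no variance across mutants
  flat <- gen_mutant_panel(quick_panel(c(1, 1, 1), cv = 0))
  expect_error(correlate_anions(flat), "variance")
})
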