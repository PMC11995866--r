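#!/usr/bin/env Rscript
# Stage 3: photocycle kinetics. Global three-exponential fits of the
# simulated flash-photolysis matrices, intermediate assignment from the
# species-associated difference spectra, and O-intermediate accumulation
# calls. Run 01_simulate_datasets.R first.

suppressPackageStartupMessages(library(halopump))

in_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

cases <- list(
  list(name = "WT-NaCl-photocycle", truth_ms = c(0.050, 2.2, 12)),
  list(name = "H167Q-photocycle", truth_ms = c(0.20, 16, 65)),
  list(name = "H167A-photocycle", truth_ms = c(0.050, 2.2, 12)),
  list(name = "H167I-photocycle", truth_ms = c(0.050, 2.2, 12))
)

rows <- list()
for (case in cases) {
  data <- read_matrix_csv(file.path(in_dir, paste0(case$name, ".csv")),
                          "transient")
  fit <- suppressWarnings(fit_global(data, n_exp = 3))
  o <- suppressWarnings(detect_o_accumulation(fit))
  labels <- if (fit$degenerate) rep(NA_character_, 3) else
    assign_intermediates(fit)$scheme$labels
  cat(sprintf("%-20s tau = %s ms  labels %s  O %s (score %.2f)%s\n",
              case$name,
              paste(signif(1000 * fit$scheme$tau_s, 3), collapse = " / "),
              paste(labels, collapse = ","),
              ifelse(o$accumulating, "accumulating", "absent"), o$score,
              ifelse(fit$converged, "", "  [flagged: not converged]")))
  rows[[case$name]] <- data.frame(
    scenario = case$name,
    tau1_ms = 1000 * fit$scheme$tau_s[1],
    tau2_ms = 1000 * fit$scheme$tau_s[2],
    tau3_ms = 1000 * fit$scheme$tau_s[3],
    planted_tau2_ms = case$truth_ms[2],
    planted_tau3_ms = case$truth_ms[3],
    o_accumulating = o$accumulating, o_score = o$score,
    rss = fit$rss, converged = fit$converged, degenerate = fit$degenerate
  )
  # persist the full fit record (taus in seconds, spectra as CSV)
  rec <- result_record(
    stage = "photocycle",
    inputs = list(data = file.path(in_dir, paste0(case$name, ".csv"))),
    parameters = list(n_exp = 3),
    outputs = list(tau_s = fit$scheme$tau_s, labels = labels, rss = fit$rss,
                   converged = fit$converged,
                   o_accumulating = o$accumulating, o_score = o$score),
    seed = 1
  )
  write_result_json(rec, file.path("results",
                                   paste0(case$name, "_fit.json")))
}

tab <- do.call(rbind, rows)
rownames(tab) <- NULL
utils::write.csv(tab, "results/photocycle_fits.csv", row.names = FALSE)
cat("fit table written to results/photocycle_fits.csv\n")

# Note: the O-free mutants carry only two real kinetic components, so the
# third fitted tau there parameterizes noise; their time constants are
# reported but only the classification is interpreted.
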