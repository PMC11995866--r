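#!/usr/bin/env Rscript
# Stage 1: materialize the scenario catalog as CSV datasets under
# results/data/. Every downstream stage can be rerun from these files; the
# generators are seeded, so this stage is fully reproducible.

suppressPackageStartupMessages(library(halopump))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

titrations <- c("WT-Cl", "WT-SO4", "R71A-Cl", "H167A-SO4",
                "WT-Cl-two-site", "WT-SO4-two-site")
for (nm in titrations) {
  series <- gen_titration(scenario(nm))
  write_titration_csv(series, file.path(out_dir, paste0(nm, ".csv")))
  cat(sprintf("titration %-16s %3d wavelengths x %2d concentrations\n", nm,
              length(series$wavelengths_nm), length(series$concentrations_mM)))
}

photocycles <- c("WT-NaCl-photocycle", "H167Q-photocycle",
                 "H167A-photocycle", "H167I-photocycle")
for (nm in photocycles) {
  data <- gen_transient(scenario(nm))
  write_transient_csv(data, file.path(out_dir, paste0(nm, ".csv")))
  cat(sprintf("transient %-16s %3d wavelengths x %2d times (%.2g-%g s)\n", nm,
              length(data$wavelengths_nm), length(data$times_s),
              min(data$times_s), max(data$times_s)))
}

trace <- gen_ph_trace(scenario("WT-pH-trace"))
write_ph_csv(trace, file.path(out_dir, "WT-pH-trace.csv"))
cat(sprintf("pH trace: %d samples, light on %g-%g s\n",
            length(trace$times_s), trace$light_on_s, trace$light_off_s))

panel <- gen_mutant_panel(scenario("alanine-panel"))
write_panel_csv(panel, file.path(out_dir, "alanine-panel.csv"))
cat(sprintf("mutant panel: %d mutants x 2 anions x %d replicates\n",
            length(unique(panel$mutant)), max(panel$replicate)))

cat("datasets written to", out_dir, "\n")
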