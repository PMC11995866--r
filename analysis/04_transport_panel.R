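#!/usr/bin/env Rscript
# Stage 4: transport activities. Initial-slope statistic on the pH trace,
# expression normalization of the mutant panel, permutation many-to-one
# comparison against WT (family-wise 0.05), and the chloride-vs-sulfate
# activity correlation. Run 01_simulate_datasets.R first.

suppressPackageStartupMessages(library(halopump))

in_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

trace <- read_ph_csv(file.path(in_dir, "WT-pH-trace.csv"))
act <- initial_slope(trace)
cat(sprintf("pH trace: initial slope %.3g pH/s over %g s (drift %.2g pH/s)\n",
            act$slope, act$window_s, act$drift))

panel <- read_panel_csv(file.path(in_dir, "alanine-panel.csv"))
norm <- normalize_panel(panel)

set.seed(1)
sig <- do.call(rbind, lapply(c("Cl", "SO4"), function(an) {
  res <- compare_to_wt(panel, an, n_perm = 1999)
  res$anion <- an
  res
}))

tab <- merge(norm, sig[, c("mutant", "anion", "p_adj", "significant")],
             by = c("mutant", "anion"), all.x = TRUE)
tab$relative_pct <- 100 * tab$relative_to_wt
tab <- tab[order(tab$mutant != "WT", tab$mutant, tab$anion), ]
utils::write.csv(tab, "results/transport_activity.csv", row.names = FALSE)

cat("\nmutants significantly different from WT (p_adj < 0.05):\n")
hit <- tab[!is.na(tab$significant) & tab$significant, ]
for (i in seq_len(nrow(hit))) {
  cat(sprintf("  %-6s %-3s %5.1f%% of WT (p_adj = %.3g)\n", hit$mutant[i],
              hit$anion[i], hit$relative_pct[i], hit$p_adj[i]))
}

corr <- correlate_anions(panel)
cat(sprintf("\nCl vs SO4 normalized activity: R = %.2f (p = %.2g, n = %d)\n",
            corr$R, corr$p_value, corr$n))
write_result_json(result_record(
  stage = "correlation",
  inputs = list(panel = file.path(in_dir, "alanine-panel.csv")),
  parameters = list(exclude = character(0)),
  outputs = unclass(corr), seed = 1
), "results/correlation.json")
cat("tables written to results/transport_activity.csv and results/correlation.json\n")
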