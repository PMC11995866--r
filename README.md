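# halopump

Kinetic, binding and transport analysis for light-driven anion-pump
rhodopsins.

Microbial rhodopsins of the halorhodopsin family pump anions (Cl⁻, Br⁻ and,
in the cyanobacterial pump studied here, even divalent SO₄²⁻) into the cell
after absorbing a photon. Characterizing such a pump rests on three
quantitative measurements, and this package implements the full analysis
chain for all three, aimed at spectroscopists and protein biophysicists
working with flash photolysis, titration and cell-suspension transport
assays:

* **Photocycle kinetics.** Flash-induced difference absorbance
  ΔA(λ, t) is modeled as an irreversible sequential chain
  K → L → O → ground with first-order decays. Concentrations follow the
  closed-form Bateman solution; a global fit shares the time constants
  across all wavelengths and solves the per-wavelength amplitudes exactly
  at each step (variable projection):
  ΔA(λ, t) = Σᵢ DADSᵢ(λ) e^(−t/τᵢ).
  Species-associated difference spectra (SADS) follow by an exact linear
  map, photointermediates are labeled from their band positions, and
  accumulation of the red-shifted O intermediate is scored against the
  bleach depth.
* **Anion binding.** Titration spectra are reduced to a normalized curve at
  the difference-spectrum peak and fitted with the constrained isotherms
  ΔA = x/(K_d + x) (amplitude fixed at 1) and
  ΔA = V₁·x/(K_d1 + x) + (1 − V₁)·x/(K_d2 + x), with AICc model selection,
  shift classification (blue/red) and an isosbestic-point two-state check.
* **Transport activity.** Light-induced extracellular pH traces yield the
  0–10 s initial-slope statistic (drift-corrected OLS); mutant panels are
  normalized by expression, compared against wild type with a permutation
  maxT many-to-one test (a distribution-free analogue of Dunnett's test),
  and the chloride–sulfate activity correlation is quantified by Pearson R.

Every stage has a seeded synthetic-data generator
(`gen_titration()`, `gen_transient()`, `gen_ph_trace()`,
`gen_mutant_panel()`) with known ground truth, plus a catalog of default
scenarios planted at the reported wild-type and mutant parameter values
(`scenario_catalog()`), so each estimator is validated by parameter
recovery.

## Worked example

```r
library(halopump)

# --- anion titration: wild-type-like chloride binding -----------------
series <- gen_titration(scenario("WT-Cl", seed = 1))
curve  <- extract_curve(series)
fit    <- select_model(curve)
fit
#> One-site isotherm fit: Kd = 0.5336 mM (rss 0.0222, AICc -108)
classify_shift(difference_spectra(series), series$wavelengths_nm)
#> [1] "blue"

# --- photocycle: global 3-exponential fit -----------------------------
data <- gen_transient(scenario("WT-NaCl-photocycle", seed = 1))
pfit <- assign_intermediates(fit_global(data, n_exp = 3))
pfit$scheme
#> Sequential scheme: K (tau 0.04984 ms) -> L (tau 2.205 ms) -> O (tau 12.1 ms) -> ground
detect_o_accumulation(pfit)$score
#> [1] 0.5232
```

The titration was generated with a planted K_d of 0.59 mM and per-cell
noise of 0.02 absorbance units; the single-seed fit recovers 0.53 mM, and
averaging over 20 seeds recovers the plant within a few percent. The
transient matrix was planted at decay time constants of 0.050, 2.2 and
12 ms for the K, L and O intermediates; the fit recovers them to better
than 1% and scores O accumulation at ≈ 0.52 of the bleach depth
(threshold 0.10).

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
sequence, each a thin script over the package functions that prints what it
found and writes tables under `results/`:

```sh
Rscript analysis/01_simulate_datasets.R    # catalog scenarios -> results/data/*.csv
Rscript analysis/02_binding_titrations.R   # shifts, isosbestic, Kd fits -> binding_fits.csv
Rscript analysis/03_photocycle_kinetics.R  # global fits, O calls -> photocycle_fits.csv
Rscript analysis/04_transport_panel.R      # slopes, Dunnett-style flags, R -> transport_activity.csv
```

A declarative alternative is `run_pipeline()` with a YAML config; a demo
config ships at `inst/extdata/demo_pipeline.yaml`.

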