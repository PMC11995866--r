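---
title: "Models and methods: photocycle kinetics, anion binding and transport activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: photocycle kinetics, anion binding and transport activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halopump)
```

halopump implements the quantitative analysis chain used to characterize
light-driven anion-pump rhodopsins — proteins such as the cyanobacterial
halorhodopsin that pump Cl⁻ (and, uniquely, SO₄²⁻) inward after absorbing a
photon. Three measurement types are covered, each with a seeded synthetic
generator so that every estimator can be validated by parameter recovery:

1. **Flash photolysis / photocycle kinetics** — global multi-exponential
   fitting of transient absorption matrices under an irreversible sequential
   scheme, with decay- and species-associated difference spectra (DADS/SADS),
   intermediate assignment and O-intermediate accumulation detection.
2. **Anion titrations** — difference spectra, shift classification,
   isosbestic-point checks, and constrained one-/two-site binding-isotherm
   fits with AICc model selection.
3. **Transport assays** — the 0–10 s initial-slope statistic on light-induced
   extracellular pH traces, expression normalization, permutation many-to-one
   comparison against wild type, and the chloride–sulfate activity
   correlation.

## The sequential photocycle model

After an instantaneous photoexcitation the pigment traverses a chain of
spectroscopically distinct intermediates, K → L → O → ground state, each
decaying first-order with time constant $\tau_j$. With the first intermediate
at unit concentration at $t = 0$, the concentrations obey

$$c_1(t) = e^{-t/\tau_1}, \qquad
\frac{dc_j}{dt} = \frac{c_{j-1}}{\tau_{j-1}} - \frac{c_j}{\tau_j},\; c_j(0)=0,$$

whose closed form (the Bateman solution for a radioactive-decay-style chain)
is a linear combination of the exponentials $e^{-t/\tau_i}$, $i \le j$.
`bateman_concentrations()` evaluates it analytically; the unit tests verify
it against an independent Runge–Kutta integration. Exactly coincident time
constants make the exponential expansion singular; they are handled by a
$10^{-9}$ relative split of the rates, which is numerically indistinguishable
from the analytic repeated-root limit at the package's tolerances (the
continuity test asserts this at $\tau_2/\tau_1 = 1 + 10^{-6}$).

Modeling choices worth stating:

* **Photoexcitation is treated as instantaneous.** The earliest simulated
  observation is 0.01 ms and K formation is unresolved at that resolution,
  so the chain starts in K with unit concentration.
* **Three observable species.** The N/O distinction made in some
  photocycle schemes is collapsed into a single red-shifted species; nothing
  in a three-exponential fit of these data can separate them.
* **No instrument response, photoselection or branching.** Out of scope.

### Global fitting by variable projection

The measured matrix is modeled as
$\Delta A(\lambda, t) = \sum_i \mathrm{DADS}_i(\lambda)\, e^{-t/\tau_i}$
with the $\tau_i$ shared across all wavelengths. For fixed taus the
amplitudes are a linear least-squares problem solved exactly per wavelength
(variable projection), so the nonlinear search runs over only `n_exp`
log-parameterized time constants. Numerical safeguards, each of which proved
necessary on synthetic data:

* **Multi-start.** Eight deterministic starts spanning quantile ranges of
  the log time grid; best residual sum of squares wins, ties broken by the
  lexicographically smallest tau vector. Fitted taus are reported sorted
  ascending, which fixes the labeling order.
* **Observability bounds.** Taus are constrained to
  $[t_{\min}/7,\; 20\,t_{\max}]$ and any component that has decayed to below
  $10^{-3}$ of its initial value before the first sample is rejected inside
  the objective. Without this, a fit with one superfluous exponential (for
  example a three-exponential fit of a photocycle whose O amplitude is zero)
  can park a "ghost" tau far below the first observation and pay for a tiny
  noise improvement with astronomically scaled amplitudes.
* **Degeneracy flag.** Fitted taus within a ratio of 1.05 are flagged; the
  DADS→SADS map is ill-conditioned there, and `detect_o_accumulation()`
  then drops the component with the smallest DADS norm before deriving
  SADS.
* **Unweighted least squares** on the log-spaced samples as provided; no
  time reweighting is applied.

SADS follow from DADS through the exact linear map given by the Bateman
coefficients (`dads_from_sads()` / `sads_from_dads()`); reconstruction from
either representation agrees to $10^{-10}$.

### Intermediate assignment and O detection

Species are labeled from their SADS: the earliest (fastest) species with a
positive band red of its own bleach is K-like; a positive maximum in
440–500 nm is L-like and in 590–640 nm O-like; labels are never duplicated
and a species without a positive lobe is "bleach-only". O accumulation is
scored as the largest positive SADS amplitude in 590–640 nm (any species)
relative to the bleach depth in 520–590 nm; the default decision threshold
of 0.10 was chosen so that the catalog's O-forming scenarios (score ≈ 0.5)
and O-free scenarios (score ≈ noise, < 0.05) separate with a wide margin,
and it is configurable.

## Binding isotherms

Anion binding shifts the visible absorption band (blue for Cl⁻, red for
SO₄²⁻ in the wild-type protein). The absorbance change at the tracked peak
of the difference spectrum follows, for a single site,

$$\Delta A(x) = V_{\max}\,\frac{x}{K_d + x},$$

and for two sites

$$\Delta A(x) = V_{\max,1}\frac{x}{K_{d1}+x} + V_{\max,2}\frac{x}{K_{d2}+x},$$

with $V_{\max}$ (respectively $V_{\max,1}+V_{\max,2}$) fixed at 1. The fits
are in linear concentration space with the 0 mM point included; no Hill
exponent is used (both equations are hyperbolic). $K_d$s are
log-parameterized; the two-site fit uses a deterministic multi-start and
reports $K_{d1} \le K_{d2}$. Model choice uses small-sample-corrected AIC
with a parsimony margin: two-site is returned only when its AICc is better
by more than 2.

### Normalization and the difference-measurement nuisance

The amplitude-fixed-at-1 constraint requires a normalized curve.
`extract_curve()` divides by the fitted plateau of a provisional fit rather
than by the largest observed point, so the constraint stays self-consistent
when the highest concentration is sub-saturating. Two further choices were
forced by the statistics of difference measurements and are worth spelling
out because they materially change recovery accuracy:

* **Selection/read decoupling.** The tracked wavelength is the largest-|ΔA|
  lobe of the highest-concentration difference spectrum. Picking the argmax
  of the raw noisy column couples the choice to the noise realization at
  that cell — noise the reference column shares with *every* concentration —
  and biased recovered $K_d$s by tens of percent in simulation. The peak is
  therefore located on a smoothed copy of alternate grid cells, and ΔA is
  read from the complementary cells, averaged over a ±10 nm bandwidth. For
  a two-state series the difference-spectrum shape is concentration
  independent, so any fixed read weighting rescales the curve without
  distorting the isotherm.
* **Shared-offset correction.** The reference spectrum's noise at the read
  window enters all non-reference columns identically — a random constant
  offset on every $x > 0$ point. The provisional fit therefore includes an
  offset nuisance for the $x > 0$ points, shrunk by a single zero
  pseudo-observation (the offset has the same sampling variance as one
  point's read noise, making that its natural ridge weight), with a two-site
  shape (which nests one-site) so a genuine high-affinity component is not
  absorbed into the nuisance. The offset-corrected curve is then normalized
  by a one-site plateau; the two-site fitter additionally profiles a free
  overall scale, so its shape parameters are insensitive to residual
  normalization error. The reported models remain exactly the two equations
  above.

The isosbestic check accepts a common crossing when the worst |ΔA| across
columns at the best wavelength is below 5% of the global |ΔA| maximum,
widened to three robust noise SDs for noisy data; absence of a crossing is
the package's diagnostic for a non-two-state series.

## Transport statistics

The transport readout is indirect: light-driven anion uptake drives a
secondary H⁺ influx (amplified by the protonophore CCCP), observed as an
extracellular pH increase. The activity statistic is the OLS slope of pH
over the first 10 s of illumination, minus the pre-illumination drift slope
(the assay's baselines drift; an uncorrected mode is available). Alkalization
is positive by convention, and traces with decreasing pH report negative
activity rather than a magnitude.

Replicate slopes are divided by relative expression (WT = 1) before
averaging; mean ± SD with n is reported along with activity relative to WT.
Mutant-vs-WT comparisons control the family-wise error at 0.05 in the
spirit of Dunnett's many-to-one test, but via a permutation maxT null
(group labels permuted jointly, the maximum absolute pooled-variance t over
the family recorded) — at n = 3–5 replicates the multivariate-t quantiles
of the tabulated test rest on normality that cannot be checked, while the
permutation version is exact under exchangeability. The null simulation in
the test suite bounds the realized family-wise error at ≤ 0.07 for nominal
0.05. The chloride–sulfate correlation is a plain Pearson R over per-mutant
normalized means with an OLS line, excluding nothing by default.

## What the synthetic generators emulate — and what they do not

* **Titrations**: Gaussian absorption bands *in wavelength space* (a
  modeling convenience; real retinal-protein bands are asymmetric and more
  naturally Gaussian in energy), mixed by the exact isotherm, with
  homoscedastic Gaussian noise per cell. Catalog scenarios plant the
  reported dissociation constants (WT 0.59 mM Cl⁻ / 3.6 mM SO₄²⁻, R71A
  4.5 mM Cl⁻, H167A 6.5 mM SO₄²⁻; two-site 0.094/2.2 mM Cl⁻ and
  1.2/82 mM SO₄²⁻ with an arbitrary amplitude split of 0.6/0.4, since no
  split is reported) on 16 log-spaced concentrations 0.01–1000 mM
  (20 points, 0.001–1000 mM for two-site) at noise SD 0.02 (0.01)
  absorbance. Band maxima are approximate — the source measurements report
  them only as "around" values — and the unphotolyzed maximum is taken as
  545 nm with ±10–15 nm shifts.
* **Photocycles**: three-species sequential chains on 420–710 nm at 10 nm
  and 60 log-spaced times over 0.01 ms–4 s, planted at the reported time
  constants (wild type 0.050/2.2/12 ms in NaCl; H167Q 0.20/16/65 ms), with
  noise at 1% of the peak |ΔA|. The O-free mutants (H167A, H167I) are
  planted with zero O amplitude *and* a bleach-only K spectrum, mirroring
  the observation that those mutants show only the ~560 nm depletion and an
  L band; a red-shifted K lobe would spill into the 590–640 nm detection
  window and is not seen in those mutants' spectra.
* **pH traces**: linear drift, a linear light-on rise, single-exponential
  post-illumination relaxation (the relaxation shape does not enter the
  0–10 s statistic), Gaussian noise, 1 Hz sampling.
* **Panels**: per-replicate slopes with fractional Gaussian noise
  (CV 0.1, n = 4 by default, within the reported n = 3–5), expression
  levels fixed and known (the half-expression K33A-like entry plants half
  the observed slope with WT-like intrinsic activity).

Not emulated: photoselection/anisotropy, instrument-response convolution,
shot noise or any heteroscedasticity, band asymmetry, pH-dependent
protonation of the Schiff base, and biological-vs-technical replicate
structure. Passing recovery tests therefore demonstrate estimator
correctness under the stated noise model, not robustness to every
instrumental artifact of real spectrometers.

## Problem sizes and reproducibility

Recovery suites use 20 seeded replicates per condition (the acceptance
script's `--seed` offsets the whole block), titration grids of 151
wavelengths × 17–21 concentrations, transient matrices of 30 × 60, null
simulations of 500 panels with 199-permutation tests, and a
10⁴-point grid-search oracle for the one-site fit — sizes at which the full
suite runs in about a minute on one core while leaving every statistical
check well-powered. All generators restore the caller's RNG state; identical
scenario + seed gives bit-identical data.

## Known limitations

* The sequential scheme is irreversible and unbranched; back-reactions or
  parallel cycles would bias the taus in ways the fit cannot flag.
* With an O-free photocycle, a three-exponential fit has one surplus
  component; its tau is a noise parameter and only the classification (not
  that tau) should be interpreted.
* The one-site fit's accuracy depends on the normalization plateau; at very
  sub-saturating titrations (max concentration below ~2 Kd) the plateau and
  Kd become jointly weakly identified.
* The permutation test assumes exchangeability of replicates across groups
  under the null; heteroscedastic replicate noise between mutants would
  inflate its error rate.
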