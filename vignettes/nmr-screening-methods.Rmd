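---
title: "Methods: 1H-NMR cohort screening with NMRScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1H-NMR cohort screening with NMRScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`NMRScreen` implements the analysis chain used in ¹H-NMR metabolomics of
two-group longitudinal cohorts: preprocessing of 1D spectra into a
feature matrix, latent-variable modelling per comparison, a
multi-criterion differential-metabolite screen, and pathway
over-representation. This vignette is the package's account of the
methods, their assumptions, the tunable parameters, and the choices made
where the underlying procedure left the design open.

## Study design and data model

The emulated design has two groups — normoxic control (C) and chronic
hypoxia (H) — sampled on gestational days D8, D11, D14, D17 and D20 with
8 animals per group and day, in plasma and urine. `Spectrum1D` holds one
processed spectrum (strictly descending ppm axis, the NMR plotting
convention) with its sample metadata; `FeatureMatrix` is a
`SummarizedExperiment` subclass whose assay holds features (bins or
named metabolites) by samples. All comparisons are within-day C-vs-H;
across-day trajectory PCA is descriptive only and drives no screening
decision.

## Spectral preprocessing

**Apodization and transform.** FIDs are multiplied by
exp(−π·lb·t) — adding lb Hz to every linewidth — and Fourier
transformed; the real part is returned on a ppm axis derived from the
spectral width and the 600.13 MHz proton frequency. Defaults: lb = 1 Hz
for plasma, 0.3 Hz for urine. Phase and baseline correction are assumed
done upstream (as by acquisition-side software); only a linear baseline
is ever subtracted here.

**Calibration.** The axis is shifted so a reference resonance lands on
its nominal shift: the lactate doublet at 1.33 ppm for plasma (the
doublet is located as the strongest pair of local maxima separated by
roughly one J = 7 Hz; its midpoint is the reference), the TSP singlet at
0.00 ppm for urine. The search window defaults to nominal ± 0.1 ppm.
Detection requires the smoothed maximum to exceed the window median by
five times the noise level, with noise estimated from point-to-point
differences (`mad(diff(y))/√2`) so that a window crowded with genuine
resonances is not mistaken for noise. Calibration is idempotent up to
one grid step.

**Binning.** Equal-width bins tile the retained region — 0.5–9.0 ppm at
0.002 ppm for plasma, 0.5–9.5 ppm at 0.005 ppm for urine — and each bin
value is the trapezoidal *integral* of intensity over the bin
(intensity × ppm), not the mean intensity, matching integral-based
bucketing. The urea (5.5–6.0 / 5.55–6.00 ppm) and residual-water
(4.54–5.23 / 4.50–5.10 ppm) windows are excluded. Bins overlapping an
exclusion window, wholly or partially, are **dropped rather than
truncated**, keeping every retained bin the same width; with the default
plasma grid the window edges align with the bin grid and 3655 bins
remain (4250 − 250 − 345). Only the exactly stated windows are excluded;
any extra margin is the caller's configuration.

**Normalization.** `total_area` rescales each sample to the
cohort-median total integral. `pqn` (probabilistic quotient) divides
each sample by the median quotient against the median spectrum; it is
the default for urine, where per-sample dilution varies strongly, and
`none` is the default for plasma. The applied factors are stored in the
object metadata so dilution recovery can be verified.

**Quantification.** A metabolite's value is the sum of retained bin
integrals inside its assignment windows (user-supplied or derived from a
peak library as centre ± 0.02 ppm, merged when overlapping). Window
truncation of Lorentzian tails cancels in any between-group ratio, so
fold changes are unbiased even though a window captures ~96 % of a
line's area.

## Latent-variable models

Class coding is C = −1, H = +1 throughout, so positive weights, scores
and correlation loadings mean "higher under hypoxia".

* **Scaling.** PCA uses mean-centring; PLS-DA and OPLS-DA use Pareto
  scaling (centre, divide by √SD), the usual compromise for NMR bins
  where unit variance inflates noise regions. Constant features pass
  through as centred zeros and are flagged, not fatal.
* **PCA** is computed by SVD; explained variance ratios are singular
  values squared over the total sum of squares, and the sign convention
  (largest-magnitude loading element positive) makes results
  deterministic.
* **PLS-DA** is NIPALS with X- and y-deflation; for a single binary
  response each component is closed-form, so no iteration tolerance is
  involved.
* **OPLS-DA** performs orthogonal signal filtering: with
  w ∝ Xᵀy fixed, each orthogonal component takes the part of the loading
  p orthogonal to w, deflates X by it, and the single predictive
  component is fitted on the filtered matrix. Orthogonal scores are
  exactly uncorrelated with y by construction; with zero orthogonal
  components the model coincides with 1-component PLS-DA. The default of
  1 predictive + 1 orthogonal component is the conventional choice for
  two-class models and is configurable; the within-day rank of the data
  caps the number automatically.
* **VIP** uses the weighted-weights formula whose squares average to 1;
  for OPLS-DA only the predictive component carries class information,
  so VIP reduces to √F·|w_p|.
* **Validation.** Q² = 1 − PRESS/SS from class-stratified K-fold
  cross-validation (default 7 folds, the common default in chemometrics
  software); negative Q² is reported as-is. The permutation test
  (default n = 200) refits the model on uniformly permuted labels and
  uses the add-one estimator p = (1 + #{null ≥ observed})/(n + 1), so
  the smallest attainable p is 1/201 and p = 0 is impossible. CV-ANOVA
  forms F = ((SS − PRESS)/d₁)/(PRESS/d₂) with d₁ = number of model
  components and d₂ = n − 1 − d₁, following the published CV-ANOVA
  formulation for PLS/OPLS models; all-zero residuals are flagged as
  degenerate rather than reported as p = 0.

All stochastic steps (fold assignment, permutations, simulation) take
explicit seeds; nothing depends on the global RNG state.

## The screen

Per comparison and metabolite the screen computes the correlation
loading r = cor(x_j, t_p), VIP, the two-sided Welch t-test p (Welch
because group variances are not assumed equal; a pooled variant is
available), and the fold change mean(H)/mean(C). A metabolite is
*significant* when p < α (default 0.05), |r| ≥ r\*, and VIP is at or
above the (1 − 0.10) quantile of the comparison's VIPs (linear
interpolation). Two correlation thresholds coexist deliberately:

* the **screening rule** defaults to r\*(α, df) with df = 2n − 2 (the
  pooled two-group df; ≈ 0.497 at n = 8, reproducing the familiar
  |r| > 0.5 volcano rule), and
* the **display threshold** of report tables defaults to
  r\*(0.05, 7) = 0.666, with sub-threshold r rendered as the literal
  `/`.

Both are exposed as configuration, since the conventional df = 7
threshold (consistent with df = n − 1 at n = 8) and the pooled-df rule
cannot be reconciled from first principles; the package keeps each
reproducible. No multiple-testing correction is applied across
metabolites by default — the three-way conjunction is the guard — and
fold changes for composite lipid envelopes can be masked per feature
while their r is still reported. Volcano datasets carry
x = log₂(fold change), y = −log₁₀(p), size = VIP and colour = |r|;
masked cells are skipped and counted. Union/intersection counts across
fluids canonicalize names first (spelling variants, Greek alpha), and
always satisfy inclusion–exclusion exactly.

## Pathway over-representation

`ora()` computes the upper-tail hypergeometric probability of the
observed overlap between the hit list and each pathway restricted to the
background, with BH adjustment across tested pathways. The background is
the set of quantified metabolites in the relevant fluid(s), not a
universal compound database, because the screen can only ever nominate
quantified metabolites. The packaged
`demo_pathways_synthetic.gmt` is a small curated demonstration resource
built from this package's own metabolite vocabulary — it is not a KEGG
export, and enriched-pathway counts against it are illustrative only.
Network-diffusion analyses over metabolite–enzyme–reaction graphs are
out of scope.

## The synthetic generator

The generator exists so that every downstream stage is testable without
any external data. It emulates: the 2 × 5 × 8 cohort layout; Lorentzian
lines (the natural NMR lineshape) with default 1.5 Hz linewidth at
600.13 MHz and fixed multiplet patterns (s/d/t/q at J = 7 Hz; "m"
rendered as one broadened line); lognormal metabolite concentrations
(strictly positive, right-skewed; default log-SD 0.15) with planted
(metabolite, day) fold changes in the H group on the 0.4–2.0 scale of
the emulated study; Gaussian chemical-shift jitter (SD 0.002 ppm — one
plasma bin — to exercise binning robustness); a smooth sinusoidal
baseline; white noise (default SD 0.5 a.u.); and, for urine, a lognormal
per-sample dilution factor with CV 0.3 that exists precisely so PQN has
something to remove. Spectra default to 16384 points over the fluid's
range. Base levels are arbitrary units — the emulated study reports no
absolute concentrations, so only fold changes are meaningful — with a
few genuinely abundant species (lactate, glucose, lipid envelopes,
creatinine, urea, TSP) raised above 1 so the calibration references
dominate their neighbourhoods as they do in real biofluids.

What it does **not** emulate: quantum-mechanical spin systems, J-coupling
fine structure beyond the fixed patterns, T2/relaxation differences
between pulse sequences, peak overlap pathologies of real biofluids, or
correlated biological covariation between metabolites. Passing recovery
tests therefore demonstrate that the pipeline's statistics behave as
designed under a faithful noise model, not that any particular real
cohort would yield the same counts.

## Problem sizes and numerical choices

The test-suite experiments use sizes chosen to probe each property
directly: the recovery experiment runs 200 simulated cohorts of 8
animals per group with planted fold changes 2.0 and 0.5 at log-SD 0.15
(the screen's operating point), asserting sensitivity ≥ 0.9 and
per-comparison false-positive rate ≤ 0.05; permutation-p uniformity uses
500 null datasets of 12 samples × 5 features with 39 permutations each;
model-property sweeps use 100 random models up to 32 × 20. Rendering
oracles integrate single-line spectra on 16384-point grids (trapezoidal
integration recovers a unit-area Lorentzian's concentration within 1 %
on the fluid's range). Ties and degeneracies: constant features are
flagged and masked (r undefined), zero-variance t-tests return p = 1
when means agree, empty hit lists return empty enrichment results, and
bins are labelled by centre ppm to six decimals.

## Known limitations

* OPLS-DA component counts and cross-validation layout in commercial
  chemometrics software are not bit-reproducible; this package fixes its
  own deterministic conventions instead of chasing another
  implementation's.
* Assignment windows are user configuration; there is no automated peak
  annotation against spectral databases.
* The urine dilution-normalization method of any particular published
  study is rarely stated; PQN is this package's default, recorded in the
  output provenance.
* Multi-class (> 2 group) discriminant analysis and batch correction are
  out of scope.
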