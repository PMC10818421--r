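---
title: "Methods: OPLS-DA chemometrics for ATR-FTIR fecal fingerprints"
author: "ftirDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OPLS-DA chemometrics for ATR-FTIR fecal fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

ftirDA implements a complete chemometric workflow for mid-infrared
(4000–400 cm⁻¹) ATR-FTIR absorbance spectra of clinical samples: spectral
preprocessing, binary OPLS-DA with permutation-test validation, a
multi-algorithm classification benchmark with cross-validation and
site-based external validation, and univariate spectral-marker selection.
Because clinical fecal-spectrum cohorts are rarely shareable, the package
ships a synthetic cohort generator that emulates the statistical structure
such studies rely on; every pipeline stage is exercised and validated
against that generator.

# The data model

Spectra live in a `SpectraSet` (a `SummarizedExperiment`): wavenumbers as
rows (stored descending, 4000 → 400, matching acquisition order) and
individual replicate spectra as columns, with per-spectrum sample metadata
(`sample_id`, `cohort` HC/UC, week-8/week-56 remission labels RM/NRM,
collection `site_id`, `replicate_index`). The default acquisition grid,
`buildGrid(4000, 400, 0.5)`, has 7201 points — 0.5 cm⁻¹ is the unique
uniform spacing consistent with that range and feature count; the
instrument's optical resolution (4 cm⁻¹) is a separate parameter and not
the data spacing. The wide CSV interchange format (six metadata columns,
then one column per wavenumber) round-trips bit-exactly because absorbance
is serialized at `%.17g`.

# The synthetic cohort generator

`generateCohort()` draws replicate-level spectra from a forward model

$$A(\nu) = f \cdot \Big[\sum_b a_b e^{-(\nu - c_b)^2 / 2\sigma_b^2} + B(\nu)\Big]
  + o + s\,(\nu - \nu_{mid}) + \varepsilon(\nu),$$

with 14 Gaussian absorption bands, a per-replicate log-normal pathlength
factor $f$ (contact-area/penetration variation), a per-replicate linear
baseline, and white noise $\varepsilon$.

**Cohort structure.** Defaults are the study conditions the pipeline
targets: 30 healthy controls, 62 patients, 9 replicate acquisitions per
sample, week-8/week-56 remission prevalences 24.2 % and 41.9 % assigned by
exact count (`round(rate × n)`, so prevalence checks are deterministic;
the week-8 RM set nests inside the week-56 set as far as counts allow),
and patients split 51/11 over two collection sites. Seven band centers
(3271, 1629, 1437, 1408, 1316, 1244, 1149 cm⁻¹) carry biochemical
assignments and group effects; the remaining seven are generic mid-IR
positions (CH stretches, ester C=O, amide II, ring modes) included as
documented placeholders.

**Group effects.** Effects are multiplicative folds on band amplitudes:
UC vs HC — 1316 ×1.37, 1408 ×1.26, 1437 ×1.20, 1244 ×1.29, with
HC-dominant bands 3271, 1629, 1149 at reciprocal folds (1/1.37, 1/1.38,
1/1.21); RM vs NRM — 1149 ×1.21 (week 8) and ×1.24 (week 56), 1408 ×0.99
(week 56). The direction of the protein-band effects is genuinely
ambiguous in the source literature on such cohorts (band-level listings
and summary sentences disagree); the defaults follow the band-level
listing and every fold is overridable. Because all RM patients are UC
patients, the remission folds stack multiplicatively on top of the cohort
folds for the same bands — a deliberate interaction that mirrors nested
clinical labels.

**Area-neutral effects.** Default band amplitudes are chosen so the
UC-vs-HC folds preserve total spectral area to within 0.1 %
($\sum_b a_b \sigma_b (f_b - 1) \approx 0$). A constant mass of dried
material on the ATR crystal absorbs a roughly constant total; composition
shifts redistribute absorbance rather than change it. This matters
technically: area normalization divides by the row sum, so an
area-imbalanced effect set would leak a uniform group offset into every
wavenumber, biasing recovered fold changes and making unaffected bands
spuriously significant.

**Between-subject variability.** Two per-sample terms are held constant
across a sample's replicates: a log-normal jitter on every band amplitude
(`amplitude_sigma`, default 0.08 ≈ 8 % CV) and a "chemical background" of
120 minor Gaussian bands at random positions (amplitude SD 0.012 AU,
widths 8–30 cm⁻¹, ≈ 0.02 AU pointwise SD). The background gives
within-group variance full rank across samples, which real cohorts have
and which the permutation-test intercept diagnostics presuppose: without
it, within-group variance is low-rank instrument noise, permuted-label
models cannot overfit, and the R²Y-intercept rule degenerates. Replicate
noise defaults: `noise_sd` 0.001 AU (a clean ATR 100 %-line),
`pathlength_sigma` 0.08, baseline offset ±0.01 AU, slope ±2·10⁻⁶ AU/cm⁻¹,
per-site additive shift SD 0.004 AU.

**What the generator does not emulate.** Water-vapor and CO₂ lines, Mie
scattering, detector drift, peak-position shifts between subjects,
non-Gaussian band shapes, and covariance between specific metabolite
bands. Consequently, passing tests demonstrate that the *pipeline*
recovers planted structure under realistic noise — not that real fecal
spectra contain such structure.

**Reproducibility.** All randomness derives from one seed through fixed
per-sample/per-replicate sub-streams (a multiplicative-congruential hash),
so equal configs give bit-identical cohorts and enlarging a cohort leaves
existing samples unchanged.

# Preprocessing

Stages run in a fixed order: replicate averaging → ATR correction →
Savitzky–Golay derivative → row normalization → column scaling.

* **Replicate averaging**: replicates sorted by index are averaged in
  consecutive groups of 3 (9 acquisitions → 3 averaged spectra). The
  grouping is consecutive because acquisition order is the only structure
  available; it is configurable.
* **ATR correction** (off by default): multiplies absorbance at $\nu$ by
  $\nu/\nu_{ref}$ ($\nu_{ref}$ = 1000 cm⁻¹). The evanescent-wave
  penetration depth scales as $1/\nu$, so uncorrected ATR spectra
  over-weight low wavenumbers. Vendor "advanced ATR correction" algorithms
  are proprietary; this linear depth correction is the openly documented
  first-order approximation, and it is off by default so results remain
  interpretable without it.
* **Savitzky–Golay derivatives**: 7-point window, polynomial order 3, with
  respect to wavenumber in physical units (index-space coefficients are
  divided by the spacing per order, sign-corrected for descending
  storage). Edge points use the filter matrix's one-sided fits, so
  polynomials up to the filter order are reproduced exactly everywhere.
* **Row normalizations** (per spectrum): *area* (divide by the total sum;
  invariant to positive rescaling — this is what cancels the
  multiplicative pathlength factor), *min-max* (affine map onto [0, 1]),
  *amide* (subtract the global minimum, divide by the amide I maximum in
  1650–1600 cm⁻¹ minus the global minimum; values above the amide maximum
  legitimately exceed 1), *vector* (unit Euclidean norm; defined on
  derivative spectra, and the configuration rejects it without one).
* **Column scalings** (per wavelength, across samples): mean-centering,
  Pareto (÷ √SD), unit variance (÷ SD); sample SD (n − 1); constant
  columns are centered and left at zero (0/0 → 0). Scaling statistics are
  recorded and can be frozen and re-applied, which is how external
  validation avoids leaking validation-set statistics.

The normalized pre-scaling matrix is kept alongside the scaled one:
t-tests and fold changes are computed on it, because column scaling would
distort the fold-change interpretation.

# OPLS-DA

The binary label is coded 0/1 (positive class = lexicographically larger:
UC over HC, RM over NRM) and mean-centered. For each orthogonal
component, the loading $p$ of the current predictive score is
orthogonalized against the predictive weight $w \propto X^T y$ to give an
orthogonal weight; the corresponding score/loading pair is deflated from
X. The final predictive component is extracted from the filtered matrix
and y is regressed on its score. With this scheme OPLS with $k$
orthogonal components reproduces the fitted values of a
$(k+1)$-component NIPALS PLS (the classical equivalence), which the test
suite verifies against an independent NIPALS implementation to 10⁻⁶, and
predictive/orthogonal scores are orthogonal to machine precision.

* **R²Y** is the training-fit explained variance; **Q²Y** is
  $1 - \mathrm{PRESS}/\mathrm{SS}$ from stratified k-fold CV (default 10)
  refitting the entire procedure per fold.
* **Component selection** (`autofitOpls`): orthogonal components are added
  greedily while Q²Y improves by more than 0.01. Commercial autofit rules
  are proprietary; a greedy Q²-gain rule with an explicit threshold is the
  transparent emulation.
* **Permutation test**: labels are permuted (rows permuted freely — when
  the matrix carries 3 averaged spectra per sample this scrambles
  replicate triples, exactly as a row-oriented chemometrics package would
  do it), the model is refit with the same component count, and R²Y/Q²Y
  are regressed on the absolute label correlation, including the observed
  model at correlation 1. The model is declared valid when the R²Y
  intercept is below 0.4 and the Q²Y intercept below 0.05. Empirical
  p-values use the add-one rule, so they are never exactly zero.
* **CV-ANOVA**: $F = [(\mathrm{SS} - \mathrm{PRESS})/d_1] /
  [\mathrm{PRESS}/d_2]$ with $d_1$ = components consumed and
  $d_2 = n - 1 - d_1$; PRESS ≥ SS yields p = 1 rather than an error.
* **VIP**: computed over the single predictive component,
  $\mathrm{VIP}_j = \sqrt{p}\,|w_j|$, so squared VIPs average exactly 1
  and VIP ≥ 1 marks above-average contributors. Multi-component VIP
  variants exist in commercial software; the predictive-only form is the
  one that matches the single-predictive-component model used here.
* **Classification**: ypred ≥ 0.5 on the 0/1 scale calls the positive
  class — the natural midpoint; no source states the commercial cutoff.

# Classifier benchmark

Logistic regression (ridge-penalized, λ = 1/(C·n), matching the C
convention of penalized LR implementations), KNN, decision tree, random
forest, linear and RBF SVM, and OPLS-DA itself, each with an exhaustive
hyperparameter grid searched by stratified inner 5-fold CV on accuracy.
Grids contain the winning settings such studies report (LR C = 1; RBF SVM
γ = 10⁻⁴ with C = 100 or 1000). Ties break toward the simpler model
(smaller C, smaller γ, fewer neighbors, shallower/fewer trees, fewer
components). Outer evaluation is 10-fold CV with per-fold train/test
accuracy, precision, recall, F1 (zero-denominator cases return 0 with a
warning) and rank-based (mid-rank ties) ROC-AUC, summarized as
mean ± 1.96·SD/√k — the normal approximation whose CIs can exceed 1, the
only computation consistent with published tables printing e.g.
"0.99 (0.98–1.01)".

**CV unit.** By default folds are stratified *and grouped by sample*: the
3 averaged spectra of one sample never straddle a fold boundary (asserted
on every run). Treating averaged spectra as independent CV units
(`cv_unit = "spectrum"`) is also implemented because published workflows
appear to do exactly that; it inflates test metrics through
near-duplicate leakage, and on the synthetic cohort it is the mode that
reproduces the near-perfect accuracies such tables print. Reports record
which mode produced them. This is the single most consequential
ambiguity in reproducing published numbers of this kind.

**External validation** splits samples by collection site (51/11 by
default), learns preprocessing column statistics on the development site
only, applies them frozen to the validation site, refits the
grid-searched model on the full development set, and reports single-shot
validation metrics (AUC is reported as NA when the validation set is
single-class; other metrics are still computed).

# Spectral markers

Per wavenumber: pooled-variance Student's t (Welch optional, off by
default), two-sided p, and fold change (ratio of group means, first-named
group over comparator), all on normalized pre-scaling intensities. A
wavenumber is selected when VIP ≥ 1.0 (inclusive) *and* p < 0.05
(exclusive). No multiple-testing correction is applied by default — the
VIP gate plays that role in this tradition — but Benjamini–Hochberg is
available behind a flag.

# Pipeline

`runFullStudy()` executes, per contrast: preprocessing grid search (every
normalization × scaling × derivative combination, invalid cells skipped
with a logged reason), ranking by Q²Y with R²Y as tie-break (Q² first
because predictability, not fit, is the selection criterion), best-model
OPLS-DA with autofit, permutation validation, CV-ANOVA, marker table,
classifier benchmark, and site-based external validation. All randomness
derives from the single config seed; reports (CSV per artifact plus a
study-level JSON) are written atomically. Rerunning a config reproduces
byte-identical reports.

# Numerical choices and degenerate inputs

Grid uniformity tolerance 10⁻⁹ of the spacing; `nearestIndex` ties
resolve to the lower wavenumber; zero-sum rows, constant rows and
zero-norm rows are errors for the respective normalizations; constant
columns scale to zero rather than erroring; single-class responses,
ragged CSV rows and off-grid band centers are errors with context; OPLS
refuses n_ortho ≥ min(n − 1, p); empirical permutation p-values lie in
(0, 1].

# Problem sizes used by the test suite

Module tests run on coarse grids (30–300 points) with reduced cohorts.
The calibration studies use the full default cohort (92 samples × 9
replicates) on a 401-point grid spanning 3700–700 cm⁻¹ (7.5 cm⁻¹
spacing) — the band-carrying region at a spacing that keeps ~100-fold
permutation refits tractable — and the marker-recovery study uses the
full 4000–400 cm⁻¹ range at 2.5 cm⁻¹ (1441 points), because VIP ≥ 1 is a
relative threshold and truncating the silent spectral regions would
depress in-band VIPs. Marker recovery is measured with only the
contrast-under-test effect map active, since the default maps deliberately
stack remission folds on cohort-effect bands (see above) and partially
cancel there.

# Known limitations

* The ATR correction is a first-order physical approximation, not a
  reconstruction of any vendor algorithm.
* OPLS-DA is binary-only (single y column); multi-class problems are out
  of scope.
* CV-ANOVA degrees of freedom follow the published formulation; exact
  commercial bookkeeping is proprietary and may differ slightly.
* The generator's defaults make the cohort contrast strongly separable by
  design; absolute metric values on synthetic cohorts say nothing about
  clinical performance on real spectra.
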