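---
title: "Methods: explainable OCT-based glaucoma staging with glocr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable OCT-based glaucoma staging with glocr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the choices made where the design
was genuinely open, and what the bundled synthetic cohort does and does not
demonstrate about real clinical data.

## The diagnostic problem and the data model

Glaucoma thins the retinal nerve fibre layer (RNFL) around the optic nerve
head and the ganglion cell–inner plexiform layer (GC-IPL) in the macula.
A spectral-domain OCT exam summarises one eye as:

* a 256-sample circumpapillary RNFL thickness profile in TSNIT order
  (temporal → superior → nasal → inferior → temporal), in µm. The healthy
  profile shows a "double hump" at the superior and inferior poles because
  the arcuate nerve fibre bundles enter there; the profile completes exactly
  one revolution of the scan circle, so its natural frequency unit is cycles
  per revolution and the double hump corresponds to a fundamental of 2;
* device summaries: average RNFL thickness, inter-eye RNFL symmetry (%),
  four quadrant and twelve clock-hour means;
* GC-IPL average, minimum and six sector thicknesses;
* nine macular ETDRS subfield thicknesses plus cube average, cube volume,
  central-foveal and central-minimum measures;
* the visual-field mean deviation (MD, dB), the functional global index.

Severity staging follows the Mills MD bands: early glaucoma above −6 dB,
moderate in (−12, −6] dB, advanced at or below −12 dB, with both boundary
values read into the worse stage. An eye whose central field is destroyed
without meeting the MD criterion can carry an explicit central-field-defect
flag and is labelled advanced on that basis only — never inferred from MD.
Normal eyes are clinician-assigned controls, not an MD-derived category, so
`stage_from_md()` applies only to eyes already diagnosed glaucomatous.

A cohort is a plain data frame, one row per eye, with a canonical CSV
serialisation (`t000..t255` TSNIT columns; a semicolon-joined single-column
dialect is also read). Missingness is structured: an imaging artefact wipes
out a whole parameter group (RNFL, GC-IPL or macular), which is exactly how
`artefact_mask()` reports it, and an eye enters the cohort only if at least
one group survives.

## Feature catalog (67 spatial + 64 frequency)

The default catalog (`default_catalog()`) enumerates 131 named features.
The exact feature-by-feature inventory of the original device analyses is
not public, so the catalog is a documented reconstruction that totals
exactly 67 spatial and 64 frequency features; it is versioned and swappable
via JSON so a different enumeration can be dropped in without touching code.

Spatial (67): RNFL 46 — average, inter-eye symmetry, 4 quadrants, 12 clock
hours, {mean, median, sd, skewness, kurtosis} × {whole, T, S, N, I} (25),
and Shannon entropy, Fisher information, SNR (3); GC-IPL 8 — average,
minimum, 6 sectors; macular 13 — 9 ETDRS subfields (central subfield among
them), cube average, cube volume, central-foveal and central-minimum
thickness. The central-minimum measure is the reconstruction's thirteenth
macular entry: the named macular analyses enumerate twelve, and the device's
macular report carries a central-minimum value, so it completes the count
without inventing an unrelated quantity.

Frequency (64): for each of five signals (whole profile and the four
64-sample quadrant slices) and two estimators (periodogram; Welch), the five
summaries total power, peak power, peak frequency, mean power, power sd
(50); total and peak detail power at db4 wavelet levels 1–4 of the whole
signal (8); the harmonic slope of each signal's periodogram (5); and the
normalised spectral entropy of the whole-signal periodogram (1).

Conventions worth stating because the field has several:

* **Quadrants** are the four consecutive 64-sample blocks, assigned T, S, N,
  I in TSNIT order.
* **Clock hours** are twelve contiguous sectors of ~21.3 samples. The
  sample-to-hour anchoring is chosen so that the superior quadrant carries
  clocks {11, 12, 1} and the inferior quadrant clocks {5, 6, 7} for a right
  eye — the anatomical convention in which clock 11 is "part of superior"
  and clocks 6–7 "part of inferior" — and the left-eye labels are the
  mirror (2↔10, 3↔9, …).
* **Skewness/kurtosis** use population (n) normalisation; kurtosis is
  non-excess (normal → 3); zero-variance segments report both as 0, flagged
  by construction rather than propagating NaN.
* **Histograms** for entropy and the Fisher measure use 16 equal-width bins
  over [min, max] of the profile; entropy is in bits; the Fisher measure is
  the discrete `Σ (p[i+1] − p[i])² / p[i]` with zero-probability
  denominators skipped. SNR is mean/sd, `Inf` for a constant profile.
* **Inter-eye symmetry** is `100 · max(0, r)` with `r` the Pearson
  correlation of the two fellow-eye profiles aligned index-by-index: since
  each eye's TSNIT ordering starts at its own temporal side, index
  alignment is already the anatomical mirror, and the package applies no
  further re-indexing. The device's own symmetry definition is unpublished;
  device-exported values therefore take precedence over recomputation
  everywhere (`extract_spatial()` only fills in what the device did not
  provide).

## Spectral estimation

Signals are demeaned before every spectral analysis, so the DC level
(overall thickness) remains a spatial feature and the spectra describe
shape. The one-sided periodogram is normalised so that summed power equals
the mean square of the demeaned signal (Parseval); a pure tone of amplitude
A then carries total power A²/2 at its bin, which is the closed form the
test suite checks. Welch estimation averages modified periodograms of
Hann-windowed segments with coherent-gain compensation (`/ sum(w)²`), so a
single full-length rectangular segment reproduces the periodogram
bit-for-bit — the degenerate case that pins the normalisation. Defaults:
segment length 64 with 50% overlap on the whole profile, 32 on the
64-sample quadrant slices (keeping ≥ 3 segments); both are parameters, not
constants, because no published value exists for them.

The discrete wavelet transform uses the db4 (8-tap Daubechies) filters with
periodised convolution, which keeps the analysis orthogonal: detail
energies plus the final approximation energy reproduce the signal energy to
1e−9, the oracle the tests use. Band summaries apply the periodogram to the
detail coefficients *without* demeaning — wavelet details carry no
meaningful offset, and removing their mean would delete the energy of a
pure alternating (Nyquist) signal entirely.

Harmonic slopes are least-squares slopes of log10 power at harmonics
k·fundamental, k = 1..5, with powers floored at machine epsilon; the
fundamental defaults to 2 cycles/revolution (the double hump) and the same
bin-index convention is applied to quadrant slices. Spectral entropy is
Shannon entropy of the power distribution divided by log(#bins), so it is 0
for a line spectrum and exactly 1 for a flat one.

## Preprocessing

**Imputation.** Artefact-masked groups are completed by chained linear
regressions: columns initialised at their means, visited in order of
increasing missingness, each regressed on all other columns over its
observed rows, iterated until the largest cell change falls below 1e−3 or
10 sweeps. The procedure is deterministic (no posterior draws) and returns
a single completed matrix — the classifiers consume one completed dataset,
so multiple-completion variance pooling is out of scope. Observed cells are
never altered (asserted exactly in the tests), and `mice_apply()` carries
the fitted regressions onto held-out rows so no test-fold statistic leaks
into training. The regressor family and iteration count are undocumented in
the source material; linear chained regression with these defaults is the
package's documented choice.

**Oversampling.** SMOTE interpolates uniformly between a minority point and
one of its 5 nearest minority neighbours until classes balance; originals
are preserved verbatim and every synthetic point lies exactly on a
minority-pair segment (verified geometrically in the tests).

**Scaling.** Min–max to [0,1] for KNN, standardisation for SVM, none for
random forests; parameters are fitted on the training split only, apply-set
values are not clipped, and zero-range columns map to 0, flagged.

Imputation and oversampling never feed feature selection or the
explainability analyses — those stages run on non-augmented rows only —
and a single switch (`impute = FALSE, smote = FALSE`) reproduces the
artefact-free-only sub-analysis.

## Feature selection

One-way ANOVA F scores rank features; a feature with distinct group means
and zero within-group variance sorts first via an `Inf` sentinel. Pearson
correlation pruning builds the graph of `|r| > 0.98` pairs
(pairwise-complete observations) and keeps the highest-F feature of each
connected component, with ties broken by catalog order — the
connected-component reading matches the worked case of four mutually
correlated macular thickness measures reduced to one survivor. Constant
columns have undefined correlation; they are retained and flagged rather
than silently dropped. The wrapper stage records a random-forest
cross-validated accuracy curve over increasing prefixes of the F-ranked
list, but the curve is advisory: the binding rule is the absolute cut-off
F ≥ 30 (a fraction-of-maximum alternative is a config option). Pruning is
idempotent and the ranking is invariant to column order up to the
documented tie-break.

## Classification and evaluation

Three classifier families with their standard grids: KNN with k ∈ 1..40
(min–max scaled), RBF-SVM with C ∈ {0.1, 1, 10, 100} × γ ∈
{0.001, 0.01, 0.1} (standardised; probabilities by the library's built-in
Platt-type calibration fitted on training data), and random forests with
100 trees and maximum depth {3, 6, ∞} (unscaled; probability = tree vote
fraction; depth d is mapped to `maxnodes = 2^d`, capped at the training
size, because the implementation exposes node count rather than depth).
Grid search maximises mean cross-validated accuracy on stratified row folds
inside each training fold, breaking ties toward the earlier (simpler) grid
row. KNN probabilities are neighbour vote fractions.

Outer evaluation is patient-level: both eyes of a patient always share a
fold, folds are stratified by patient label with sizes differing by at most
one patient, and every preprocessing statistic is fitted inside the
training fold. Schemes: `binary` (all glaucoma vs normal), `OvR` (each
class vs the rest), and `OvO` read as each glaucoma stage vs normal only —
the three stage-vs-normal binary problems, not all class pairs. Metrics are
sensitivity, specificity, accuracy, F1 at the 0.5 score threshold, and AUC
as the trapezoid over the empirical ROC (computed in tie-corrected rank
form, cross-checked against an independent ROC library in the tests);
aggregates report mean ± sd, SE = sd/√n and the 95% CI mean ± 1.96·SE
clipped to [0, 1]. Repeated (shuffled) cross-validation re-draws the
patient folds per repeat.

CFD-based advanced eyes are excluded from the staging problems by default
(their MD does not define their stage) and included in overall diagnosis;
`include_cfd` flips the switch, since the original analysis protocol for
these eyes is not documented.

## Explanation

Shapley attributions use marginal (interventional) coalition values: the
value of feature set S is the mean prediction with S pinned to the
explained instance and the remaining features drawn from a background
sample (≤ 200 seeded rows). Exact mode enumerates all 2^m subsets (m ≤ 15)
and satisfies efficiency, dummy and symmetry to 1e−9; sampled mode averages
marginal contributions along random permutations and converges to the
exact values (checked at 10² vs 10⁴ permutations on an interaction model —
for an additive model a single permutation is already exact, which is why
the convergence oracle must contain interactions). The marginal choice
matches the Monte Carlo treatment the partial-dependence estimator applies;
conditional-expectation variants are out of scope.

PDP/ICE: the partial dependence at grid value v is the mean prediction over
the data with the feature pinned to v; ICE rows are the per-sample curves
and the PDP is exactly their columnwise mean (a definitional identity the
tests assert at 1e−12). Cut-offs are the feature values where the PDP
crosses a horizontal decision boundary, linearly interpolated between the
bracketing grid points, taking the first crossing from the declared
high-risk side (low values, for thickness- and symmetry-like features) and
logging any others.

## The likelihood calculator (GLOC)

`build_gloc()` stores, for each of the nine explainable spatial features
(major: RNFL symmetry, inferior and superior quadrant thickness; minor:
GC-IPL inferotemporal, superotemporal, inferior and superior sectors,
average RNFL, average GC-IPL), its one-way PDP lookup curve and
decision-boundary cut-off. Two design choices need justification:

* **Isotonic lookup curves.** The stored curve is the monotone-decreasing
  (isotonic least-squares) projection of the raw PDP. The risk direction is
  declared a priori — thinner or less symmetric is never protective — so
  local non-monotonicity in a forest's PDP is estimation wiggle, not
  signal. Projection makes each per-feature probability monotone in its
  input and gives a unique boundary crossing. On the default cohort, raw
  curves produced monotonicity violations in 105/360 random input sweeps;
  isotonic curves reduce this to the path-switch cases below.
* **Boundary and threshold at the model's base rate.** Marginal PDP values
  concentrate around the class prior: pinning one feature and averaging the
  model over the cohort cannot push the mean prediction far from the base
  rate when the other eight features still carry most of the signal.
  Consequently a fixed 0.5 boundary may never intersect any curve, and a
  fixed absolute call threshold sits on the wrong part of the scale. The
  pipeline therefore places the decision boundary, and reports the
  operating point, at the model's mean predicted probability — its
  indifference point — while the API defaults remain boundary 0.5 and
  threshold 0.25 for compatibility with an externally calibrated scale.
  This is why GLOC likelihoods should be read as a relative scale anchored
  at the base rate, not as calibrated posterior probabilities.

Scoring follows the major/minor priority rule: per-feature probabilities by
linear interpolation on the lookup curves (clamped at the ends; missing
inputs contribute their cut-off probability and flag the result partial);
if all major criteria lie on the glaucomatous side of their cut-offs the
likelihood is the mean major probability, else if all minor criteria do it
is the mean minor probability, else the mean of all nine. The "all"
quorum is configurable (e.g. 2-of-3) because the source phrasing is
ambiguous; group means are unweighted, with the weight vector exposed.
A five-bin verbal scale (edges 0.10/0.25/0.50/0.75, left-closed) and the
binary call complete the result.

**A structural caveat.** The priority rule is discontinuous at decision-path
switches: when the last major criterion crosses its cut-off, the likelihood
jumps from the minor-group (or combined) mean to the major-group mean,
which can be *lower* — e.g. minors deeply abnormal (mean probability 0.95)
while the majors barely cross (mean 0.51). This is a property of the
algorithm, not of the implementation; it holds under every quorum reading,
and it is asserted explicitly as a characterisation test. Within any fixed
path, and in every per-feature probability, the calculator is monotone; the
sensitivity/specificity trade-off in the threshold is monotone uncondition-
ally, because each eye's likelihood is fixed while the threshold moves.

## The synthetic cohort

The generator exists so that every stage is exercisable without patient
data; its defaults are the reference cohort conditions, chosen once:

* class structure 334 normal eyes (paired, 167 patients), 86 early, 72
  moderate, 37 MD-advanced, 73 CFD-advanced (one eye per glaucoma patient);
* TSNIT = baseline 65 µm + Gaussian bumps of 70 µm (superior, centre
  sample 96) and 78 µm (inferior, centre 224) with scale 15 samples
  (width ≈ 30), attenuated by 0 / 0.25 / 0.45 / 0.65 for normal / early /
  moderate / MD-advanced (0.60 for CFD-advanced), plus 6 µm sample noise —
  amplitudes and attenuations are calibration choices producing overlapping
  but separable classes, since no quantitative per-stage amplitudes are
  published;
* MD uniform within each stage's Mills band, so generated labels always
  re-derive under `stage_from_md()`;
* GC-IPL and macular summaries affine in the eye's mean TSNIT plus noise,
  so the cross-parameter correlation that chained-equation imputation
  exploits actually exists;
* inter-eye jitter of 4 µm plus asymmetric attenuation of the unrecorded
  fellow eye in disease, so RNFL symmetry degrades with severity;
* artefact masking i.i.d. per parameter group at 3.65%, redrawn in the
  rare all-three-groups event (such eyes were excluded by design).

What passing tests on this cohort do **not** show: the generator produces
smooth Gaussian-bump morphology with homoscedastic noise — no speckle, no
segmentation-failure morphology, no focal wedge defects, no age drift, no
longitudinal correlation — and its classes are cleaner than clinical
reality. Near-perfect synthetic AUCs demonstrate that the pipeline's
plumbing, leakage guards and explanations behave correctly, not that the
models would reach those numbers on patients.

## Problem sizes and numerical tolerances

The test suite runs a 74-eye cohort for unit-level checks and the full
602-eye default cohort inside the end-to-end suites; spectral oracles use
1,000 random signals (Parseval at 1e−9 relative), Shapley axioms 1e−9,
PDP/ICE identities 1e−12, imputation recovery 1e−6, and the sampled-Shapley
convergence check 10² vs 10⁴ permutations on a 6-feature interaction model
with a 30-row background. The acceptance script regenerates the full
cohort, runs the complete pipeline once with a random-forest classifier and
writes its headline quantities as JSON; all randomness descends from the
single `--seed` argument.

## Known limitations

* The 67/64 catalog is a reconstruction; device-specific inventories may
  differ in composition though not in count.
* The inter-eye symmetry formula is a stand-in for an unpublished device
  definition; device values pass through untouched where present.
* GLOC likelihoods are prior-anchored, not calibrated probabilities, and
  the priority rule is discontinuous at path switches (see above).
* Staging explanations are binary (glaucoma vs normal); multiclass
  attribution is out of scope.
* Optic nerve head parameters (cup-to-disc ratio, rim area) are not
  modelled, and no real OCT export parsing (DICOM or native device files)
  is attempted.
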