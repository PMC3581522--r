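---
title: "Reference-cluster intensity normalization: model, phantom design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-cluster intensity normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistical problem

Non-quantitative brain uptake images carry an arbitrary multiplicative
per-subject scale. All group statistics in this package therefore operate
on ratio-normalized images: each volume is divided by a reference value so
that the reference mean equals a fixed target (default 1, a dimensionless
scale; the classical target of 50 is available via the `target` argument
but changes nothing downstream, since every statistic used here is
scale-free).

Three reference families are implemented:

* **CGM** — the cerebral global mean by the two-pass rule: first the mean
  `m0` of all finite voxels, then the mean of voxels strictly above
  `m0/8`. The rule is pinned explicitly and unit-tested, since "default
  settings" of the historical implementation are otherwise ambiguous.
  `NaN` (out-of-brain) voxels are excluded from both passes.
* **ROI** — the arithmetic mean over a supplied binary mask (cerebellum,
  sensorimotor cortex, or any other region).
* **RC** — the data-driven reference cluster, below.

In a population with widespread hypometabolism the patients' global mean
is depressed, so CGM scaling divides patients by too small a number. Two
consequences follow, and both are exploited or guarded against here:
true deficits shrink (underestimation), and spared tissue appears
*increased* in patients. The reference-cluster method runs the
patients-greater-than-controls contrast on CGM-normalized images and
escalates the voxel-level family-wise-error threshold through a fixed grid
(0.05, 0.01, 10⁻³, 10⁻⁴, 10⁻⁵, 10⁻⁶) until the surviving voxels form one
coherent component; that component — the most-preserved tissue — becomes
the reference region.

## Inference machinery

**Voxel-wise GLM.** Ordinary least squares per voxel with design columns
intercept, group (patient = 1), mean-centered age, sex; one-sided
t-contrasts for decreases and increases separately. Residual degrees of
freedom are `n − rank(X)`. A covariate that is constant in a cohort is
dropped with a warning and recorded in the design's provenance. Voxels
with zero residual variance receive `±Inf` sentinels, are flagged, and are
excluded from permutation null distributions. The analysis mask is the
intersection of finite voxels across subjects, optionally intersected with
a user brain mask; no proportional implicit masking is applied.

**Family-wise error.** The primary method is max-statistic permutation:
group labels are permuted across subjects (covariates stay attached to
their subjects), the full model is refit, and the maximum t over the mask
forms the null. This is exact under exchangeability, which holds for the
two-group null regardless of the data's spatial correlation. Bonferroni
over in-mask voxels is provided as a closed-form alternative and is the
default inside the reference-cluster escalation, because the deepest grid
level (10⁻⁶) cannot be resolved by a permutation null of practical size
(the smallest achievable p is `1/(nPerm+1)`); Bonferroni is valid, if
conservative, at any level. Both choices are recorded in the provenance.

**Cluster-extent inference.** The t-map is thresholded at the Student
quantile of the uncorrected forming p (default 0.001), components are
extracted under 18-connectivity (faces + edges, the convention of the
standard neuroimaging packages; 6 and 26 are available), and the
cluster-level FWE is controlled by the permutation null of the maximum
suprathreshold cluster size. Survivors must also meet the reporting extent
filter of k ≥ 100 voxels; the filter is interpreted non-strictly by
default with a `kStrict` flag, since "greater than" conventions differ.
The extent filter is a reporting choice layered on top of the calibrated
permutation test — calibration checks therefore run with `kMin = 0`.

**Coherence rule.** "Most of the cluster volume in one region" is
operationalized anatomically agnostically: the largest connected component
must contain at least 90% of all suprathreshold voxels and at least 50
voxels. The full escalation path (alpha, threshold, suprathreshold count,
component count, largest fraction) is returned as provenance, and the
search stops at the first coherent level — under a null cohort no level is
coherent and non-empty, and the derivation raises an error by design.

## The synthetic phantom

There is no public data set attached to this problem, so validation rests
on a phantom that emulates spatially normalized, 12-mm-smoothed PET
volumes on a 32³ grid of 2 mm voxels (desk scale; the statistical
properties validated here are resolution-independent). The generative rule
per subject is

> value(v) = s · b(p) · exp(σ_b·w_b(p)·G(v) − ½σ_b²w_b(p)²) ·
> (1 − s_i · w(p) · (1 − f)) + ε(v), then Gaussian smoothing,

with parcel p = parcel(v), baseline uptake b, per-subject global scale
s ~ LogNormal(0, 0.1) (the nuisance normalization removes), deficit
severity weights w, hypometabolism factor f (default 0.85), per-patient
severity multiplier s_i ~ LogNormal(0, 0.2), a per-subject smooth
biological field G (unit variance, 20 mm FWHM correlation length) with
amplitude σ_b and per-parcel weights w_b, additive scanner noise ε, and a
single effective 12 mm FWHM kernel (truncated at 4 SD) applied after noise
to emulate scanner PSF and preprocessing smoothing jointly. Smoothing is
mask-normalized so means inside the brain are preserved at its edge.
Setting all variability parameters to zero reduces the rule to a pure
multiplicative deficit — the form used by the closed-form unit tests.

Design choices that were genuinely open, and how they were fixed:

* **Geometry.** An ellipsoidal brain is tiled into frontal,
  anterior-temporal, sensorimotor, occipital, cerebellum, vermis and
  "other" parcels. A tentorium-like non-brain gap separates the
  cerebellar cap from the cerebrum, as in a real brain mask; without it,
  smoothing makes the posterior "apparent preservation" gradient
  spatially contiguous with the cerebellum and no threshold can isolate
  the cap. The 12 mm kernel still bridges the thin gap partially, which
  the tests quantify (the residual leakage is an order of magnitude
  smaller than the simulated deficit).
* **Disease topography.** Affected parcels (frontal, anterior-temporal)
  carry weight 1; the remaining cerebrum carries weight 0.6 — widespread
  substantial but milder involvement, consistent with extensive deficits
  at mild disease stages; the vermis is nearly spared (0.05) so the
  cerebellar cap stays internally coherent; the cerebellum is fully
  spared. With this profile the mild tier sits close to the global mean,
  so under CGM normalization only the truly spared cap shows a strong
  apparent increase — the phenomenon the reference-cluster method feeds
  on — while under cerebellar normalization the mild tier is genuinely
  detectable, reproducing the characteristic extent ordering
  CGM < SMC < CBL ≤ RC.
* **Biological variability.** The field amplitude is damped in the
  cerebellum/vermis (weight 0.3) — cerebellar uptake is notably stable
  across subjects, which is the empirical reason it serves as a reference
  region — and amplified in association cortex ("other", weight 2).
  The heterogeneous cortex contributes variance to the global mean that
  ROI references avoid; this is what breaks the otherwise scale-invariant
  trade-off between CGM's signal compression and its noise averaging, and
  it is the mechanism by which reference quality translates into
  classification accuracy.
* **Two-center presets.** `center1` is the default; `center2` has a
  rescaled baseline vector, more scanner noise (12 vs 8), a wider global
  scale (0.13 vs 0.10) and a much larger biological amplitude (0.09 vs
  0.02), emulating both a different acquisition protocol and the more
  heterogeneous control population of a memory-clinic setting. Accuracy
  at center 2 is therefore noise-limited rather than ceiling-limited,
  which is where the choice of reference region matters.
* **Cohort covariates.** Ages are Normal(62, 9) clipped to [40, 90]; sex
  is Bernoulli(0.5). Covariates are generated independently of the images,
  so the permutation null's exchangeability assumption holds exactly.

What the phantom does **not** model: PET physics (attenuation, scatter,
reconstruction), anatomical realism, partial-volume effects, multiple
disease subtypes, or site-specific spatial-normalization error. Passing
tests therefore demonstrate the statistical machinery and the logic of the
reference-cluster method under a controlled generative model — not
clinical performance on real scans.

## Classification evaluation

Discrimination uses one scalar feature per subject — the mean normalized
uptake inside an evaluation pattern — in a logistic model fit by IRLS with
a ridge of 10⁻⁸ on the slope (convergence under perfect separation; at
feature scales near 1 the ridge is far below the likelihood curvature and
does not move the boundary). Decision threshold is probability 0.5.
Repeated split-half cross-validation (default 5000 repetitions) splits
each class separately (stratified; odd counts send the extra subject to
training) and scores accuracy, sensitivity and specificity on the held-out
half. Note that a single fixed null cohort carries accidental separation
that resplitting cannot remove; chance level (0.5) emerges in expectation
over cohorts, which is how the chance-level control is computed.
Scheme comparisons use independent-sample t-tests on the per-repetition
accuracy arrays with Bonferroni correction over pairs — the field's
customary but anticonservative comparison, flagged as such in the output.

The evaluation pattern can be the pattern detected under cerebellar
normalization (the field's reference standard) or the overlap of the
patterns detected under all schemes. On the phantom the mild-tier deficit
is so widespread that the cerebellar-normalization pattern approaches the
whole cerebrum, which makes its mean nearly proportional to the global
mean and blunts scheme differences; the overlap pattern — which the CGM
scheme restricts to tissue more affected than the global mean, i.e. the
truly affected parcels — is focal, and is therefore what the acceptance
analysis uses for the cross-center comparison.

## Numerical choices and degenerate inputs

* Grid compatibility is asserted to 10⁻⁵ mm; no implicit resampling ever.
* `NaN` marks out-of-brain voxels; every reduction ignores it; a voxel
  non-finite in any subject leaves the analysis mask.
* Permutation draws that make the permuted design rank-deficient (possible
  when a permuted group column collides with a binary covariate) are
  redrawn; in exhaustive mode they are dropped with a warning.
* Cluster size thresholds use `quantile(type = 1)` on the integer null;
  cluster p-values use the add-one convention `(1+b)/(nPerm+1)`.
* Problem sizes used by the validation suite: 24³ null phantoms with
  10v10 subjects and 199 permutations for calibration (200 cohorts), 32³
  with 20v20 for recovery and ordering properties (10–20 seeds), 13v11
  for the second center, 500–5000 CV repetitions. These were chosen as
  the smallest sizes at which the targeted effects are comfortably
  resolvable.
* Every stochastic stage takes an explicit seed; `runStudy()` derives
  stage seeds deterministically from one global seed and reruns are
  bitwise identical.

## Known limitations

* Bonferroni inside the escalation is conservative where voxels are
  strongly correlated (smoothed data); the achieved alpha is therefore
  below nominal at each level, which biases the derived cluster towards
  compactness. The permutation method is available down to alphas of
  `1/(nPerm+1)`.
* The coherence rule is purely topological; an optional atlas-composition
  criterion would require shipping a parcellation, which is out of scope —
  a `LabelVolume` can be supplied to record composition instead.
* With 18-connectivity and heavy smoothing, nearby but distinct spared
  regions can merge through blend voxels; the phantom's tentorial gap
  mirrors the anatomical separation that prevents this in real data.
* Independent-sample t-tests on resampled accuracies understate the
  variance of the mean accuracy; the pairwise comparison p-values should
  be read as descriptive orderings, not calibrated error rates.
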