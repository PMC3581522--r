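# refclust

Data-driven **reference-cluster (RC) intensity normalization** for brain
metabolic imaging (FDG-PET and kin), with the statistical machinery needed
to evaluate it end to end: voxel-wise group GLMs with permutation
family-wise-error control, cluster-extent inference, and split-half
cross-validated patient/control discrimination — all exercisable on
synthetic smoothed-PET phantoms with known ground truth.

## The problem

PET uptake images are not quantitative: each scan carries an arbitrary
per-subject global scale, so images must be rescaled to a reference before
subjects can be compared. The classic choices are the **cerebral global
mean** (CGM), the **cerebellum** (CBL), or the **primary sensorimotor
cortex** (SMC). In neurodegeneration all of these are problematic: when
patients have extensive regional hypometabolism their global mean is itself
depressed, so CGM scaling *underestimates* true deficits and manufactures
spurious "hypermetabolism" in spared regions; and a-priori reference ROIs
may be partially affected by disease or contaminated by smoothing at their
borders.

The reference-cluster approach turns the CGM artifact into a tool. After
global-mean normalization, a voxel-wise two-sample GLM

&nbsp;&nbsp;&nbsp;&nbsp;*y*<sub>v</sub> = β₀ + β₁·group + β₂·age + β₃·sex + ε,&nbsp;&nbsp;
*t*<sub>v</sub> = *c*ᵀβ̂ / √(σ̂²·*c*ᵀ(XᵀX)⁻¹*c*)

is thresholded on the *patients > controls* contrast at escalating
voxel-level FWE levels (0.05, 0.01, 10⁻³, …, 10⁻⁶) until the
suprathreshold set collapses onto one coherent connected component — the
tissue with *most preserved* uptake. That cluster becomes the
normalization reference for all subsequent analyses, including data from
other imaging centers.

## What the package provides

- `readVolume()` / `writeVolume()` — NIfTI I/O with opaque geometry,
  strict grid checking (`assertSameGrid()`), `NaN` out-of-brain sentinels.
- `spmGlobalMean()`, `roiMean()`, `normalizeVolume()` — the two-pass
  mean/8 global-mean rule and ratio normalization to any reference.
- `fitGLM()`, `voxelFweThreshold()`, `clusterInference()`,
  `connectedComponents()` — voxel-wise OLS with nuisance covariates,
  max-statistic permutation (or Bonferroni) voxel-level FWE, and
  permutation cluster-extent inference at a p<0.001 forming threshold with
  a k>100 extent filter (18-connectivity).
- `deriveReferenceCluster()` — the threshold-escalation RC search with
  full provenance; `exportReferenceCluster()` ships the mask for reuse.
- `extractPatternMeans()`, `splitHalfCV()`, `compareDistributions()` —
  single-feature logistic discrimination under repeated (default 5000×)
  stratified split-half cross-validation, with pairwise scheme comparisons.
- `simulateCohort()` / `centerPreset()` — a synthetic two-center phantom:
  smoothed (12 mm FWHM, 2 mm voxels) volumes of controls and patients with
  frontal/anterior-temporal hypometabolism, widespread milder cortical
  involvement, a spared cerebellum analog, per-subject global scale,
  biological variability and scanner noise — every downstream claim is
  testable against its ground-truth masks.
- `runStudy()` — the full two-cohort design in one call (simulate or
  ingest, normalize four ways, detect decreases/increases, derive the RC
  on cohort A and apply it to cohort B, evaluate, compare), fully seeded
  and bitwise-reproducible. A thin CLI lives in `inst/exec/refclust`.

## Worked example

```r
library(refclust)

sim <- simulateCohort(centerPreset("center1"), nControls = 20,
                      nPatients = 20, seed = 7)
design <- buildDesign(sim$manifest)

## derive the reference cluster from the CGM-normalized increase contrast
cgm <- normalizeCohort(sim$volumes, referenceSpec("cgm"))
rc  <- deriveReferenceCluster(cgm, design, mask = sim$truth@brainMask)
rc
#> ReferenceRegion: 946 voxels at voxel-FWE alpha 0.05 (bonferroni), coherence 0.931
diceCoefficient(rc@mask, sim$truth@preservedMask)
#> [1] 0.8255675

## detection of hypometabolism under two normalizations
cbl <- maskFromLabels(sim$truth@parcellation, "cerebellum")
for (ref in list(referenceSpec("cgm"), referenceSpec("roi", cbl, "CBL"),
                 referenceSpec("roi", rc@mask, "RC"))) {
  nv <- normalizeCohort(sim$volumes, ref)
  cs <- clusterInference(nv, design, "decrease", nPerm = 199, seed = 1,
                         mask = sim$truth@brainMask)
  cat(ref@name, ": extent", totalExtent(cs), "voxels, peak t",
      round(peakT(cs), 1), "\n")
}
#> CGM : extent 4242 voxels, peak t 12.9
#> CBL : extent 11977 voxels, peak t 18.8
#> RC : extent 11990 voxels, peak t 18.7
```

The detected hypometabolic extent grows CGM < CBL ≤ RC: global-mean
scaling hides most of the mild widespread deficit (it only finds tissue
*more* affected than the average), while the data-driven cluster, being
the least-biased reference, recovers the most. The RC mask overlaps the
true spared cerebellar parcel at Dice ≈ 0.8.

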