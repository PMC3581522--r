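#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' BrainVolume: a 3D scalar brain image
#'
#' Container for one subject's 3D scalar grid (uptake in arbitrary units)
#' together with its voxel geometry. The affine/header geometry is carried
#' opaquely from input to output and never used for resampling: all
#' processing happens in voxel space and volumes entering a joint analysis
#' must already share a grid (see [assertSameGrid()]). `NaN`/`NA` is the
#' sentinel for out-of-brain voxels; every reduction in the package ignores
#' them.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot geometry opaque geometry (an `RNifti` header list or `NULL`),
#'   round-tripped unchanged through [writeVolume()] / [readVolume()].
#'
#' @seealso [readVolume()], [writeVolume()], [voxelData()]
#' @export
setClass("BrainVolume",
  representation(data = "array", voxelSize = "numeric", geometry = "ANY"),
  prototype(voxelSize = c(2, 2, 2), geometry = NULL))

setValidity("BrainVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all grid dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive finite values (mm)")
  TRUE
})

#' MaskVolume: a binary region mask
#'
#' A 0/1 volume on the same grid as its companion images; used for reference
#' regions, analysis masks, detected patterns, and phantom ground truth.
#'
#' @slot data 3D array of 0/1 values (no `NA`).
#' @slot voxelSize,geometry as in [BrainVolume-class].
#' @export
setClass("MaskVolume", contains = "BrainVolume")

setValidity("MaskVolume", function(object) {
  v <- object@data
  if (anyNA(v)) return("mask must not contain NA")
  if (!all(v == 0 | v == 1)) return("mask values must be 0 or 1")
  TRUE
})

#' LabelVolume: an integer parcellation
#'
#' Non-negative integer labels on the image grid, with 0 as background, plus
#' a label table mapping each nonzero label to a parcel name. Stands in for
#' an anatomical atlas parcellation.
#'
#' @slot data 3D array of non-negative integers.
#' @slot labelTable named integer vector: values are labels, names are
#'   parcel names; every nonzero label present in the grid must appear.
#' @export
setClass("LabelVolume", contains = "BrainVolume",
  representation(labelTable = "integer"))

setValidity("LabelVolume", function(object) {
  v <- object@data
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    return("labels must be non-negative integers")
  present <- setdiff(unique(as.integer(v)), 0L)
  if (!all(present %in% object@labelTable))
    return("every nonzero label in the grid must appear in labelTable")
  if (is.null(names(object@labelTable)) || anyNA(names(object@labelTable)))
    return("labelTable must be a named integer vector")
  TRUE
})

#' ReferenceSpec: how to compute a normalization reference value
#'
#' @slot kind `"cgm"` (cerebral global mean via the two-pass SPM rule) or
#'   `"roi"` (mean over a mask).
#' @slot mask a [MaskVolume-class] (required iff `kind == "roi"`).
#' @slot name short display name, e.g. `"CGM"`, `"CBL"`, `"SMC"`, `"RC"`.
#' @seealso [referenceSpec()], [normalizeVolume()]
#' @export
setClass("ReferenceSpec",
  representation(kind = "character", mask = "ANY", name = "character"),
  prototype(mask = NULL))

setValidity("ReferenceSpec", function(object) {
  if (!object@kind %in% c("cgm", "roi")) return("kind must be 'cgm' or 'roi'")
  if (object@kind == "roi") {
    if (!is(object@mask, "MaskVolume")) return("roi reference requires a MaskVolume")
    if (sum(object@mask@data) < 1) return("roi reference mask is empty")
  }
  TRUE
})

#' NormalizedVolume: an intensity-normalized image
#'
#' A [BrainVolume-class] rescaled so that the mean within its reference
#' equals `target`; keeps the pre-normalization reference value for
#' provenance.
#'
#' @slot reference the [ReferenceSpec-class] used.
#' @slot referenceValue scalar mean in the reference before rescaling.
#' @slot target scalar the reference mean was mapped to (default 1).
#' @export
setClass("NormalizedVolume", contains = "BrainVolume",
  representation(reference = "ReferenceSpec", referenceValue = "numeric",
                 target = "numeric"))

#' GroupDesign: per-cohort model matrix with group contrasts
#'
#' Columns: intercept, group indicator (patient = 1), mean-centered age, sex
#' (dropped with a warning if constant). The decrease contrast is
#' `-1` on the group column (patients lower), the increase contrast `+1`.
#'
#' @slot X numeric model matrix, one row per subject (row names = subject ids).
#' @slot groupCol index of the group indicator column.
#' @slot group integer 0/1 group labels (patient = 1), in row order.
#' @slot dropped character vector of covariate columns dropped for rank
#'   deficiency (provenance).
#' @seealso [buildDesign()], [contrastVector()]
#' @export
setClass("GroupDesign",
  representation(X = "matrix", groupCol = "integer", group = "integer",
                 dropped = "character"))

setValidity("GroupDesign", function(object) {
  X <- object@X
  if (nrow(X) <= ncol(X)) return("need more subjects than design columns")
  if (qr(X)$rank < ncol(X)) return("design matrix is rank deficient")
  g <- X[, object@groupCol]
  if (!all(g %in% c(0, 1))) return("group column must be 0/1")
  if (length(unique(g)) < 2L) return("both groups must be present")
  TRUE
})

#' TStatResult: voxel-wise GLM t-statistics
#'
#' Per-voxel ordinary-least-squares fit of a [GroupDesign-class] over the
#' analysis mask (voxels finite in every subject, optionally intersected
#' with a user mask), with the t-statistic for one contrast.
#'
#' @slot tMap 3D array of t values, `NaN` outside the analysis mask; voxels
#'   with zero residual variance carry `+/-Inf` sentinels (see `zeroVar`).
#' @slot df residual degrees of freedom, n - rank(X).
#' @slot beta p x V matrix of coefficient estimates over in-mask voxels.
#' @slot sigma2 numeric(V) residual variance per in-mask voxel.
#' @slot maskIdx integer linear indices of in-mask voxels (column order of
#'   `beta`/`sigma2`).
#' @slot analysisMask [MaskVolume-class] of analysed voxels.
#' @slot contrast numeric contrast vector applied.
#' @slot zeroVar logical(V) flag for zero-residual-variance voxels.
#' @seealso [fitGLM()]
#' @export
setClass("TStatResult",
  representation(tMap = "array", df = "numeric", beta = "matrix",
                 sigma2 = "numeric", maskIdx = "integer",
                 analysisMask = "MaskVolume", contrast = "numeric",
                 zeroVar = "logical"))

#' ClusterSet: suprathreshold connected components
#'
#' Clusters from 3D connected-component labelling of a suprathreshold mask,
#' sorted by decreasing size, with optional peak statistics and (after
#' [clusterInference()]) permutation cluster-level p-values.
#'
#' @slot clusters list, one element per cluster: `indices` (linear voxel
#'   indices), `size`, `peakT`, `peakIJK`, and for inference results
#'   `pFWE`.
#' @slot formingThreshold t threshold that binarized the map (`NA` when the
#'   input was already binary).
#' @slot connectivity 6, 18 or 26.
#' @slot dim grid dimensions.
#' @slot nullMaxSize numeric, permutation null of maximum cluster size
#'   (empty unless produced by [clusterInference()]).
#' @seealso [connectedComponents()], [clusterInference()], [totalExtent()]
#' @export
setClass("ClusterSet",
  representation(clusters = "list", formingThreshold = "numeric",
                 connectivity = "integer", dim = "integer",
                 nullMaxSize = "numeric"),
  prototype(nullMaxSize = numeric(0)))

#' ReferenceRegion: a data-driven reference cluster
#'
#' The spared-tissue cluster found by escalating voxel-level FWE thresholds
#' on the patients-greater-than-controls contrast of global-mean-normalized
#' images, plus full escalation provenance.
#'
#' @slot mask binary [MaskVolume-class] of the cluster.
#' @slot provenance list: `alpha` achieved, `path` (data.frame of the
#'   escalation: alpha, threshold, suprathreshold count, number of
#'   components, largest-component fraction), `size`, `coherence`
#'   (largest-component fraction at the accepted level), `method`, `df`.
#' @seealso [deriveReferenceCluster()], [exportReferenceCluster()]
#' @export
setClass("ReferenceRegion",
  representation(mask = "MaskVolume", provenance = "list"))

setValidity("ReferenceRegion", function(object) {
  if (sum(object@mask@data) < 1) return("reference region is empty")
  TRUE
})

#' AccuracyDistribution: split-half cross-validation metrics
#'
#' Per-repetition accuracy, sensitivity and specificity from repeated
#' stratified split-half cross-validation of a single-feature logistic
#' classifier.
#'
#' @slot accuracy,sensitivity,specificity numeric vectors of length `nRep`,
#'   all in \[0, 1\].
#' @slot nRep number of repetitions.
#' @slot seed RNG seed used.
#' @slot scheme name of the normalization scheme evaluated.
#' @seealso [splitHalfCV()], [compareDistributions()]
#' @export
setClass("AccuracyDistribution",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", nRep = "integer",
                 seed = "integer", scheme = "character"))

setValidity("AccuracyDistribution", function(object) {
  n <- object@nRep
  if (length(object@accuracy) != n || length(object@sensitivity) != n ||
      length(object@specificity) != n)
    return("metric arrays must all have length nRep")
  rng <- range(c(object@accuracy, object@sensitivity, object@specificity))
  if (rng[1] < 0 || rng[2] > 1) return("metrics must lie in [0, 1]")
  TRUE
})

#' PhantomParams: synthetic cohort generator settings
#'
#' Parameters of the smoothed-PET phantom; see [phantomParams()] for the
#' meaning and defaults of each field.
#'
#' @seealso [phantomParams()], [centerPreset()], [simulateCohort()]
#' @export
setClass("PhantomParams",
  representation(shape = "integer", voxelSize = "numeric",
                 baseline = "numeric", hypometabolismFactor = "numeric",
                 affected = "character", preserved = "character",
                 severityWeights = "numeric", subjectScaleSd = "numeric",
                 severitySd = "numeric", biolSd = "numeric",
                 biolWeights = "numeric",
                 biolFwhm = "numeric", noiseSd = "numeric",
                 smoothingFwhm = "numeric"))

setValidity("PhantomParams", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 4L))
    return("shape must be 3 dimensions >= 4")
  if (object@hypometabolismFactor <= 0)
    return("hypometabolismFactor must be > 0")
  if (any(object@baseline <= 0)) return("baseline uptake must be > 0")
  if (length(intersect(object@affected, object@preserved)) > 0)
    return("affected and preserved parcels must be disjoint")
  if (!all(c(object@affected, object@preserved) %in% names(object@baseline)))
    return("affected/preserved must name parcels present in baseline")
  sigmaVox <- object@smoothingFwhm / 2.3548 / min(object@voxelSize)
  if (sigmaVox >= 3 && any(object@shape < 16L))
    return("shape components must be >= 16 when smoothing is >= 3 voxels FWHM")
  TRUE
})

#' PhantomTruth: ground truth for a synthetic cohort
#'
#' @slot parcellation [LabelVolume-class] parcel labels.
#' @slot affectedMask,preservedMask,brainMask [MaskVolume-class] ground-truth
#'   masks (affected and preserved are disjoint, all inside the brain mask).
#' @slot subjectScales numeric, per-subject true global scales (filled by
#'   [simulateCohort()]).
#' @export
setClass("PhantomTruth",
  representation(parcellation = "LabelVolume", affectedMask = "MaskVolume",
                 preservedMask = "MaskVolume", brainMask = "MaskVolume",
                 subjectScales = "numeric"),
  prototype(subjectScales = numeric(0)))

setValidity("PhantomTruth", function(object) {
  a <- object@affectedMask@data; p <- object@preservedMask@data
  b <- object@brainMask@data
  if (any(a * p != 0)) return("affected and preserved masks must be disjoint")
  if (any(a > b) || any(p > b)) return("all masks must lie inside the brain mask")
  TRUE
})
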