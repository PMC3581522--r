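#' Cerebral global mean via the two-pass mean/8 rule
#'
#' The classic SPM global-calculation rule: first pass, the mean `m0` of
#' all finite voxels; second pass, the mean of finite voxels strictly above
#' `m0 / 8`. The thresholding suppresses out-of-brain and CSF voxels so the
#' estimate approximates mean cerebral uptake. `NaN` voxels are excluded
#' from both passes.
#'
#' @param img a [BrainVolume-class].
#' @return scalar global mean.
#' @export
spmGlobalMean <- function(img) {
  stopifnot(is(img, "BrainVolume"))
  v <- img@data[is.finite(img@data)]
  if (length(v) == 0L) stop("image has no finite voxels")
  m0 <- mean(v)
  keep <- v > m0 / 8
  if (!any(keep))
    stop("degenerate image: no voxel exceeds mean/8 threshold")
  mean(v[keep])
}

#' Mean uptake inside a region of interest
#'
#' Arithmetic mean over masked finite voxels.
#'
#' @param img a [BrainVolume-class].
#' @param mask a [MaskVolume-class] on the same grid.
#' @return scalar ROI mean.
#' @export
roiMean <- function(img, mask) {
  stopifnot(is(img, "BrainVolume"), is(mask, "MaskVolume"))
  assertSameGrid(img, mask)
  v <- img@data[mask@data > 0]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("mask covers no finite voxels")
  mean(v)
}

#' Construct a reference specification
#'
#' @param kind `"cgm"` (two-pass global mean) or `"roi"` (mask mean).
#' @param mask [MaskVolume-class], required for `kind = "roi"`.
#' @param name display name (defaults to upper-case `kind`).
#' @return a [ReferenceSpec-class].
#' @export
referenceSpec <- function(kind = c("cgm", "roi"), mask = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (is.null(name)) name <- toupper(kind)
  new("ReferenceSpec", kind = kind, mask = mask, name = name)
}

#' Intensity-normalize a volume to a reference
#'
#' Rescales the image by `target / referenceValue`, where the reference
#' value is the two-pass global mean (`kind = "cgm"`) or the ROI mean
#' (`kind = "roi"`). After normalization the mean within the reference
#' equals `target` exactly (to floating point). The operation is invariant
#' to any positive rescaling of the input, which is what makes
#' non-quantitative uptake images comparable across subjects.
#'
#' @param img a [BrainVolume-class].
#' @param ref a [ReferenceSpec-class] (or a [MaskVolume-class] /
#'   [ReferenceRegion-class], taken as an ROI reference).
#' @param target reference mean after normalization (default 1, a
#'   dimensionless ratio scale).
#' @return a [NormalizedVolume-class].
#' @export
normalizeVolume <- function(img, ref, target = 1.0) {
  stopifnot(is(img, "BrainVolume"))
  if (is(ref, "ReferenceRegion"))
    ref <- referenceSpec("roi", mask = ref@mask, name = "RC")
  if (is(ref, "MaskVolume")) ref <- referenceSpec("roi", mask = ref)
  stopifnot(is(ref, "ReferenceSpec"))
  refVal <- if (ref@kind == "cgm") spmGlobalMean(img)
            else roiMean(img, ref@mask)
  if (!is.finite(refVal) || refVal <= 0)
    stop("non-positive reference value (", format(refVal),
         ") in reference '", ref@name, "': pathological mask or data")
  new("NormalizedVolume", data = img@data * (target / refVal),
      voxelSize = img@voxelSize, geometry = img@geometry,
      reference = ref, referenceValue = refVal, target = target)
}

#' Normalize a whole cohort
#'
#' Applies [normalizeVolume()] with one reference to every volume of a
#' cohort.
#'
#' @param volumes list of [BrainVolume-class].
#' @inheritParams normalizeVolume
#' @return list of [NormalizedVolume-class].
#' @export
normalizeCohort <- function(volumes, ref, target = 1.0) {
  lapply(.asVolumeList(volumes), normalizeVolume, ref = ref, target = target)
}
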