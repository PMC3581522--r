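#' Accessors for volume objects
#'
#' `voxelData()` returns the raw 3D array, `voxelSize()` the voxel edge
#' lengths in mm, `gridDim()` the grid dimensions.
#'
#' @param x a [BrainVolume-class] (or subclass).
#' @return `voxelData`: 3D array; `voxelSize`: numeric(3); `gridDim`:
#'   integer(3).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelData
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "BrainVolume", function(x) x@data)

#' @rdname voxelData
#' @export
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)

#' @rdname voxelData
#' @export
setMethod("gridDim", "BrainVolume", function(x) dim(x@data))

#' Total surviving cluster extent
#'
#' Sum of cluster sizes (in voxels) in a [ClusterSet-class]; the quantity
#' reported per normalization scheme when comparing detection sensitivity.
#'
#' @param x a [ClusterSet-class].
#' @return integer total number of voxels across clusters.
#' @export
setGeneric("totalExtent", function(x) standardGeneric("totalExtent"))

#' @rdname totalExtent
#' @export
setMethod("totalExtent", "ClusterSet", function(x)
  sum(vapply(x@clusters, function(cl) cl$size, numeric(1))))

#' Peak t-value across clusters
#'
#' @param x a [ClusterSet-class].
#' @return numeric peak |t| over all clusters (`NA` if none or if the set
#'   was built from a plain binary mask).
#' @export
setGeneric("peakT", function(x) standardGeneric("peakT"))

#' @rdname peakT
#' @export
setMethod("peakT", "ClusterSet", function(x) {
  if (length(x@clusters) == 0L) return(NA_real_)
  suppressWarnings(max(vapply(x@clusters, function(cl)
    if (is.null(cl$peakT)) NA_real_ else cl$peakT, numeric(1)), na.rm = TRUE))
})

#' Number of clusters
#' @param x a [ClusterSet-class].
#' @return integer count of clusters.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname nClusters
#' @export
setMethod("nClusters", "ClusterSet", function(x) length(x@clusters))

#' Cluster masks as binary volumes
#'
#' @param x a [ClusterSet-class].
#' @param which cluster indices (default all).
#' @param merge if `TRUE` (default) return one [MaskVolume-class] covering
#'   the union; otherwise a list of per-cluster masks.
#' @param voxelSize voxel size to stamp on the result (mm).
#' @return a [MaskVolume-class] or list thereof.
#' @export
setGeneric("clusterMask", function(x, which = seq_along(x@clusters),
                                   merge = TRUE, voxelSize = c(2, 2, 2))
  standardGeneric("clusterMask"))

#' @rdname clusterMask
#' @export
setMethod("clusterMask", "ClusterSet", function(x, which, merge, voxelSize) {
  one <- function(idx) {
    arr <- array(0, dim = x@dim)
    arr[idx] <- 1
    new("MaskVolume", data = arr, voxelSize = voxelSize, geometry = NULL)
  }
  if (merge) {
    one(unlist(lapply(x@clusters[which], function(cl) cl$indices)))
  } else {
    lapply(x@clusters[which], function(cl) one(cl$indices))
  }
})

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("(voxels %.3g x %.3g x %.3g mm)\n", object@voxelSize[1],
              object@voxelSize[2], object@voxelSize[3]))
  v <- object@data[is.finite(object@data)]
  if (length(v))
    cat(sprintf("  finite voxels: %d, range [%.4g, %.4g]\n",
                length(v), min(v), max(v)))
})

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d, %d voxels set\n",
      d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "NormalizedVolume", function(object) {
  callNextMethod()
  cat(sprintf("  normalized to %s (%s): reference value %.6g -> target %g\n",
              object@reference@name, object@reference@kind,
              object@referenceValue, object@target))
})

setMethod("show", "GroupDesign", function(object) {
  cat("GroupDesign:", nrow(object@X), "subjects x", ncol(object@X),
      "columns [", paste(colnames(object@X), collapse = ", "), "]\n")
  cat(sprintf("  %d controls, %d patients\n",
              sum(object@group == 0L), sum(object@group == 1L)))
  if (length(object@dropped))
    cat("  dropped (rank):", paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "TStatResult", function(object) {
  cat("TStatResult: df =", object@df, ",", length(object@maskIdx),
      "in-mask voxels\n")
  tv <- object@tMap[object@maskIdx]
  tv <- tv[is.finite(tv)]
  if (length(tv))
    cat(sprintf("  t range [%.3f, %.3f]; %d zero-variance voxels\n",
                min(tv), max(tv), sum(object@zeroVar)))
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(object@clusters), "cluster(s),",
      object@connectivity, "-connectivity", sep = "")
  if (is.finite(object@formingThreshold))
    cat(", forming t >", format(object@formingThreshold, digits = 4))
  cat("\n")
  for (cl in utils::head(object@clusters, 5)) {
    cat(sprintf("  size %d", cl$size))
    if (!is.null(cl$peakT)) cat(sprintf(", peak t %.2f", cl$peakT))
    if (!is.null(cl$pFWE)) cat(sprintf(", cluster pFWE %.4g", cl$pFWE))
    cat("\n")
  }
  if (length(object@clusters) > 5) cat("  ...\n")
})

setMethod("show", "ReferenceRegion", function(object) {
  p <- object@provenance
  cat(sprintf("ReferenceRegion: %d voxels at voxel-FWE alpha %.2g (%s), coherence %.3f\n",
              sum(object@mask@data), p$alpha, p$method, p$coherence))
})

setMethod("show", "AccuracyDistribution", function(object) {
  cat(sprintf("AccuracyDistribution [%s], %d repetitions:\n",
              object@scheme, object@nRep))
  cat(sprintf("  accuracy    %.3f +/- %.3f\n", mean(object@accuracy),
              stats::sd(object@accuracy)))
  cat(sprintf("  sensitivity %.3f +/- %.3f\n", mean(object@sensitivity),
              stats::sd(object@sensitivity)))
  cat(sprintf("  specificity %.3f +/- %.3f\n", mean(object@specificity),
              stats::sd(object@specificity)))
})

setMethod("show", "PhantomParams", function(object) {
  cat("PhantomParams:", paste(object@shape, collapse = " x "), "grid,",
      object@smoothingFwhm, "mm FWHM smoothing\n")
  cat("  parcels:", paste(names(object@baseline), collapse = ", "), "\n")
  cat(sprintf("  hypometabolism factor %.3g in {%s}; preserved {%s}\n",
              object@hypometabolismFactor,
              paste(object@affected, collapse = ", "),
              paste(object@preserved, collapse = ", ")))
})
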