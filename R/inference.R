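# Permutation engine shared by voxel-level and cluster-level FWE.
#
# Permutes the group labels across subjects while nuisance covariates stay
# attached to their subjects, refits the GLM, and summarises each permuted
# t-vector (max t, max suprathreshold cluster size, ...). `exhaustive`
# enumerates every distinct group assignment instead of sampling.
.permNull <- function(Y, X, groupCol, cvec, nPerm, seed = NULL,
                      exhaustive = FALSE, summarise) {
  g0 <- X[, groupCol]
  n <- nrow(X)
  n1 <- sum(g0 == 1)
  tryStat <- function(Xp) {
    fit <- tryCatch(.glmCore(Y, Xp, cvec), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    summarise(fit$t)
  }
  if (exhaustive) {
    combs <- utils::combn(n, n1)
    N <- ncol(combs)
    null <- vapply(seq_len(N), function(j) {
      g <- numeric(n); g[combs[, j]] <- 1
      Xp <- X; Xp[, groupCol] <- g
      tryStat(Xp)
    }, numeric(1))
    if (anyNA(null)) {
      warning("dropping ", sum(is.na(null)),
              " degenerate relabeling(s) from the exhaustive null")
      null <- null[!is.na(null)]
      N <- length(null)
    }
    return(list(null = null, N = N, exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  null <- numeric(nPerm)
  attempts <- 0L
  b <- 1L
  while (b <= nPerm) {
    Xp <- X
    Xp[, groupCol] <- g0[sample.int(n)]
    s <- tryStat(Xp)
    attempts <- attempts + 1L
    if (is.na(s)) {
      if (attempts > 10L * nPerm) stop("too many degenerate permutations")
      next
    }
    null[b] <- s
    b <- b + 1L
  }
  list(null = null, N = nPerm, exhaustive = FALSE)
}

.maxFiniteT <- function(tvec) {
  tf <- tvec[is.finite(tvec)]
  if (!length(tf)) return(-Inf)
  max(tf)
}

# Observed fit plus the matrices the permutation engine needs.
.prepareGLM <- function(volumes, design, contrast, mask) {
  volumes <- .asVolumeList(volumes)
  cvec <- contrastVector(design, contrast)
  maskIdx <- .commonFiniteIdx(volumes, mask)
  if (length(maskIdx) == 0L) stop("analysis mask is empty")
  Y <- .stackVolumes(volumes, maskIdx)
  obs <- .glmCore(Y, design@X, cvec)
  list(Y = Y, X = design@X, cvec = cvec, maskIdx = maskIdx, obs = obs,
       dim = dim(volumes[[1]]@data), voxelSize = volumes[[1]]@voxelSize)
}

#' Voxel-level family-wise-error threshold
#'
#' Computes the one-sided t threshold controlling the family-wise error
#' over all analysed voxels at level `alpha`, either by the permutation
#' distribution of the maximum t (group labels permuted across subjects,
#' covariates kept; exact under exchangeability) or by Bonferroni over the
#' in-mask voxel count. Zero-residual-variance voxels are excluded from the
#' max-statistic null.
#'
#' @inheritParams fitGLM
#' @param alpha FWE level in (0, 1).
#' @param method `"permutation"` or `"bonferroni"`.
#' @param nPerm number of random permutations (>= 100) for the permutation
#'   method.
#' @param seed RNG seed for the permutation draw.
#' @param exhaustive enumerate all distinct group assignments instead of
#'   sampling (small cohorts only).
#' @return scalar t threshold, with attributes `method`, `alpha`, `df`,
#'   and for permutation `nullMaxT` (the null sample) and `nPerm`.
#' @export
voxelFweThreshold <- function(volumes, design, contrast = "increase",
                              alpha = 0.05,
                              method = c("permutation", "bonferroni"),
                              nPerm = 1000, seed = NULL, exhaustive = FALSE,
                              mask = NULL) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  prep <- .prepareGLM(volumes, design, contrast, mask)
  df <- prep$obs$df
  if (method == "bonferroni") {
    V <- length(prep$maskIdx)
    thr <- stats::qt(1 - alpha / V, df)
    return(structure(thr, method = "bonferroni", alpha = alpha, df = df,
                     V = V))
  }
  n <- nrow(prep$X); n1 <- sum(prep$X[, design@groupCol] == 1)
  if (choose(n, n1) < 1 / alpha)
    stop("only ", choose(n, n1), " distinct relabelings available; ",
         "cannot control FWE at alpha = ", alpha,
         " by permutation - use method = 'bonferroni'")
  if (!exhaustive && nPerm < 100) stop("nPerm must be >= 100")
  pn <- .permNull(prep$Y, prep$X, design@groupCol, prep$cvec, nPerm, seed,
                  exhaustive, summarise = .maxFiniteT)
  k <- if (pn$exhaustive) floor(alpha * pn$N) else floor(alpha * (pn$N + 1))
  if (k < 1)
    stop("nPerm too small to resolve alpha = ", alpha,
         "; increase nPerm or use method = 'bonferroni'")
  thr <- sort(pn$null, decreasing = TRUE)[k]
  structure(thr, method = "permutation", alpha = alpha, df = df,
            nullMaxT = pn$null, nPerm = pn$N, exhaustive = pn$exhaustive)
}

#' Voxel-wise permutation test with FWE-corrected p-values
#'
#' Runs the max-statistic permutation test and returns, for every analysed
#' voxel, the FWE-corrected p-value: the proportion of (re)labelings whose
#' maximum t reaches the voxel's observed t. With `exhaustive = TRUE` the
#' p-values are exact; otherwise the add-one convention
#' `(1 + #exceedances) / (nPerm + 1)` is used.
#'
#' @inheritParams voxelFweThreshold
#' @return list with `tObs` (observed t per in-mask voxel), `pFWE`
#'   (corrected p-values), `maskIdx`, `null` (max-t null sample), `df`.
#' @export
voxelPermutationTest <- function(volumes, design, contrast = "increase",
                                 nPerm = 1000, seed = NULL,
                                 exhaustive = FALSE, mask = NULL) {
  prep <- .prepareGLM(volumes, design, contrast, mask)
  pn <- .permNull(prep$Y, prep$X, design@groupCol, prep$cvec, nPerm, seed,
                  exhaustive, summarise = .maxFiniteT)
  tObs <- prep$obs$t
  exceed <- vapply(tObs, function(t) sum(pn$null >= t), numeric(1))
  pFWE <- if (pn$exhaustive) exceed / pn$N else (1 + exceed) / (pn$N + 1)
  list(tObs = tObs, pFWE = pFWE, maskIdx = prep$maskIdx, null = pn$null,
       df = prep$obs$df)
}

#' 3D connected components of a binary mask
#'
#' Maximal connected components under 6-, 18- (default, the SPM
#' convention: faces + edges) or 26-neighbour contiguity, sorted by
#' decreasing size.
#'
#' @param binary a [MaskVolume-class] (or 0/1/logical 3D array).
#' @param connectivity 6, 18 or 26.
#' @param tMap optional 3D array of t values used to record each cluster's
#'   peak.
#' @param formingThreshold recorded in the result for provenance.
#' @return a [ClusterSet-class].
#' @export
connectedComponents <- function(binary, connectivity = 18, tMap = NULL,
                                formingThreshold = NA_real_) {
  arr <- if (is(binary, "MaskVolume")) binary@data else binary
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  lab <- .labelComponents(as.logical(arr), as.integer(d),
                          as.integer(connectivity))
  nLab <- max(lab)
  clusters <- list()
  if (nLab > 0) {
    idxByLab <- split(which(lab > 0), lab[lab > 0])
    clusters <- lapply(idxByLab, function(idx) {
      cl <- list(indices = idx, size = length(idx))
      if (!is.null(tMap)) {
        tv <- tMap[idx]
        pk <- idx[which.max(tv)]
        cl$peakT <- max(tv)
        cl$peakIJK <- as.integer(arrayInd(pk, d))
      }
      cl
    })
    clusters <- clusters[order(vapply(clusters, function(cl) cl$size,
                                      numeric(1)), decreasing = TRUE)]
    names(clusters) <- NULL
  }
  new("ClusterSet", clusters = clusters,
      formingThreshold = as.numeric(formingThreshold),
      connectivity = as.integer(connectivity), dim = as.integer(d))
}

# Max suprathreshold cluster size of one t-vector, for the permutation null.
.maxClusterSize <- function(tvec, thr, maskIdx, dims, connectivity) {
  sel <- is.finite(tvec) & tvec > thr
  if (!any(sel)) return(0)
  arr <- logical(prod(dims))
  arr[maskIdx[sel]] <- TRUE
  lab <- .labelComponents(arr, dims, connectivity)
  if (max(lab) == 0L) return(0)
  max(tabulate(lab[lab > 0L]))
}

#' Cluster-extent inference
#'
#' Thresholds the voxel-wise t-map at an uncorrected forming threshold
#' (Student quantile at `1 - formingP`), extracts connected components,
#' and controls the cluster-level family-wise error by the permutation
#' null of the maximum cluster size at the same forming threshold.
#' Surviving clusters must have size at least `kMin` voxels (the extent
#' report filter; non-strict by default, `kStrict = TRUE` for `> kMin`)
#' AND exceed the `1 - clusterAlpha` quantile of the max-size null.
#'
#' @inheritParams voxelFweThreshold
#' @param formingP uncorrected voxel-level forming p (default 0.001).
#' @param kMin minimum cluster extent in voxels (default 100; 0 disables
#'   the filter).
#' @param kStrict require size strictly greater than `kMin`.
#' @param clusterAlpha cluster-level FWE level (default 0.05).
#' @param connectivity neighbourhood for contiguity (default 18).
#' @return a [ClusterSet-class] of surviving clusters (each with `pFWE`),
#'   carrying the max-size null in `@nullMaxSize`.
#' @export
clusterInference <- function(volumes, design, contrast = "decrease",
                             formingP = 0.001, kMin = 100, kStrict = FALSE,
                             clusterAlpha = 0.05, nPerm = 1000, seed = NULL,
                             connectivity = 18, mask = NULL) {
  stopifnot(formingP > 0, formingP < 1, clusterAlpha > 0, clusterAlpha < 1)
  prep <- .prepareGLM(volumes, design, contrast, mask)
  df <- prep$obs$df
  thrForm <- stats::qt(1 - formingP, df)
  connectivity <- as.integer(connectivity)
  dims <- as.integer(prep$dim)

  pn <- .permNull(prep$Y, prep$X, design@groupCol, prep$cvec, nPerm, seed,
                  exhaustive = FALSE, summarise = function(tvec)
                    .maxClusterSize(tvec, thrForm, prep$maskIdx, dims,
                                    connectivity))
  sizeThr <- stats::quantile(pn$null, 1 - clusterAlpha, type = 1,
                             names = FALSE)

  tMap <- array(NaN, dim = dims)
  tMap[prep$maskIdx] <- prep$obs$t
  supra <- array(FALSE, dim = dims)
  sel <- is.finite(prep$obs$t) & prep$obs$t > thrForm
  supra[prep$maskIdx[sel]] <- TRUE
  cs <- connectedComponents(supra, connectivity, tMap = tMap,
                            formingThreshold = thrForm)

  keep <- vapply(cs@clusters, function(cl) {
    sizeOK <- if (kStrict) cl$size > kMin else cl$size >= kMin
    sizeOK && cl$size > sizeThr
  }, logical(1))
  survivors <- lapply(cs@clusters[keep], function(cl) {
    cl$pFWE <- (1 + sum(pn$null >= cl$size)) / (pn$N + 1)
    cl
  })
  new("ClusterSet", clusters = survivors, formingThreshold = thrForm,
      connectivity = connectivity, dim = dims, nullMaxSize = pn$null)
}

#' Derive a data-driven reference cluster
#'
#' Walks a descending grid of voxel-level FWE levels (lenient to
#' stringent) on the patients-greater-than-controls contrast of
#' global-mean-normalized images. At each level the suprathreshold voxels
#' are decomposed into connected components; the escalation stops at the
#' first level where the largest component contains at least
#' `coherenceFraction` of all suprathreshold voxels (the operational
#' reading of "most of the cluster volume in one region") and has at least
#' `minSize` voxels. The largest component is returned as the reference
#' region, with the full escalation path as provenance.
#'
#' Under a null cohort no level yields a coherent non-empty cluster and an
#' error is raised — the expected behaviour when there is no disease
#' effect to spare a region from.
#'
#' @param volumes CGM-normalized cohort volumes (manifest row order).
#' @inheritParams voxelFweThreshold
#' @param alphas descending FWE levels (default 0.05, 0.01, 1e-3 ... 1e-6).
#' @param coherenceFraction required largest-component fraction (default
#'   0.9).
#' @param minSize minimum component size in voxels (default 50).
#' @param method `"bonferroni"` (default: valid at arbitrarily small
#'   alpha) or `"permutation"` (requires `nPerm >= 1/min(alphas) - 1`).
#' @param connectivity neighbourhood for contiguity (default 18).
#' @return a [ReferenceRegion-class].
#' @export
deriveReferenceCluster <- function(volumes, design,
                                   alphas = c(0.05, 0.01, 1e-3, 1e-4,
                                              1e-5, 1e-6),
                                   coherenceFraction = 0.9, minSize = 50,
                                   method = c("bonferroni", "permutation"),
                                   nPerm = 1000, seed = NULL,
                                   connectivity = 18, mask = NULL) {
  method <- match.arg(method)
  alphas <- sort(alphas, decreasing = TRUE)
  prep <- .prepareGLM(volumes, design, "increase", mask)
  df <- prep$obs$df
  V <- length(prep$maskIdx)
  dims <- as.integer(prep$dim)
  connectivity <- as.integer(connectivity)

  nullMaxT <- NULL
  if (method == "permutation") {
    if (floor(min(alphas) * (nPerm + 1)) < 1)
      stop("nPerm = ", nPerm, " cannot resolve voxel-FWE alpha = ",
           min(alphas), "; increase nPerm or use method = 'bonferroni'")
    nullMaxT <- .permNull(prep$Y, prep$X, design@groupCol, prep$cvec, nPerm,
                          seed, exhaustive = FALSE,
                          summarise = .maxFiniteT)$null
  }

  path <- data.frame(alpha = numeric(0), threshold = numeric(0),
                     nSupra = integer(0), nComponents = integer(0),
                     largestFraction = numeric(0))
  for (alpha in alphas) {
    thr <- if (method == "bonferroni") stats::qt(1 - alpha / V, df)
           else sort(nullMaxT, decreasing = TRUE)[floor(alpha * (nPerm + 1))]
    sel <- is.finite(prep$obs$t) & prep$obs$t > thr
    nSupra <- sum(sel)
    if (nSupra == 0L) {
      path <- rbind(path, data.frame(alpha = alpha, threshold = thr,
                                     nSupra = 0L, nComponents = 0L,
                                     largestFraction = NA_real_))
      next
    }
    supra <- array(FALSE, dim = dims)
    supra[prep$maskIdx[sel]] <- TRUE
    lab <- .labelComponents(supra, dims, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    largest <- max(sizes)
    frac <- largest / nSupra
    path <- rbind(path, data.frame(alpha = alpha, threshold = thr,
                                   nSupra = nSupra,
                                   nComponents = length(sizes),
                                   largestFraction = frac))
    if (frac >= coherenceFraction && largest >= minSize) {
      maskArr <- array(0, dim = dims)
      maskArr[lab == which.max(sizes)] <- 1
      rcMask <- new("MaskVolume", data = maskArr,
                    voxelSize = prep$voxelSize, geometry = NULL)
      return(new("ReferenceRegion", mask = rcMask,
                 provenance = list(alpha = alpha, threshold = thr,
                                   path = path, size = largest,
                                   coherence = frac, method = method,
                                   df = df, connectivity = connectivity)))
    }
  }
  stop("no reference cluster found: no FWE level yielded a coherent ",
       "non-empty cluster (expected under a null cohort)")
}
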