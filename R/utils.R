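# Internal numerics shared across modules.

# 1D Gaussian kernel, sd in voxels, truncated at 4 SD and renormalized.
.gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(4 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Band matrix applying the kernel along one axis with zero padding.
.convMatrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    keep <- j >= 1L & j <= n
    K[cbind(i[keep], j[keep])] <- kernel[off + r + 1L]
  }
  K
}

# Separable 3D Gaussian convolution (zero-padded).
.smooth3dRaw <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (ax in 1:3) {
    k <- .gaussKernel1d(sigmaVox[ax])
    if (length(k) == 1L) next
    K <- .convMatrix(d[ax], k)
    perm <- c(ax, setdiff(1:3, ax))
    m <- K %*% matrix(aperm(arr, perm), nrow = d[ax])
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

#' Gaussian smoothing of a brain volume
#'
#' Separable Gaussian smoothing with the kernel truncated at 4 standard
#' deviations. Smoothing is mask-normalized: values are convolved together
#' with the support mask and their ratio taken, so means inside the mask are
#' not dragged towards zero at mask edges. Voxels outside the support
#' (non-finite in the input, or outside `mask`) stay `NaN`.
#'
#' @param img a [BrainVolume-class].
#' @param fwhm full width at half maximum of the kernel, mm (scalar or
#'   length 3).
#' @param mask optional [MaskVolume-class] support; defaults to the finite
#'   voxels of `img`.
#' @return a [BrainVolume-class] on the same grid.
#' @export
gaussianSmooth <- function(img, fwhm, mask = NULL) {
  stopifnot(is(img, "BrainVolume"))
  fwhm <- rep_len(fwhm, 3L)
  sigmaVox <- fwhm / (2 * sqrt(2 * log(2))) / img@voxelSize
  arr <- img@data
  supp <- if (is.null(mask)) is.finite(arr) else {
    assertSameGrid(img, mask)
    mask@data > 0 & is.finite(arr)
  }
  vals <- ifelse(supp, arr, 0)
  num <- .smooth3dRaw(vals, sigmaVox)
  den <- .smooth3dRaw(supp + 0, sigmaVox)
  out <- array(NaN, dim = dim(arr))
  out[supp] <- num[supp] / den[supp]
  new("BrainVolume", data = out, voxelSize = img@voxelSize,
      geometry = img@geometry)
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint ones. Used to score recovered regions against ground truth.
#'
#' @param a,b [MaskVolume-class] objects (or plain 0/1 arrays) on the same
#'   grid.
#' @return numeric in \[0, 1\] (`NaN` if both masks are empty).
#' @export
diceCoefficient <- function(a, b) {
  av <- if (is(a, "MaskVolume")) a@data else a
  bv <- if (is(b, "MaskVolume")) b@data else b
  stopifnot(identical(dim(av), dim(bv)))
  2 * sum(av * bv) / (sum(av) + sum(bv))
}

# Deterministic per-stage seed derivation, kept inside 32-bit range.
.deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 10007) %% 2147483647)
}

# Stack a list of volumes into a subjects x voxels matrix over mask indices.
.stackVolumes <- function(volumes, maskIdx) {
  n <- length(volumes)
  Y <- matrix(0, nrow = n, ncol = length(maskIdx))
  for (i in seq_len(n)) Y[i, ] <- volumes[[i]]@data[maskIdx]
  Y
}

# Indices finite in all subjects (and inside an optional user mask).
.commonFiniteIdx <- function(volumes, mask = NULL) {
  ok <- is.finite(volumes[[1]]@data)
  for (v in volumes[-1]) ok <- ok & is.finite(v@data)
  if (!is.null(mask)) ok <- ok & mask@data > 0
  which(ok)
}

.asVolumeList <- function(volumes) {
  if (is(volumes, "BrainVolume")) return(list(volumes))
  stopifnot(is.list(volumes), length(volumes) >= 1L,
            all(vapply(volumes, is, logical(1), "BrainVolume")))
  for (v in volumes[-1]) assertSameGrid(volumes[[1]], v)
  volumes
}
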