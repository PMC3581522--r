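# Shared fixtures: tiny volumes and noise-free phantom settings.

mkVol <- function(arr, voxelSize = c(2, 2, 2)) {
  new("BrainVolume", data = arr, voxelSize = voxelSize, geometry = NULL)
}

mkMask <- function(arr, voxelSize = c(2, 2, 2)) {
  new("MaskVolume", data = arr + 0, voxelSize = voxelSize, geometry = NULL)
}

constVol <- function(value, dims = c(4, 4, 4)) {
  mkVol(array(value, dim = dims))
}

# Phantom parameters with every stochastic component switched off, so the
# generative rule is a deterministic closed form.
noiselessParams <- function(factor = 0.8, shape = c(24, 24, 24), ...) {
  phantomParams(shape = shape, hypometabolismFactor = factor,
                subjectScaleSd = 0, severitySd = 0, biolSd = 0,
                noiseSd = 0, ...)
}

# 6-connectivity erosion, repeated `k` times (independent of the package's
# own component code).
erodeMask <- function(mask, k = 1) {
  arr <- mask@data > 0
  d <- dim(arr)
  for (i in seq_len(k)) {
    out <- arr
    sh <- function(a, ax, off) {
      idx <- rep(list(quote(expr = )), 3)
      src <- seq_len(d[ax]) - off
      src[src < 1 | src > d[ax]] <- NA
      padded <- array(FALSE, dim = d)
      ok <- !is.na(src)
      idxTo <- idxFrom <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idxTo[[ax]] <- which(ok); idxFrom[[ax]] <- src[ok]
      padded[idxTo[[1]], idxTo[[2]], idxTo[[3]]] <-
        a[idxFrom[[1]], idxFrom[[2]], idxFrom[[3]]]
      padded
    }
    for (ax in 1:3) for (off in c(-1, 1)) out <- out & sh(arr, ax, off)
    arr <- out
  }
  mkMask(arr + 0, mask@voxelSize)
}

# Manifest for n1 controls + n2 patients with varying covariates.
mkManifest <- function(n1, n2, sex = NULL) {
  n <- n1 + n2
  if (is.null(sex)) sex <- rep(c(0, 1), length.out = n)
  data.frame(id = sprintf("s%02d", seq_len(n)),
             group = rep(c("control", "patient"), c(n1, n2)),
             age = seq(55, 75, length.out = n), sex = sex,
             path = NA_character_, stringsAsFactors = FALSE)
}

# Wrap scalar per-subject values as single-voxel volumes for fitGLM.
scalarVolumes <- function(values) {
  lapply(values, function(v) mkVol(array(v, dim = c(1, 1, 1))))
}
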