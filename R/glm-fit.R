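#' Build the group-comparison design matrix
#'
#' Columns: intercept, group indicator (patient = 1), mean-centered age,
#' sex — age and sex as nuisance covariates. A covariate column that is
#' constant across subjects (e.g. a single-sex cohort) is dropped with a
#' warning and recorded in the design's provenance.
#'
#' @param manifest cohort manifest data.frame (see [readManifest()]).
#' @param covariates nuisance covariates to include (subset of
#'   `c("age", "sex")`).
#' @return a [GroupDesign-class].
#' @export
buildDesign <- function(manifest, covariates = c("age", "sex")) {
  .validateManifest(manifest)
  group <- as.integer(manifest$group == "patient")
  X <- cbind(intercept = 1, group = group)
  dropped <- character(0)
  if ("age" %in% covariates) {
    age <- manifest$age - mean(manifest$age)
    if (stats::var(age) > 0) X <- cbind(X, age = age)
    else dropped <- c(dropped, "age")
  }
  if ("sex" %in% covariates) {
    if (stats::var(manifest$sex) > 0) X <- cbind(X, sex = manifest$sex)
    else dropped <- c(dropped, "sex")
  }
  if (length(dropped))
    warning("dropping constant covariate column(s): ",
            paste(dropped, collapse = ", "))
  rownames(X) <- manifest$id
  new("GroupDesign", X = X, groupCol = 2L, group = group, dropped = dropped)
}

#' Contrast vector for a design
#'
#' `"decrease"` tests patients < controls (-1 on the group column),
#' `"increase"` patients > controls (+1). Both are one-sided.
#'
#' @param design a [GroupDesign-class].
#' @param direction `"decrease"`, `"increase"`, or a numeric contrast of
#'   length `ncol(design@X)` returned unchanged.
#' @return numeric contrast vector.
#' @export
contrastVector <- function(design, direction = c("decrease", "increase")) {
  if (is.numeric(direction)) {
    stopifnot(length(direction) == ncol(design@X))
    return(direction)
  }
  direction <- match.arg(direction)
  cvec <- numeric(ncol(design@X))
  cvec[design@groupCol] <- if (direction == "decrease") -1 else 1
  cvec
}

# Core OLS t-statistics for all voxels at once.
# Y: subjects x voxels; X: design; cvec: contrast. Zero-residual-variance
# voxels get +/-Inf sentinels (0 when the numerator is also 0).
.glmCore <- function(Y, X, cvec) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  rss <- colSums((Y - X %*% B)^2)
  df <- n - p
  sigma2 <- rss / df
  num <- drop(cvec %*% B)
  cScale <- drop(cvec %*% XtXinv %*% cvec)
  scale2 <- colMeans(Y^2)
  zv <- sigma2 <= 1e-16 * pmax(scale2, .Machine$double.xmin)
  tval <- num / sqrt(sigma2 * cScale)
  tval[zv] <- sign(num[zv]) * Inf
  tval[zv & num == 0] <- 0
  list(t = tval, beta = B, sigma2 = sigma2, df = df, zeroVar = zv)
}

#' Voxel-wise general linear model
#'
#' Fits `y = X beta + e` by ordinary least squares independently at every
#' voxel of the analysis mask (voxels finite in all subjects, optionally
#' intersected with a user mask) and forms the t-statistic
#' `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` with
#' `df = n - rank(X)`. Voxels with zero residual variance get `+/-Inf`
#' sentinels and are flagged.
#'
#' @param volumes list of grid-compatible [BrainVolume-class] /
#'   [NormalizedVolume-class], in manifest row order.
#' @param design a [GroupDesign-class] with `nrow(X) == length(volumes)`.
#' @param contrast `"decrease"`, `"increase"`, or a numeric contrast.
#' @param mask optional [MaskVolume-class] restricting the analysis.
#' @return a [TStatResult-class].
#' @export
fitGLM <- function(volumes, design, contrast = "decrease", mask = NULL) {
  volumes <- .asVolumeList(volumes)
  stopifnot(is(design, "GroupDesign"))
  if (length(volumes) != nrow(design@X))
    stop("number of volumes (", length(volumes),
         ") does not match design rows (", nrow(design@X), ")")
  cvec <- contrastVector(design, contrast)
  maskIdx <- .commonFiniteIdx(volumes, mask)
  if (length(maskIdx) == 0L) stop("analysis mask is empty")
  Y <- .stackVolumes(volumes, maskIdx)
  fit <- .glmCore(Y, design@X, cvec)
  d <- dim(volumes[[1]]@data)
  tMap <- array(NaN, dim = d)
  tMap[maskIdx] <- fit$t
  am <- array(0, dim = d); am[maskIdx] <- 1
  new("TStatResult", tMap = tMap, df = fit$df, beta = fit$beta,
      sigma2 = fit$sigma2, maskIdx = maskIdx,
      analysisMask = new("MaskVolume", data = am,
                         voxelSize = volumes[[1]]@voxelSize, geometry = NULL),
      contrast = cvec, zeroVar = fit$zeroVar)
}
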