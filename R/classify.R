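#' Extract per-subject mean uptake from a pattern mask
#'
#' One scalar feature per subject: the mean normalized uptake inside the
#' hypometabolic-pattern mask. This is the single independent variable of
#' the downstream logistic classifier.
#'
#' @param volumes list of [NormalizedVolume-class] / [BrainVolume-class]
#'   in manifest row order.
#' @param pattern non-empty [MaskVolume-class].
#' @param manifest cohort manifest data.frame.
#' @return data.frame with columns `id`, `group`, `feature`.
#' @export
extractPatternMeans <- function(volumes, pattern, manifest) {
  volumes <- .asVolumeList(volumes)
  .validateManifest(manifest)
  stopifnot(is(pattern, "MaskVolume"))
  if (sum(pattern@data) < 1) stop("pattern mask is empty")
  if (length(volumes) != nrow(manifest))
    stop("number of volumes does not match manifest rows")
  feats <- vapply(volumes, roiMean, numeric(1), mask = pattern)
  data.frame(id = manifest$id, group = manifest$group, feature = feats,
             stringsAsFactors = FALSE)
}

#' Voxel-wise intersection of pattern masks
#'
#' The overlap of hypometabolic patterns detected under several
#' normalization schemes — the conservative common pattern.
#'
#' @param patterns list of >= 2 grid-compatible [MaskVolume-class].
#' @return a [MaskVolume-class]; error if the intersection is empty.
#' @export
patternOverlap <- function(patterns) {
  stopifnot(is.list(patterns), length(patterns) >= 2L,
            all(vapply(patterns, is, logical(1), "MaskVolume")))
  for (p in patterns[-1]) assertSameGrid(patterns[[1]], p)
  acc <- patterns[[1]]@data
  for (p in patterns[-1]) acc <- acc * p@data
  if (sum(acc) < 1)
    stop("patterns have empty intersection: no common pattern")
  new("MaskVolume", data = acc, voxelSize = patterns[[1]]@voxelSize,
      geometry = patterns[[1]]@geometry)
}

#' Single-feature logistic regression
#'
#' Maximum-likelihood logistic fit of class on one scalar feature by
#' iteratively reweighted least squares, with a tiny ridge (1e-8) on the
#' slope so the fit converges under perfect separation without materially
#' moving the decision boundary at feature scales near 1.
#'
#' @param features numeric feature per subject.
#' @param labels 0/1 class labels (1 = patient); both classes must be
#'   present.
#' @param ridge ridge penalty on the slope.
#' @param maxIter,tol IRLS iteration controls.
#' @return list with `intercept`, `slope`, and `predict(x)` returning 0/1
#'   classes at the probability-0.5 threshold.
#' @export
fitLogistic <- function(features, labels, ridge = 1e-8, maxIter = 100,
                        tol = 1e-10) {
  stopifnot(length(features) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes")
  X <- cbind(1, features)
  beta <- c(stats::qlogis(mean(labels) * 0.98 + 0.01), 0)
  pen <- diag(c(0, ridge))
  for (iter in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (labels - p) / w
    XtW <- t(X * w)
    betaNew <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  beta <- drop(beta)
  list(intercept = beta[1], slope = beta[2],
       predict = function(x) as.integer(beta[1] + beta[2] * x > 0))
}

#' Repeated split-half cross-validated classification
#'
#' Each repetition randomly splits every class into halves (stratified;
#' with odd class sizes the extra subject goes to training), fits the
#' logistic model on the training half and scores the held-out half:
#' accuracy = correct/total, sensitivity = correct patients / patients,
#' specificity = correct controls / controls. Reproducible for a fixed
#' seed.
#'
#' @param features numeric feature per subject.
#' @param labels 0/1 labels (1 = patient) or `"control"`/`"patient"`.
#' @param nRep repetitions (default 5000).
#' @param seed RNG seed.
#' @param scheme name stored in the result.
#' @return an [AccuracyDistribution-class].
#' @export
splitHalfCV <- function(features, labels, nRep = 5000, seed = 1,
                        scheme = "feature") {
  if (is.character(labels)) labels <- as.integer(labels == "patient")
  stopifnot(length(features) == length(labels), all(labels %in% c(0, 1)))
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  if (length(idx1) < 2 || length(idx0) < 2)
    stop("need at least 2 subjects per class")
  nTest1 <- floor(length(idx1) / 2)
  nTest0 <- floor(length(idx0) / 2)
  set.seed(seed)
  acc <- sens <- spec <- numeric(nRep)
  for (r in seq_len(nRep)) {
    test1 <- sample(idx1, nTest1)
    test0 <- sample(idx0, nTest0)
    train <- setdiff(seq_along(labels), c(test1, test0))
    fit <- fitLogistic(features[train], labels[train])
    sens[r] <- mean(fit$predict(features[test1]) == 1)
    spec[r] <- mean(fit$predict(features[test0]) == 0)
    acc[r] <- (sens[r] * nTest1 + spec[r] * nTest0) / (nTest1 + nTest0)
  }
  new("AccuracyDistribution", accuracy = acc, sensitivity = sens,
      specificity = spec, nRep = as.integer(nRep), seed = as.integer(seed),
      scheme = scheme)
}

# Two-sample t-test p-value that tolerates degenerate (constant) arrays.
.safeTTestP <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Compare accuracy distributions between normalization schemes
#'
#' Pairwise two-sample t-tests on the per-repetition accuracy arrays with
#' Bonferroni correction over the number of pairs, plus a within-scheme
#' comparison of sensitivity versus specificity (Bonferroni over schemes).
#' Note: treating resampled accuracies as independent samples is
#' anticonservative; it is implemented as the field's customary
#' comparison and flagged as such here.
#'
#' @param dists named list of >= 2 [AccuracyDistribution-class] with equal
#'   `nRep`.
#' @param alpha significance level before correction (default 0.05).
#' @return list with `pairwise` (data.frame: schemes, mean difference, p,
#'   Bonferroni-corrected p, significant), `sensVsSpec` (per scheme), and
#'   `alpha`.
#' @export
compareDistributions <- function(dists, alpha = 0.05) {
  stopifnot(is.list(dists), length(dists) >= 2L,
            all(vapply(dists, is, logical(1), "AccuracyDistribution")))
  nreps <- vapply(dists, function(d) d@nRep, integer(1))
  if (length(unique(nreps)) != 1L)
    stop("all distributions must have the same nRep")
  nm <- names(dists)
  if (is.null(nm)) nm <- vapply(dists, function(d) d@scheme, character(1))
  pairs <- utils::combn(length(dists), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- dists[[i1]]@accuracy; b <- dists[[i2]]@accuracy
    p <- .safeTTestP(a, b)
    data.frame(scheme1 = nm[i1], scheme2 = nm[i2],
               meanDiff = mean(a) - mean(b), p = p,
               pBonferroni = min(1, p * m), stringsAsFactors = FALSE)
  }))
  pw$significant <- pw$pBonferroni < alpha
  ss <- do.call(rbind, lapply(seq_along(dists), function(i) {
    se <- dists[[i]]@sensitivity; sp <- dists[[i]]@specificity
    p <- .safeTTestP(se, sp)
    data.frame(scheme = nm[i], meanSens = mean(se), meanSpec = mean(sp),
               p = p, pBonferroni = min(1, p * length(dists)),
               stringsAsFactors = FALSE)
  }))
  ss$significant <- ss$pBonferroni < alpha
  list(pairwise = pw, sensVsSpec = ss, alpha = alpha,
       note = "independent-sample t-tests on resampled accuracies are anticonservative")
}
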