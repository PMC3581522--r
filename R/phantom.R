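#' Phantom generator parameters
#'
#' Settings of the synthetic smoothed-PET cohort generator. The phantom
#' emulates spatially normalized, Gaussian-smoothed FDG-PET volumes of a
#' patients-vs-controls study: a geometric brain parcellation with
#' cortex-like baseline uptake per parcel, a multiplicative regional
#' deficit in patients, a per-subject multiplicative global scale (the
#' nuisance that intensity normalization exists to remove), per-subject
#' biological fluctuation of parcel uptake, additive scanner noise, and a
#' single effective Gaussian smoothing kernel applied after noise.
#'
#' Patients' deficit in parcel p is `1 - s_i * w_p * (1 - factor)`, where
#' `factor` is `hypometabolismFactor`, `w_p` the parcel severity weight
#' (1 for affected parcels, 0 for the preserved parcel, intermediate
#' elsewhere — widespread mild hypometabolism with a spared
#' cerebellum-analog), and `s_i` a per-patient lognormal severity. With
#' `severitySd = 0`, `parcelSd = 0` the rule reduces to a fixed
#' multiplicative deficit in the affected parcels only.
#'
#' @param shape grid dimensions (default 32^3).
#' @param voxelSize voxel edge length, mm (default 2).
#' @param baseline named baseline uptake per parcel, arbitrary units.
#' @param hypometabolismFactor multiplicative uptake retained in affected
#'   parcels of patients (default 0.85; 1 = null phantom).
#' @param affected,preserved parcel names with full deficit / none.
#' @param severityWeights named per-parcel deficit weights in \[0, 1\].
#' @param subjectScaleSd sdlog of the per-subject global scale
#'   (lognormal, default 0.1).
#' @param severitySd sdlog of the per-patient severity multiplier
#'   (default 0.2; 0 = identical deficit in all patients).
#' @param biolSd sdlog amplitude of the per-subject smooth multiplicative
#'   biological-variability field (default 0.02; 0 = none). This is the
#'   between-subject regional variability that limits discrimination.
#' @param biolWeights named per-parcel multiplier of `biolSd`; defaults
#'   damp the field in the cerebellum-analog and vermis (0.3), encoding
#'   the across-subject stability of cerebellar uptake that makes it a
#'   usable reference region.
#' @param biolFwhm correlation length (FWHM, mm) of the biological field
#'   (default 20).
#' @param noiseSd additive Gaussian noise sd before smoothing (default 8).
#' @param smoothingFwhm Gaussian kernel FWHM, mm (default 12).
#' @return a [PhantomParams-class].
#' @seealso [centerPreset()], [makeParcellation()], [simulateCohort()]
#' @export
phantomParams <- function(shape = c(32L, 32L, 32L), voxelSize = 2,
                          baseline = c(frontal = 55, anterior_temporal = 52,
                                       sensorimotor = 56, occipital = 54,
                                       cerebellum = 48, vermis = 46,
                                       other = 50),
                          hypometabolismFactor = 0.85,
                          affected = c("frontal", "anterior_temporal"),
                          preserved = "cerebellum",
                          severityWeights = c(frontal = 1,
                                              anterior_temporal = 1,
                                              sensorimotor = 0.6,
                                              occipital = 0.6,
                                              cerebellum = 0, vermis = 0.05,
                                              other = 0.6),
                          subjectScaleSd = 0.1, severitySd = 0.2,
                          biolSd = 0.02,
                          biolWeights = c(frontal = 0.8,
                                          anterior_temporal = 0.8,
                                          sensorimotor = 1.2,
                                          occipital = 1.2,
                                          cerebellum = 0.3, vermis = 0.3,
                                          other = 2),
                          biolFwhm = 20, noiseSd = 8,
                          smoothingFwhm = 12) {
  new("PhantomParams", shape = as.integer(rep_len(shape, 3L)),
      voxelSize = rep_len(as.numeric(voxelSize), 3L),
      baseline = baseline, hypometabolismFactor = hypometabolismFactor,
      affected = affected, preserved = preserved,
      severityWeights = severityWeights[names(baseline)],
      subjectScaleSd = subjectScaleSd, severitySd = severitySd,
      biolSd = biolSd, biolWeights = biolWeights[names(baseline)],
      biolFwhm = biolFwhm, noiseSd = noiseSd,
      smoothingFwhm = smoothingFwhm)
}

#' Two-center phantom presets
#'
#' Presets emulating cross-center acquisition differences (noise level,
#' global-scale variability, baseline uptake vector) without modelling
#' scanner physics. `"center1"` is the default parameter set; `"center2"`
#' is noisier with a rescaled baseline, emulating a different acquisition
#' protocol.
#'
#' @param name `"center1"` or `"center2"`.
#' @param ... overrides passed to [phantomParams()].
#' @return a [PhantomParams-class].
#' @export
centerPreset <- function(name = c("center1", "center2"), ...) {
  name <- match.arg(name)
  if (name == "center1") return(phantomParams(...))
  phantomParams(baseline = 0.9 * c(frontal = 55, anterior_temporal = 52,
                                   sensorimotor = 57, occipital = 53,
                                   cerebellum = 47, vermis = 45, other = 50),
                noiseSd = 12, subjectScaleSd = 0.13, biolSd = 0.09, ...)
}

#' Build the phantom parcellation and ground-truth masks
#'
#' Deterministic geometric parcellation of an ellipsoidal brain: a
#' cerebellum-analog cap (with a small medial vermis) placed inferiorly, an
#' anterior frontal block, inferior-anterior temporal parcels, a superior
#' sensorimotor slab, a posterior occipital block, and remaining tissue.
#' Every brain voxel gets exactly one nonzero label.
#'
#' @param params a [PhantomParams-class].
#' @return a [PhantomTruth-class] with parcellation and affected /
#'   preserved / brain masks.
#' @export
makeParcellation <- function(params) {
  stopifnot(is(params, "PhantomParams"))
  d <- params@shape
  cu <- function(n) ((seq_len(n) - (n + 1) / 2) / (0.46 * n))
  ux <- array(rep(cu(d[1]), times = d[2] * d[3]), dim = d)
  uy <- array(rep(rep(cu(d[2]), each = d[1]), times = d[3]), dim = d)
  uz <- array(rep(cu(d[3]), each = d[1] * d[2]), dim = d)
  ellipsoid <- ux^2 + uy^2 + uz^2 <= 1
  # Tentorium-like non-brain gap separating the cerebellar cap from the
  # cerebrum, as in a real brain mask.
  gap <- uz >= -0.54 & uz < -0.42 & uy < 0.10
  brain <- ellipsoid & !gap

  lab <- array(0L, dim = d)
  parcels <- names(params@baseline)
  idOf <- stats::setNames(seq_along(parcels), parcels)

  cereZone <- brain & uz < -0.54 & uy < 0.1
  lab[cereZone & abs(ux) < 0.15] <- idOf[["vermis"]]
  lab[cereZone & abs(ux) >= 0.15] <- idOf[["cerebellum"]]
  rest <- brain & lab == 0L
  lab[rest & uy > 0.35] <- idOf[["frontal"]]
  rest <- brain & lab == 0L
  lab[rest & uy > 0.05 & uz < 0] <- idOf[["anterior_temporal"]]
  rest <- brain & lab == 0L
  lab[rest & uz > 0.5] <- idOf[["sensorimotor"]]
  rest <- brain & lab == 0L
  lab[rest & uy < -0.45] <- idOf[["occipital"]]
  lab[brain & lab == 0L] <- idOf[["other"]]

  if (any(!seq_along(parcels) %in% lab))
    stop("parcels cannot fit the grid: ",
         paste(parcels[!seq_along(parcels) %in% lab], collapse = ", "))

  vx <- params@voxelSize
  mk <- function(arr) new("MaskVolume", data = arr + 0, voxelSize = vx,
                          geometry = NULL)
  parc <- new("LabelVolume", data = lab, voxelSize = vx, geometry = NULL,
              labelTable = idOf)
  new("PhantomTruth", parcellation = parc,
      affectedMask = mk(array(lab %in% idOf[params@affected], d)),
      preservedMask = mk(array(lab %in% idOf[params@preserved], d)),
      brainMask = mk(array(brain, d)))
}

# Unit-variance smooth Gaussian field (zero-padded; slight variance loss
# at the grid edge is acceptable for a within-brain field).
.smoothField <- function(dims, sigmaVox) {
  z <- array(stats::rnorm(prod(dims)), dim = dims)
  if (all(sigmaVox <= 0)) return(z)
  zs <- .smooth3dRaw(z, sigmaVox)
  sdFactor <- sqrt(prod(vapply(sigmaVox, function(s)
    sum(.gaussKernel1d(s)^2), numeric(1))))
  zs / sdFactor
}

# One subject draw; returns the volume plus the latent global scale.
.simulateSubject <- function(truth, params, group, smooth = TRUE) {
  lab <- truth@parcellation@data
  brain <- truth@brainMask@data > 0

  sScale <- stats::rlnorm(1, 0, params@subjectScaleSd)
  severity <- if (group == "patient") {
    if (params@severitySd > 0) stats::rlnorm(1, 0, params@severitySd) else 1
  } else 0

  deficit <- pmax(1 - severity * params@severityWeights *
                    (1 - params@hypometabolismFactor), 0.05)
  perParcel <- sScale * params@baseline * deficit

  vals <- array(0, dim = dim(lab))
  vals[brain] <- perParcel[lab[brain]]
  if (params@biolSd > 0) {
    sigmaVox <- params@biolFwhm / (2 * sqrt(2 * log(2))) / params@voxelSize
    field <- .smoothField(dim(lab), sigmaVox)
    amp <- params@biolSd * params@biolWeights[lab[brain]]
    vals[brain] <- vals[brain] * exp(amp * field[brain] - amp^2 / 2)
  }
  if (params@noiseSd > 0)
    vals[brain] <- vals[brain] + stats::rnorm(sum(brain), 0, params@noiseSd)

  img <- new("BrainVolume", data = ifelse(brain, vals, NaN),
             voxelSize = params@voxelSize, geometry = NULL)
  if (smooth) img <- gaussianSmooth(img, params@smoothingFwhm,
                                    mask = truth@brainMask)
  list(volume = img, scale = sScale)
}

#' Simulate one phantom subject
#'
#' Draws a single smoothed PET-like volume for a control or patient from
#' the generative rule documented in [phantomParams()]. Uses the current
#' RNG state unless `seed` is given.
#'
#' @param truth a [PhantomTruth-class] from [makeParcellation()].
#' @param params the matching [PhantomParams-class].
#' @param group `"control"` or `"patient"`.
#' @param seed optional integer seed for this draw.
#' @param smooth apply the Gaussian kernel (default `TRUE`); `FALSE`
#'   returns the unsmoothed intermediate.
#' @return a [BrainVolume-class] (`NaN` outside the brain mask).
#' @export
simulateSubject <- function(truth, params, group = c("control", "patient"),
                            seed = NULL, smooth = TRUE) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  .simulateSubject(truth, params, group, smooth = smooth)$volume
}

#' Simulate a two-group phantom cohort
#'
#' Generates `nControls + nPatients` volumes plus a cohort manifest with
#' ages drawn Normal(62, 9) years clipped to \[40, 90\] and sex
#' Bernoulli(0.5). Fully reproducible for a fixed seed. Patients' realized
#' brain-wide mean uptake is stochastically lower than controls' whenever
#' `hypometabolismFactor < 1`.
#'
#' @param params a [PhantomParams-class].
#' @param nControls,nPatients group sizes (each >= 2).
#' @param seed integer RNG seed (required for reproducibility).
#' @return list with `volumes` (controls first, then patients), `manifest`
#'   (data.frame `id,group,age,sex,path`) and `truth` (a
#'   [PhantomTruth-class] whose `subjectScales` holds the latent
#'   per-subject global scales).
#' @export
simulateCohort <- function(params, nControls, nPatients, seed) {
  stopifnot(is(params, "PhantomParams"))
  if (nControls < 2 || nPatients < 2)
    stop("need at least 2 subjects per group")
  set.seed(seed)
  truth <- makeParcellation(params)
  n <- nControls + nPatients
  groups <- rep(c("control", "patient"), c(nControls, nPatients))
  age <- pmin(pmax(stats::rnorm(n, 62, 9), 40), 90)
  sex <- stats::rbinom(n, 1, 0.5)
  volumes <- vector("list", n)
  scales <- numeric(n)
  for (i in seq_len(n)) {
    s <- .simulateSubject(truth, params, groups[i])
    volumes[[i]] <- s$volume
    scales[i] <- s$scale
  }
  ids <- sprintf("%s%03d", ifelse(groups == "control", "ctrl", "pat"),
                 c(seq_len(nControls), seq_len(nPatients)))
  manifest <- data.frame(id = ids, group = groups, age = age, sex = sex,
                         path = NA_character_, stringsAsFactors = FALSE)
  truth@subjectScales <- scales
  list(volumes = volumes, manifest = manifest, truth = truth)
}
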