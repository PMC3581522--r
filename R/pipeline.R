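#' Study configuration
#'
#' Assembles the configuration of a full two-cohort study run. Cohorts are
#' either simulated (give `preset`, `nControls`, `nPatients` and optional
#' [phantomParams()] overrides in `params`) or ingested (give `manifest`,
#' a CSV path whose `path` column points at NIfTI volumes, plus `cblMask`
#' / `smcMask` / optional `brainMask` NIfTI paths at the top level).
#'
#' Every stochastic stage gets a named seed derived deterministically from
#' the global `seed`, so a fixed configuration is bitwise-reproducible.
#'
#' @param seed global integer seed.
#' @param outDir output directory (created if missing).
#' @param cohortA,cohortB cohort specifications (lists as above).
#' @param glm list of inference parameters: `formingP`, `kMin`,
#'   `clusterAlpha`, `nPerm`, `alphas`, `rcMethod`, `coherenceFraction`,
#'   `minSize`, `connectivity`.
#' @param cv list of cross-validation parameters: `nRep`.
#' @param evalPattern `"cbl"` (default: each cohort's pattern detected
#'   under cerebellar normalization, the field's reference standard) or
#'   `"overlap"` (the all-scheme overlap pattern of cohort A, applied to
#'   both cohorts).
#' @param target reference target value for normalization.
#' @param cblMask,smcMask,brainMask NIfTI mask paths (ingest mode only).
#' @param persistVolumes also write every normalized volume to disk
#'   (default `FALSE`; masks, patterns, tables and the report are always
#'   persisted).
#' @return a config list for [runStudy()].
#' @export
studyConfig <- function(seed = 1, outDir = tempfile("refclust_study_"),
                        cohortA = list(preset = "center1", nControls = 20,
                                       nPatients = 20),
                        cohortB = list(preset = "center2", nControls = 13,
                                       nPatients = 11),
                        glm = list(), cv = list(), target = 1.0,
                        evalPattern = c("cbl", "overlap"),
                        cblMask = NULL, smcMask = NULL, brainMask = NULL,
                        persistVolumes = FALSE) {
  glmDefaults <- list(formingP = 0.001, kMin = 100, clusterAlpha = 0.05,
                      nPerm = 500, alphas = c(0.05, 0.01, 1e-3, 1e-4, 1e-5,
                                              1e-6),
                      rcMethod = "bonferroni", coherenceFraction = 0.9,
                      minSize = 50, connectivity = 18)
  cvDefaults <- list(nRep = 1000)
  list(seed = as.integer(seed), outDir = outDir,
       cohortA = cohortA, cohortB = cohortB,
       glm = utils::modifyList(glmDefaults, glm),
       cv = utils::modifyList(cvDefaults, cv), target = target,
       evalPattern = match.arg(evalPattern),
       cblMask = cblMask, smcMask = smcMask, brainMask = brainMask,
       persistVolumes = persistVolumes)
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with the fields of [studyConfig()].
#' @return a config list.
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(studyConfig, y)
}

# Load or simulate one cohort; returns volumes, manifest, and the CBL/SMC/
# brain masks the schemes need.
.loadCohort <- function(spec, config, seed) {
  if (!is.null(spec$preset)) {
    params <- do.call(centerPreset,
                      c(list(name = spec$preset), spec$params))
    sim <- simulateCohort(params, spec$nControls, spec$nPatients, seed)
    list(volumes = sim$volumes, manifest = sim$manifest, truth = sim$truth,
         cbl = maskFromLabels(sim$truth@parcellation, "cerebellum"),
         smc = maskFromLabels(sim$truth@parcellation, "sensorimotor"),
         brain = sim$truth@brainMask)
  } else if (!is.null(spec$manifest)) {
    manifest <- readManifest(spec$manifest)
    volumes <- lapply(manifest$path, readVolume)
    if (is.null(config$cblMask) || is.null(config$smcMask))
      stop("ingest mode requires cblMask and smcMask paths in the config")
    asMask <- function(p) {
      v <- readVolume(p)
      new("MaskVolume", data = (v@data > 0) + 0, voxelSize = v@voxelSize,
          geometry = v@geometry)
    }
    list(volumes = volumes, manifest = manifest, truth = NULL,
         cbl = asMask(config$cblMask), smc = asMask(config$smcMask),
         brain = if (is.null(config$brainMask)) NULL
                 else asMask(config$brainMask))
  } else stop("cohort spec needs either 'preset' or 'manifest'")
}

.distSummary <- function(d) {
  list(scheme = d@scheme, nRep = d@nRep,
       accuracy = mean(d@accuracy), accuracySd = stats::sd(d@accuracy),
       sensitivity = mean(d@sensitivity),
       sensitivitySd = stats::sd(d@sensitivity),
       specificity = mean(d@specificity),
       specificitySd = stats::sd(d@specificity))
}

#' Run the full reference-cluster study
#'
#' Orchestrates the complete design on two cohorts: (1) normalize cohort A
#' to the global mean and derive the reference cluster from the
#' patients-greater-than-controls contrast; (2) normalize both cohorts
#' under every scheme (CGM, CBL, SMC, RC); (3) run decrease and increase
#' cluster-extent inference per scheme and cohort; (4) define the
#' evaluation patterns (the CBL-scheme decrease pattern of each cohort,
#' plus the all-scheme overlap at cohort A); (5) evaluate patient/control
#' discrimination by repeated split-half cross-validation per scheme; (6)
#' compare the accuracy distributions. The RC derived on cohort A is
#' applied unchanged to cohort B (cross-center design). If RC derivation
#' fails (null data) the study downgrades to a three-scheme comparison
#' with a warning recorded in the report.
#'
#' All stage outputs (masks, tables, JSON report) are written under
#' `config$outDir`; reruns with an identical config produce an identical
#' report.
#'
#' @param config a list from [studyConfig()] / [readStudyConfig()].
#' @return the study report (list, invisibly), also written as
#'   `report.json`.
#' @export
runStudy <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  g <- config$glm
  seed <- config$seed
  log <- list()
  note <- function(stage, ...) {
    message("[refclust] ", stage, ": ", ...)
    log[[length(log) + 1L]] <<- list(stage = stage, detail = paste0(...))
  }

  note("simulate/ingest", "loading cohorts A and B")
  A <- .loadCohort(config$cohortA, config, .deriveSeed(seed, 1L))
  B <- .loadCohort(config$cohortB, config, .deriveSeed(seed, 2L))
  writeManifest(A$manifest, file.path(config$outDir, "manifest_A.csv"))
  writeManifest(B$manifest, file.path(config$outDir, "manifest_B.csv"))
  designA <- buildDesign(A$manifest)
  designB <- buildDesign(B$manifest)

  note("derive-rc", "CGM normalization of cohort A + threshold escalation")
  cgmA <- normalizeCohort(A$volumes, referenceSpec("cgm"),
                          target = config$target)
  rc <- tryCatch(
    deriveReferenceCluster(cgmA, designA, alphas = g$alphas,
                           coherenceFraction = g$coherenceFraction,
                           minSize = g$minSize, method = g$rcMethod,
                           nPerm = g$nPerm, seed = .deriveSeed(seed, 3L),
                           connectivity = g$connectivity, mask = A$brain),
    error = function(e) {
      warning("reference-cluster derivation failed (",
              conditionMessage(e), "); downgrading to three schemes")
      NULL
    })
  rcWarning <- is.null(rc)
  if (!rcWarning)
    exportReferenceCluster(rc, file.path(config$outDir, "rc_mask.nii.gz"))

  schemes <- list(CGM = referenceSpec("cgm"))
  schemesB <- list(CGM = referenceSpec("cgm"))
  schemes$CBL <- referenceSpec("roi", A$cbl, "CBL")
  schemes$SMC <- referenceSpec("roi", A$smc, "SMC")
  schemesB$CBL <- referenceSpec("roi", B$cbl, "CBL")
  schemesB$SMC <- referenceSpec("roi", B$smc, "SMC")
  if (!rcWarning) {
    schemes$RC <- referenceSpec("roi", rc@mask, "RC")
    schemesB$RC <- referenceSpec("roi", rc@mask, "RC")
  }

  note("normalize", "applying ", length(schemes), " schemes to both cohorts")
  normA <- lapply(schemes, function(s)
    normalizeCohort(A$volumes, s, target = config$target))
  normB <- lapply(schemesB, function(s)
    normalizeCohort(B$volumes, s, target = config$target))

  note("detect", "cluster-extent inference per scheme and cohort")
  detection <- list()
  patterns <- list(A = list(), B = list())
  k <- 0L
  for (cohort in c("A", "B")) {
    norms <- if (cohort == "A") normA else normB
    design <- if (cohort == "A") designA else designB
    brain <- if (cohort == "A") A$brain else B$brain
    for (scheme in names(norms)) {
      for (direction in c("decrease", "increase")) {
        k <- k + 1L
        cs <- clusterInference(norms[[scheme]], design, direction,
                               formingP = g$formingP, kMin = g$kMin,
                               clusterAlpha = g$clusterAlpha,
                               nPerm = g$nPerm,
                               seed = .deriveSeed(seed, 100L + k),
                               connectivity = g$connectivity, mask = brain)
        detection[[length(detection) + 1L]] <-
          list(cohort = cohort, scheme = scheme, direction = direction,
               extent = totalExtent(cs), nClusters = nClusters(cs),
               peakT = if (nClusters(cs)) peakT(cs) else NA_real_)
        if (direction == "decrease" && nClusters(cs) > 0) {
          pm <- clusterMask(cs, voxelSize = norms[[scheme]][[1]]@voxelSize)
          patterns[[cohort]][[scheme]] <- pm
          writeVolume(pm, file.path(config$outDir,
                                    sprintf("pattern_%s_%s.nii.gz",
                                            cohort, scheme)))
        }
      }
    }
  }

  overlapA <- if (length(patterns$A) == length(schemes))
    tryCatch(patternOverlap(unname(patterns$A)), error = function(e) NULL)
  else NULL
  if (!is.null(overlapA))
    writeVolume(overlapA, file.path(config$outDir, "overlap_A.nii.gz"))
  if (identical(config$evalPattern, "overlap") && !is.null(overlapA)) {
    note("patterns", "evaluation pattern = all-scheme overlap of cohort A")
    evalPattern <- list(A = overlapA, B = overlapA)
  } else {
    note("patterns", "evaluation pattern = CBL decrease pattern per cohort")
    evalPattern <- list(A = patterns$A[["CBL"]], B = patterns$B[["CBL"]])
  }

  note("evaluate", "split-half cross-validation per scheme")
  classification <- list()
  dists <- list(A = list(), B = list())
  k <- 0L
  for (cohort in c("A", "B")) {
    pat <- evalPattern[[cohort]]
    if (is.null(pat)) {
      warning("no evaluation pattern for cohort ", cohort,
              "; skipping classification")
      next
    }
    norms <- if (cohort == "A") normA else normB
    manifest <- if (cohort == "A") A$manifest else B$manifest
    for (scheme in names(norms)) {
      k <- k + 1L
      ft <- extractPatternMeans(norms[[scheme]], pat, manifest)
      d <- splitHalfCV(ft$feature, ft$group, nRep = config$cv$nRep,
                       seed = .deriveSeed(seed, 200L + k), scheme = scheme)
      dists[[cohort]][[scheme]] <- d
      utils::write.csv(
        data.frame(rep = seq_len(d@nRep), accuracy = d@accuracy,
                   sensitivity = d@sensitivity, specificity = d@specificity),
        file.path(config$outDir, sprintf("cv_%s_%s.csv", cohort, scheme)),
        row.names = FALSE)
      classification[[length(classification) + 1L]] <-
        c(list(cohort = cohort), .distSummary(d))
    }
  }

  note("compare", "pairwise scheme comparisons")
  comparisons <- lapply(dists[vapply(dists, length, integer(1)) >= 2],
                        compareDistributions)

  report <- list(
    package = "refclust",
    seed = seed,
    schemes = names(schemes),
    rc = if (rcWarning) list(found = FALSE, warning = "no reference cluster")
         else list(found = TRUE, size = rc@provenance$size,
                   alpha = rc@provenance$alpha,
                   coherence = rc@provenance$coherence,
                   method = rc@provenance$method,
                   escalation = rc@provenance$path),
    detection = detection,
    classification = classification,
    comparisons = lapply(comparisons, function(cmp)
      list(pairwise = cmp$pairwise, sensVsSpec = cmp$sensVsSpec)),
    files = list(report = "report.json", manifests = c("manifest_A.csv",
                 "manifest_B.csv")),
    log = log)
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  if (isTRUE(config$persistVolumes)) {
    for (cohort in c("A", "B")) {
      norms <- if (cohort == "A") normA else normB
      for (scheme in names(norms))
        for (i in seq_along(norms[[scheme]]))
          writeVolume(norms[[scheme]][[i]],
                      file.path(config$outDir,
                                sprintf("norm_%s_%s_%03d.nii.gz", cohort,
                                        scheme, i)))
    }
  }
  invisible(report)
}

#' Export / reload a reference cluster
#'
#' Writes the binary cluster mask as NIfTI plus a JSON sidecar with the
#' escalation provenance, so other installations can load it and normalize
#' new data to the same region (applied on a mismatched grid it errors via
#' [assertSameGrid()]).
#'
#' @param region a [ReferenceRegion-class].
#' @param path output NIfTI path; the sidecar gets extension `.json`.
#' @return invisibly, `path`.
#' @export
exportReferenceCluster <- function(region, path) {
  stopifnot(is(region, "ReferenceRegion"))
  writeVolume(region@mask, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(alpha = region@provenance$alpha, size = region@provenance$size,
         coherence = region@provenance$coherence,
         method = region@provenance$method,
         escalation = region@provenance$path),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows")
  invisible(path)
}

#' @rdname exportReferenceCluster
#' @param maskPath path of an exported cluster mask.
#' @export
loadReferenceCluster <- function(maskPath) {
  v <- readVolume(maskPath)
  mask <- new("MaskVolume", data = (v@data > 0) + 0,
              voxelSize = v@voxelSize, geometry = v@geometry)
  side <- sub("\\.nii(\\.gz)?$", ".json", maskPath)
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  prov$alpha <- if (is.null(prov$alpha)) NA_real_ else prov$alpha
  prov$size <- sum(mask@data)
  prov$coherence <- if (is.null(prov$coherence)) 1 else prov$coherence
  prov$method <- if (is.null(prov$method)) "imported" else prov$method
  new("ReferenceRegion", mask = mask, provenance = prov)
}
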