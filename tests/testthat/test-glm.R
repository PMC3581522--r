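test_that("design matrix carries group and nuisance covariates", {
  m <- mkManifest(3, 3)
  d <- buildDesign(m)
  expect_equal(dim(d@X), c(6L, 4L))
  expect_equal(colnames(d@X), c("intercept", "group", "age", "sex"))
  expect_equal(d@X[, "group"], setNames(c(0, 0, 0, 1, 1, 1), m$id))
  expect_equal(sum(d@X[, "age"]), 0)    # mean-centered
  expect_equal(contrastVector(d, "decrease"), c(0, -1, 0, 0))
  expect_equal(contrastVector(d, "increase"), c(0, 1, 0, 0))

  # constant sex column is dropped with a warning, recorded in provenance
  expect_warning(d3 <- buildDesign(mkManifest(3, 3, sex = rep(1, 6))),
                 "sex")
  expect_equal(ncol(d3@X), 3L)
  expect_equal(d3@dropped, "sex")

  bad <- mkManifest(3, 3); bad$group <- "control"
  expect_error(buildDesign(bad), "both groups")
})

test_that("fitGLM reduces to the pooled two-sample t without covariates", {
  m <- mkManifest(3, 3)
  d <- buildDesign(m, covariates = character(0))
  vols <- scalarVolumes(c(1, 2, 3, 4, 5, 6))
  fit <- fitGLM(vols, d, "increase")
  expect_equal(fit@df, 4)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(fit@tMap[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(fit@tMap[1], 3.674, tolerance = 5e-4)

  # identical groups give t = 0; decrease contrast flips the sign
  expect_equal(fitGLM(scalarVolumes(rep(c(2, 5, 9), 2)),
                      d, "increase")@tMap[1], 0)
  expect_equal(fitGLM(vols, d, "decrease")@tMap[1],
               -fit@tMap[1])
})

test_that("t-maps match an independent per-voxel lm() oracle", {
  set.seed(21)
  n <- 20; nv <- 30
  m <- mkManifest(10, 10, sex = rbinom(n, 1, 0.5))
  m$age <- rnorm(n, 60, 8)
  Y <- matrix(rnorm(n * nv), n, nv)
  vols <- lapply(seq_len(n), function(i)
    mkVol(array(Y[i, ], dim = c(nv, 1, 1))))
  d <- buildDesign(m)
  fit <- fitGLM(vols, d, "increase")
  for (v in seq_len(nv)) {
    lmFit <- lm(Y[, v] ~ group + age + sex,
                data = transform(m, group = as.integer(group == "patient"),
                                 age = age - mean(age)))
    expect_equal(fit@tMap[v], summary(lmFit)$coefficients["group", "t value"],
                 tolerance = 1e-8)
  }
})

test_that("zero residual variance yields flagged infinite sentinels", {
  d <- buildDesign(mkManifest(3, 3), covariates = character(0))
  fit <- fitGLM(scalarVolumes(c(1, 1, 1, 2, 2, 2)), d, "increase")
  expect_identical(fit@tMap[1], Inf)
  expect_true(fit@zeroVar[1])
  # NaN voxels in any subject drop out of the analysis mask
  vols <- scalarVolumes(c(1, 2, 3, 4, 5, 6))
  vols[[2]]@data[1] <- NaN
  expect_error(fitGLM(vols, d), "empty")
})

test_that("connected components follow the 6/18/26 contiguity conventions", {
  solid <- array(0, c(5, 5, 5)); solid[2:4, 2:4, 2:4] <- 1
  expect_equal(nClusters(connectedComponents(solid, 6)), 1L)
  expect_equal(connectedComponents(solid, 6)@clusters[[1]]$size, 27)

  # voxels sharing an edge (two coordinates differ): joined at 18, not 6
  edge <- array(0, c(4, 4, 4)); edge[1, 1, 1] <- 1; edge[2, 2, 1] <- 1
  expect_equal(nClusters(connectedComponents(edge, 6)), 2L)
  expect_equal(nClusters(connectedComponents(edge, 18)), 1L)

  # voxels sharing only a corner: joined at 26 only
  corner <- array(0, c(4, 4, 4)); corner[1, 1, 1] <- 1; corner[2, 2, 2] <- 1
  expect_equal(nClusters(connectedComponents(corner, 18)), 2L)
  expect_equal(nClusters(connectedComponents(corner, 26)), 1L)

  # peaks recorded from a t-map, sizes sorted descending
  tm <- array(seq_len(64), c(4, 4, 4))
  two <- array(0, c(4, 4, 4)); two[1:2, 1, 1] <- 1; two[1:3, 4, 4] <- 1
  cs <- connectedComponents(two, 18, tMap = tm)
  expect_equal(vapply(cs@clusters, function(cl) cl$size, numeric(1)),
               c(3, 2))
  expect_equal(peakT(cs), max(tm[two > 0]))
})

test_that("exhaustive 3v3 permutation p-values match enumeration", {
  set.seed(31)
  nv <- 8
  Y <- matrix(rnorm(6 * nv), 6, nv)
  Y[4:6, 1] <- Y[4:6, 1] + 6        # one voxel with a strong real effect
  m <- mkManifest(3, 3)
  d <- buildDesign(m, covariates = character(0))
  vols <- lapply(1:6, function(i) mkVol(array(Y[i, ], dim = c(nv, 1, 1))))

  res <- voxelPermutationTest(vols, d, "increase", exhaustive = TRUE)

  # independent oracle: enumerate all 20 assignments, pooled t via t.test
  combs <- combn(6, 3)
  nullMax <- apply(combs, 2, function(idx) {
    max(vapply(seq_len(nv), function(v)
      unname(t.test(Y[idx, v], Y[-idx, v], var.equal = TRUE)$statistic),
      numeric(1)))
  })
  expect_equal(length(nullMax), 20L)
  pOracle <- vapply(res$tObs, function(t) mean(nullMax >= t - 1e-12),
                    numeric(1))
  expect_equal(res$pFWE, pOracle, tolerance = 1e-12)
  expect_lte(res$pFWE[1], 0.10)     # the real effect is among the smallest p
})

test_that("FWE thresholds: Bonferroni reductions and permutation guards", {
  m <- mkManifest(10, 10)
  set.seed(41)
  vols <- lapply(1:20, function(i) mkVol(array(rnorm(27), c(3, 3, 3))))
  d <- buildDesign(m)
  # single-voxel Bonferroni equals the uncorrected one-sided quantile
  one <- lapply(1:20, function(i) mkVol(array(rnorm(1), c(1, 1, 1))))
  thr1 <- voxelFweThreshold(one, d, "increase", alpha = 0.05,
                            method = "bonferroni")
  expect_equal(as.numeric(thr1), qt(0.95, 16), tolerance = 1e-12)
  thrV <- voxelFweThreshold(vols, d, "increase", alpha = 0.05,
                            method = "bonferroni")
  expect_equal(as.numeric(thrV), qt(1 - 0.05 / 27, 16), tolerance = 1e-12)

  # too few distinct relabelings for the requested alpha
  tiny <- buildDesign(mkManifest(2, 2), covariates = character(0))
  vols4 <- scalarVolumes(c(1, 2, 3, 4))
  expect_error(voxelFweThreshold(vols4, tiny, alpha = 0.01, nPerm = 100),
               "bonferroni")
  # nPerm insufficient to resolve alpha
  expect_error(voxelFweThreshold(vols, d, alpha = 0.001, nPerm = 100),
               "nPerm")
})

test_that("cluster inference applies the extent filter and the size null", {
  p <- phantomParams(shape = c(24, 24, 24))
  sim <- simulateCohort(p, 8, 8, seed = 12)
  d <- buildDesign(sim$manifest)
  nv <- normalizeCohort(sim$volumes,
                        referenceSpec("roi", sim$truth@preservedMask, "CBL"))
  cs <- clusterInference(nv, d, "decrease", kMin = 0, nPerm = 199, seed = 3,
                         mask = sim$truth@brainMask)
  expect_gt(nClusters(cs), 0)
  largest <- cs@clusters[[1]]$size
  expect_true(all(vapply(cs@clusters, function(cl) cl$pFWE, numeric(1))
                  <= 0.05 + 1e-12))

  # kMin excludes clusters below the extent threshold; non-strict vs strict
  keepAt <- clusterInference(nv, d, "decrease", kMin = largest,
                             kStrict = FALSE, nPerm = 199, seed = 3,
                             mask = sim$truth@brainMask)
  expect_true(largest %in% vapply(keepAt@clusters, function(cl) cl$size,
                                  numeric(1)))
  dropAt <- clusterInference(nv, d, "decrease", kMin = largest,
                             kStrict = TRUE, nPerm = 199, seed = 3,
                             mask = sim$truth@brainMask)
  expect_false(largest %in% vapply(dropAt@clusters, function(cl) cl$size,
                                   numeric(1)))
})

test_that("reference-cluster escalation recovers the spared cap and errors on null data", {
  sim <- simulateCohort(phantomParams(), 20, 20, seed = 3)
  d <- buildDesign(sim$manifest)
  cgm <- normalizeCohort(sim$volumes, referenceSpec("cgm"))
  rc <- deriveReferenceCluster(cgm, d, mask = sim$truth@brainMask)
  expect_s4_class(rc, "ReferenceRegion")
  expect_gte(diceCoefficient(rc@mask, sim$truth@preservedMask), 0.5)
  prov <- rc@provenance
  expect_true(all(c("alpha", "path", "size", "coherence", "method")
                  %in% names(prov)))
  expect_gte(prov$coherence, 0.9)
  expect_equal(sum(voxelData(rc@mask)), prov$size)
  # escalation path is recorded lenient-to-stringent
  expect_true(all(diff(prov$path$alpha) <= 0))

  # null phantom: no level yields a coherent cluster
  null <- simulateCohort(phantomParams(hypometabolismFactor = 1), 10, 10,
                         seed = 4)
  dn <- buildDesign(null$manifest)
  cgmN <- normalizeCohort(null$volumes, referenceSpec("cgm"))
  expect_error(deriveReferenceCluster(cgmN, dn, mask = null$truth@brainMask),
               "no reference cluster")
})
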