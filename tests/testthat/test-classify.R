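test_that("pattern means extract one scalar per subject", {
  m <- mkManifest(2, 2)
  vols <- list(constVol(1), constVol(1), constVol(2), constVol(3))
  pat <- mkMask(array(c(1, rep(0, 63)), c(4, 4, 4)))
  ft <- extractPatternMeans(vols, pat, m)
  expect_equal(ft$feature, c(1, 1, 2, 3))    # single voxel = that value
  expect_equal(ft$group, m$group)

  full <- mkMask(array(1, c(4, 4, 4)))
  expect_equal(extractPatternMeans(vols, full, m)$feature, c(1, 1, 2, 3))
  expect_error(extractPatternMeans(vols, mkMask(array(0, c(4, 4, 4))), m),
               "empty")
})

test_that("pattern overlap is a voxel-wise intersection", {
  a <- mkMask(array(c(rep(1, 32), rep(0, 32)), c(4, 4, 4)))
  b <- mkMask(array(c(rep(0, 16), rep(1, 48)), c(4, 4, 4)))
  ov <- patternOverlap(list(a, b))
  expect_equal(sum(voxelData(ov)), 16)
  expect_equal(voxelData(patternOverlap(list(a, a))), voxelData(a))
  # subset relation: A within B returns A
  sub <- mkMask(array(c(rep(1, 8), rep(0, 56)), c(4, 4, 4)))
  expect_equal(voxelData(patternOverlap(list(sub, a))), voxelData(sub))
  disj <- mkMask(array(c(rep(0, 32), rep(1, 32)), c(4, 4, 4)))
  expect_error(patternOverlap(list(a, disj)), "empty intersection")
})

test_that("ridge-stabilised logistic handles separation and degeneracy", {
  # separable: features equal labels
  f <- fitLogistic(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_equal(f$predict(c(0, 0, 0, 1, 1, 1)), c(0L, 0L, 0L, 1L, 1L, 1L))

  # constant feature: majority class wins
  f0 <- fitLogistic(rep(2, 7), c(0, 0, 0, 0, 1, 1, 1))
  expect_equal(f0$predict(rep(2, 7)), rep(0L, 7))
  f1 <- fitLogistic(rep(2, 7), c(0, 0, 0, 1, 1, 1, 1))
  expect_equal(f1$predict(rep(2, 7)), rep(1L, 7))

  # balanced symmetric data: decision boundary at 0
  fs <- fitLogistic(c(-1, -1.5, -0.5, 1, 1.5, 0.5), c(0, 0, 0, 1, 1, 1))
  expect_lt(abs(fs$intercept), 1e-6)
  expect_gt(fs$slope, 0)

  expect_error(fitLogistic(1:4, rep(1, 4)), "both classes")
})

test_that("split-half cross-validation metrics are consistent and reproducible", {
  set.seed(8)
  x <- c(rnorm(9, 1), rnorm(7, -1))
  y <- c(rep(0, 9), rep(1, 7))
  d1 <- splitHalfCV(x, y, nRep = 150, seed = 5)
  d2 <- splitHalfCV(x, y, nRep = 150, seed = 5)
  expect_identical(d1@accuracy, d2@accuracy)

  # per repetition, accuracy is the test-size-weighted mean of sens/spec
  nT1 <- floor(7 / 2); nT0 <- floor(9 / 2)
  expect_equal(d1@accuracy,
               (d1@sensitivity * nT1 + d1@specificity * nT0) / (nT1 + nT0))

  # odd class sizes: extra subject goes to training
  expect_equal(nT1 + nT0, 7)

  # character labels accepted
  dc <- splitHalfCV(x, ifelse(y == 1, "patient", "control"), nRep = 10,
                    seed = 5)
  expect_identical(dc@accuracy, d1@accuracy[1:10])

  # perfectly separated features classify every repetition perfectly
  sep <- splitHalfCV(c(rnorm(8) + 10, rnorm(8) - 10), rep(c(0, 1), each = 8),
                     nRep = 50, seed = 1)
  expect_true(all(sep@accuracy == 1))

  expect_error(splitHalfCV(1:3, c(0, 1, 1), nRep = 5), "at least 2")
})

test_that("label swap exchanges the roles of sensitivity and specificity", {
  set.seed(9)
  x <- c(rnorm(10, 0.8), rnorm(10, -0.8))
  y <- c(rep(0, 10), rep(1, 10))
  a <- splitHalfCV(x, y, nRep = 2000, seed = 2)
  b <- splitHalfCV(x, 1 - y, nRep = 2000, seed = 2)
  expect_equal(mean(a@sensitivity), mean(b@specificity), tolerance = 0.02)
  expect_equal(mean(a@specificity), mean(b@sensitivity), tolerance = 0.02)
  expect_equal(mean(a@accuracy), mean(b@accuracy), tolerance = 0.02)
})

test_that("scheme comparisons use pairwise t-tests with Bonferroni counting", {
  set.seed(10)
  mk <- function(mu, scheme) new("AccuracyDistribution",
    accuracy = pmin(pmax(rnorm(400, mu, 0.02), 0), 1),
    sensitivity = pmin(pmax(rnorm(400, mu, 0.02), 0), 1),
    specificity = pmin(pmax(rnorm(400, mu - 0.1, 0.02), 0), 1),
    nRep = 400L, seed = 1L, scheme = scheme)
  dists <- list(A = mk(0.9, "A"), B = mk(0.9, "B"), C = mk(0.7, "C"),
                D = mk(0.5, "D"))
  cmp <- compareDistributions(dists)
  expect_equal(nrow(cmp$pairwise), 6L)           # choose(4, 2) pairs
  expect_equal(cmp$pairwise$pBonferroni,
               pmin(1, cmp$pairwise$p * 6), tolerance = 1e-12)
  ac <- cmp$pairwise[cmp$pairwise$scheme1 == "A" &
                     cmp$pairwise$scheme2 == "C", ]
  expect_true(ac$significant)                    # 10 sd apart
  # a distribution against an equal-mean twin is not significant
  ab <- cmp$pairwise[cmp$pairwise$scheme1 == "A" &
                     cmp$pairwise$scheme2 == "B", ]
  expect_false(ab$significant)
  # sensitivity < specificity detected within scheme
  expect_true(all(cmp$sensVsSpec$significant))
  expect_error(compareDistributions(list(A = dists$A)), "2")

  # degenerate constant distributions compare sanely
  cst <- function(v, s) new("AccuracyDistribution",
    accuracy = rep(v, 50), sensitivity = rep(v, 50),
    specificity = rep(v, 50), nRep = 50L, seed = 1L, scheme = s)
  cc <- compareDistributions(list(X = cst(1, "X"), Y = cst(1, "Y")))
  expect_equal(cc$pairwise$p, 1)
})

test_that("pure-noise features classify at chance", {
  # a single null cohort carries accidental separation that resplitting
  # cannot remove, so chance level emerges in expectation over cohorts
  set.seed(12)
  y <- rep(c(0, 1), each = 20)
  accs <- vapply(1:200, function(i)
    mean(splitHalfCV(rnorm(40), y, nRep = 50, seed = i)@accuracy),
    numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.02)
})
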