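test_that("the two-pass global mean follows the mean/8 rule", {
  expect_equal(spmGlobalMean(constVol(50)), 50)

  # hand-computable: m0 = 4, threshold 0.5, second pass keeps the 8s
  img <- mkVol(array(c(0, 0, 0, 0, 8, 8, 8, 8), dim = c(2, 2, 2)))
  expect_equal(spmGlobalMean(img), 8)

  # homogeneity in positive rescaling
  set.seed(3)
  arr <- array(rexp(64) * 10, dim = c(4, 4, 4))
  g1 <- spmGlobalMean(mkVol(arr))
  for (c in c(0.1, 1, 17))
    expect_equal(spmGlobalMean(mkVol(c * arr)), c * g1, tolerance = 1e-12)

  # NaN voxels excluded from both passes
  arr2 <- arr; arr2[1:10] <- NaN
  expect_equal(spmGlobalMean(mkVol(arr2)),
               spmGlobalMean(mkVol(array(arr[-(1:10)],
                                         dim = c(2, 3, 9)))))
  expect_error(spmGlobalMean(mkVol(array(NaN, c(2, 2, 2)))), "finite")
})

test_that("roiMean averages masked finite voxels only", {
  arr <- array(0, dim = c(3, 3, 3)); arr[1] <- 4; arr[2] <- 8
  m <- array(0, c(3, 3, 3)); m[1:2] <- 1
  expect_equal(roiMean(mkVol(arr), mkMask(m)), 6)
  expect_equal(roiMean(constVol(3, c(3, 3, 3)), mkMask(m)), 3)
  arr[1:2] <- NaN
  expect_error(roiMean(mkVol(arr), mkMask(m)), "no finite")
})

test_that("normalization is a ratio with the stated algebraic laws", {
  set.seed(4)
  arr <- array(runif(6^3, 10, 30), dim = c(6, 6, 6))
  img <- mkVol(arr)
  m <- array(0, c(6, 6, 6)); m[1:20] <- 1
  roi <- referenceSpec("roi", mkMask(m), "ROI")

  # simple ratio: voxel 8 with roi mean 4 and target 1 -> 2
  a2 <- array(4, c(2, 2, 2)); a2[1] <- 8
  m2 <- mkMask(array(c(0, 1, 1, 1, 1, 1, 1, 1), c(2, 2, 2)))
  nv <- normalizeVolume(mkVol(a2), referenceSpec("roi", m2))
  expect_equal(voxelData(nv)[1], 2)

  for (ref in list(roi, referenceSpec("cgm"))) {
    base <- normalizeVolume(img, ref)
    # post-normalization reference mean equals target
    refMean <- if (ref@kind == "cgm") spmGlobalMean(base)
               else roiMean(base, ref@mask)
    expect_equal(refMean, 1, tolerance = 1e-10)
    # scale invariance
    for (c in c(0.1, 1, 17))
      expect_equal(voxelData(normalizeVolume(mkVol(c * arr), ref)),
                   voxelData(base), tolerance = 1e-12)
    # idempotence
    expect_equal(voxelData(normalizeVolume(base, ref)), voxelData(base),
                 tolerance = 1e-12)
    # configurable target
    expect_equal(voxelData(normalizeVolume(img, ref, target = 50)),
                 50 * voxelData(base), tolerance = 1e-12)
  }

  expect_error(normalizeVolume(mkVol(-arr), roi), "non-positive")
  # constant volume maps to constant target under any reference
  expect_equal(voxelData(normalizeVolume(constVol(10), referenceSpec("cgm"))),
               array(1, c(4, 4, 4)))
})

test_that("smoothing is linear, so normalize-then-smooth equals smooth-then-normalize", {
  set.seed(5)
  a <- mkVol(array(runif(5^3, 1, 2), dim = c(5, 5, 5)))
  b <- mkVol(array(runif(5^3, 1, 2), dim = c(5, 5, 5)))
  sAB <- gaussianSmooth(mkVol(2 * voxelData(a) + 3 * voxelData(b)), fwhm = 6)
  expect_equal(voxelData(sAB),
               2 * voxelData(gaussianSmooth(a, 6)) +
               3 * voxelData(gaussianSmooth(b, 6)), tolerance = 1e-12)
})

test_that("preserved-parcel normalization cancels the deficit; CGM inflates it", {
  p <- noiselessParams(factor = 0.8)
  tr <- makeParcellation(p)
  ctl <- simulateSubject(tr, p, "control", seed = 1)
  pat <- simulateSubject(tr, p, "patient", seed = 1)

  nCtl <- normalizeVolume(ctl, tr@preservedMask)
  nPat <- normalizeVolume(pat, tr@preservedMask)
  # in the preserved cap the residual patient/control discrepancy after
  # ROI normalization is kernel leakage only: well under the 20% deficit
  core <- which(voxelData(erodeMask(tr@preservedMask, 1)) > 0)
  expect_gt(length(core), 20)
  expect_lt(max(abs(voxelData(nPat)[core] / voxelData(nCtl)[core] - 1)),
            0.05)

  # a narrow kernel plus an uncontaminated interior reference (the
  # reference-cluster idea) makes the cancellation essentially exact
  p6 <- noiselessParams(factor = 0.8, smoothingFwhm = 6,
                        shape = c(32, 32, 32))
  tr6 <- makeParcellation(p6)
  c6 <- simulateSubject(tr6, p6, "control", seed = 1)
  p6v <- simulateSubject(tr6, p6, "patient", seed = 1)
  coreMask <- erodeMask(tr6@preservedMask, 2)
  core6 <- which(voxelData(coreMask) > 0)
  n6c <- normalizeVolume(c6, coreMask)
  n6p <- normalizeVolume(p6v, coreMask)
  expect_equal(voxelData(n6p)[core6], voxelData(n6c)[core6],
               tolerance = 5e-3)

  # global-mean normalization inflates the whole image of patients by
  # g_control / g_patient, predictable in closed form from parcel sums
  gc <- spmGlobalMean(ctl); gp <- spmGlobalMean(pat)
  lab <- voxelData(tr@parcellation)
  brain <- voxelData(tr@brainMask) > 0
  w <- p@severityWeights
  num <- sum((p@baseline)[lab[brain]])
  den <- sum((p@baseline * (1 - w * 0.2))[lab[brain]])
  expect_gt(gc / gp, 1.1)
  expect_equal(gc / gp, num / den, tolerance = 0.01)

  # algebraic identity: the CGM-normalized preserved-region ratio is the
  # raw ratio times g_control / g_patient, and nets out as apparent
  # hypermetabolism in patients
  cgmPat <- normalizeVolume(pat, referenceSpec("cgm"))
  cgmCtl <- normalizeVolume(ctl, referenceSpec("cgm"))
  rawRatio <- roiMean(pat, tr@preservedMask) / roiMean(ctl, tr@preservedMask)
  cgmRatio <- roiMean(cgmPat, tr@preservedMask) /
    roiMean(cgmCtl, tr@preservedMask)
  expect_equal(cgmRatio, rawRatio * gc / gp, tolerance = 1e-10)
  expect_gt(rawRatio, 0.92)     # leakage through the gap stays small
  expect_gt(cgmRatio, 1.05)     # spurious apparent increase under CGM
})
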