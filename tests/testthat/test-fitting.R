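# Fitting-accuracy analysis: alignment, deviation statistics, accuracy
# decomposition, gaps, and the MAS hypothesis test.

test_that("ICP aligns a self-sampled cloud to machine precision", {
  ph <- smallPhantom()
  cloud <- simulateScan(ph, pointsPerMm2 = 0.3, noiseSD = 0, seed = 1L)
  ali <- bestFitAlign(cloud, ph, preAlign = FALSE)
  expect_lt(ali$rms, 1e-6)
  ang <- acos(pmin(1, (sum(diag(ali$transform@rotation)) - 1) / 2))
  expect_lt(ang, 1e-5)
  expect_lt(sqrt(sum(ali$transform@translation^2)), 1e-4)
})

test_that("ICP recovers a known rigid pose", {
  # asymmetric shell: a perfect ellipsoid leaves the recovered pose
  # ambiguous up to its half-turn symmetries
  ph <- makeSkullPhantom(smallPhantomSpec(asym = 1.2))
  th <- 20 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pose <- RigidTransform(R, c(6, -4, 3))
  cloud <- simulateScan(ph, pointsPerMm2 = 0.3, noiseSD = 0, pose = pose, seed = 2L)
  ali <- bestFitAlign(cloud, ph)
  recovered <- composeTransform(ali$transform, pose) # should be identity
  ang <- acos(pmin(1, (sum(diag(recovered@rotation)) - 1) / 2))
  expect_lt(ang, 1e-3)
  expect_lt(sqrt(sum(recovered@translation^2)), 0.01)
  # with noise the residual settles at the noise floor
  noisy <- simulateScan(ph, pointsPerMm2 = 0.3, noiseSD = 0.1, pose = pose, seed = 3L)
  ali2 <- bestFitAlign(noisy, ph)
  expect_lt(abs(ali2$rms / 0.1 - 1), 0.2)
})

test_that("signed deviation has the offset-surface magnitude and sign", {
  ref <- icosphereMesh(20, subdiv = 4)
  outer <- icosphereMesh(20.5, subdiv = 4)
  dev <- signedDeviation(outer, ref, nSample = 4000)
  expect_lt(abs(mean(dev) - 0.5), 0.02)
  expect_true(all(dev > 0.4))
  inner <- signedDeviation(matrix(c(0, 0, 19), 1), ref)
  expect_lt(inner[1], 0) # interior point is negative
  self <- signedDeviation(ref, ref, nSample = 2000)
  expect_lt(max(abs(self)), 1e-6)
})

test_that("mean outward deviation uses only the positive subset", {
  expect_equal(as.numeric(meanOutwardDeviation(rep(0.25, 10))), 0.25)
  expect_equal(as.numeric(meanOutwardDeviation(c(2, -2))), 2)
  allNeg <- meanOutwardDeviation(c(-1, -0.5))
  expect_equal(as.numeric(allNeg), 0)
  expect_true(attr(allNeg, "noPositive"))
  expect_error(meanOutwardDeviation(numeric(0)), "empty")
})

test_that("ROI deviation localises a one-sided perturbation", {
  ref <- icosphereMesh(20, subdiv = 4)
  pts <- sampleSurface(ref, 6000, seed = 4L)
  pts <- unclass(pts)[1:6000, , drop = FALSE]
  # push points outward only where y > 0
  nrm <- pts / sqrt(rowSums(pts^2))
  bump <- ifelse(pts[, 2] > 0, 0.4, 0)
  test <- pts + bump * nrm
  globalDev <- meanOutwardDeviation(signedDeviation(test, ref))
  roiQuiet <- roiDeviation(test, ref, rbind(c(-25, -25, -25), c(25, -1, 25)))
  roiBumpy <- roiDeviation(test, ref, rbind(c(-25, 1, -25), c(25, 25, 25)))
  expect_lt(as.numeric(roiQuiet), as.numeric(globalDev))
  expect_gt(as.numeric(roiBumpy), as.numeric(globalDev))
  # ROI covering everything reproduces the global statistic
  whole <- roiDeviation(test, ref, rbind(c(-25, -25, -25), c(25, 25, 25)))
  expect_equal(as.numeric(whole), as.numeric(globalDev))
  expect_error(roiDeviation(test, ref, rbind(c(100, 100, 100), c(101, 101, 101))),
               "no test points")
})

test_that("accuracy decomposition isolates its two components", {
  ph <- smallPhantom()
  rec <- smallRecon()
  designed <- rec$defectFree
  # scanned identical to designed: no manufacturing component
  scan0 <- simulateScan(designed, pointsPerMm2 = 0.3, noiseSD = 0, seed = 5L)
  rep0 <- decomposeAccuracy(ph, designed, scan0, nSample = 8000)
  expect_lt(rep0@manufacturingComponent, 0.01)
  expect_close(rep0@totalAsSum, rep0@modelingComponent + rep0@manufacturingComponent,
               1e-12)
  # designed identical to clean: no modeling component
  scan1 <- simulateScan(ph, pointsPerMm2 = 0.3, noiseSD = 0, seed = 6L)
  rep1 <- decomposeAccuracy(ph, ph, scan1, nSample = 8000)
  expect_lt(rep1@modelingComponent, 0.01)
  # badly misaligned inputs are rejected
  far <- sweep(scan1, 2, c(100, 0, 0), "+")
  expect_error(decomposeAccuracy(ph, ph, far), "misaligned")
})

test_that("gap analysis measures axis-aligned extents and gaps", {
  box <- cubeMesh(c(0, 0, 0), c(62.25, 75.03, 5))
  g0 <- gapAnalysis(box, box)
  expect_equal(unname(g0@implantExtent), c(62.25, 75.03))
  expect_equal(unname(g0@gap), c(0, 0))
  shrunk <- cubeMesh(c(0.05, 0, 0), c(62.20, 75.03, 5))
  g1 <- gapAnalysis(shrunk, box)
  expect_close(g1@gap["x"], 0.10, 1e-9)
  expect_close(g1@gap["y"], 0, 1e-9)
  expect_error(gapAnalysis(box, TriMesh(matrix(0, 0, 3), matrix(0L, 0, 3))),
               "empty")
})

test_that("the MAS t-test matches the reference implementation", {
  scores <- simulateVAS(10, 5, mean = 3.7, sd = 0.6, seed = 11L)
  res <- masTest(scores)
  oracle <- t.test(rowMeans(scores), mu = 3, alternative = "greater")
  expect_lt(abs(res@tStatistic - unname(oracle$statistic)), 1e-9)
  expect_lt(abs(res@pValue - oracle$p.value), 1e-6)
  expect_equal(res@n, 10L)
  # per-rating observation unit
  resR <- masTest(scores, unit = "rating")
  oracleR <- t.test(as.vector(scores), mu = 3, alternative = "greater")
  expect_lt(abs(resR@tStatistic - unname(oracleR$statistic)), 1e-9)
  expect_equal(resR@n, 50L)
})

test_that("MAS decision rules handle the degenerate cases", {
  # textbook per-expert means: 0.7 above the null with small spread
  vals <- c(4, 4, 3, 4, 3, 4, 4, 3, 4, 4)
  scores <- matrix(rep(vals, 5), 10, 5)
  res <- masTest(scores)
  s <- sd(vals)
  expect_lt(abs(res@tStatistic - 0.7 / (s / sqrt(10))), 1e-9)
  expect_true(res@rejectNull)
  # all-3 table: mean equals the null, cannot reject
  all3 <- matrix(3L, 10, 5)
  res3 <- masTest(all3)
  expect_true(res3@degenerate)
  expect_false(res3@rejectNull)
  # zero variance above the null still rejects; alpha = 0 never rejects
  all4 <- matrix(4L, 10, 5)
  expect_true(masTest(all4)@rejectNull)
  expect_false(masTest(all4, alpha = 0)@rejectNull)
  expect_false(masTest(scores, alpha = 0)@rejectNull)
  expect_error(masTest(matrix(7, 3, 2)), "1..5")
})
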