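# Segmentation stage: threshold, region growing, isosurface extraction.

test_that("threshold segmentation obeys its window", {
  vol <- ImageVolume(array(-1000, c(8, 8, 8)), spacing = 1)
  expect_false(any(thresholdSegment(vol, lower = 226)@mask))
  expect_true(all(thresholdSegment(vol, lower = -Inf)@mask))
  expect_error(thresholdSegment(vol, lower = 10, upper = 0), "lower")
  ph <- smallPhantom()
  ct <- voxelizeToCT(ph, spacing = 0.8, noiseSD = 0)
  m <- thresholdSegment(ct, lower = 500)
  expect_lt(abs(maskVolume(m) / meshVolume(ph) - 1), 0.02)
})

test_that("region growing selects connected components correctly", {
  a <- array(FALSE, c(20, 10, 10))
  a[2:6, 2:6, 2:5] <- TRUE     # 100 voxels
  a[12:14, 2:3, 2:3] <- TRUE   # 12 voxels (but labeling by size, disjoint)
  mask <- BinaryMask(a, spacing = 1)
  big <- regionGrow(mask, "largest")
  expect_equal(sum(big@mask), 100)
  small <- regionGrow(mask, "seeded", seedVoxel = c(13, 2, 2))
  expect_equal(sum(small@mask), 12)
  # idempotent
  again <- regionGrow(big, "largest")
  expect_identical(again@mask, big@mask)
  # single blob passes through unchanged
  b <- array(FALSE, c(5, 5, 5)); b[2:4, 2:4, 2:4] <- TRUE
  one <- regionGrow(BinaryMask(b, 1), "largest")
  expect_identical(one@mask, b)
  expect_error(regionGrow(mask, "seeded", seedVoxel = c(1, 1, 1)), "outside")
})

test_that("mask isosurface has the right volume and lattice structure", {
  # solid ball of radius 20 on a 1 mm grid
  n <- 45
  ctr <- 23
  idx <- arrayInd(seq_len(n^3), c(n, n, n))
  ball <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= 20, c(n, n, n))
  mask <- BinaryMask(ball, spacing = 1, origin = c(0, 0, 0))
  mesh <- maskToMesh(mask, smoothIterations = 0)
  expect_true(isWatertight(mesh))
  expect_lt(abs(meshVolume(mesh) / (4 * pi * 20^3 / 3) - 1), 0.02)
  # with no smoothing, vertices sit on voxel-edge midpoints (half-lattice)
  frac <- (mesh@vertices - mask@origin[col(mesh@vertices)]) / 0.5
  expect_lt(max(abs(frac - round(frac))), 1e-9)
  expect_error(maskToMesh(BinaryMask(array(FALSE, c(3, 3, 3)), 1)), "empty")
})

test_that("segmentation round trip stays within a voxel of the phantom", {
  ph <- smallPhantom()
  ct <- voxelizeToCT(ph, spacing = 0.8, noiseSD = 0)
  mask <- regionGrow(thresholdSegment(ct, lower = 500), "largest")
  mesh <- maskToMesh(mask, smoothIterations = 10)
  expect_true(isWatertight(mesh))
  dev <- signedDeviation(mesh, ph, nSample = 5000)
  expect_lt(mean(abs(dev)), 0.8)
  expect_lt(abs(meshVolume(mesh) / meshVolume(ph) - 1), 0.03)
})
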