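# Synthetic phantom and simulators: geometry oracles are closed-form
# ellipsoid-shell volumes and the constructed symmetry of the mesh.

test_that("phantom volume matches the closed-form ellipsoid shell", {
  spec <- PhantomSpec(outerRadii = c(90, 70, 60), shellThickness = 6,
                      asymmetryAmplitude = 0)
  ph <- makeSkullPhantom(spec)
  expect_true(isWatertight(ph))
  exact <- 4 * pi / 3 * (90 * 70 * 60 - 84 * 64 * 54)
  expect_lt(abs(meshVolume(ph) / exact - 1), 0.01)
})

test_that("symmetric phantom is exactly mirror-symmetric about x = 0", {
  ph <- smallPhantom()
  refl <- mirrorMesh(ph, Plane(c(0, 0, 0), c(1, 0, 0)))
  expect_lt(hausdorffDistance(ph, refl, n = 2000), 1e-9)
})

test_that("phantom generation is deterministic for fixed spec and seed", {
  s <- smallPhantomSpec(asym = 1.5)
  a <- makeSkullPhantom(s)
  b <- makeSkullPhantom(s)
  expect_identical(a@vertices, b@vertices)
  # asymmetry actually breaks the left-right symmetry
  refl <- mirrorMesh(a, Plane(c(0, 0, 0), c(1, 0, 0)))
  expect_gt(hausdorffDistance(a, refl, n = 2000), 0.5)
})

test_that("degenerate phantom specs are rejected", {
  expect_error(PhantomSpec(outerRadii = c(40, 32, 28), shellThickness = 30),
               "shellThickness")
  expect_error(PhantomSpec(defectRadius = -1), "defectRadius")
  expect_error(PhantomSpec(outerRadii = c(-1, 32, 28)), "outerRadii")
})

test_that("noise-free voxelization reproduces the mesh volume", {
  ph <- smallPhantom()
  ct <- voxelizeToCT(ph, spacing = 0.8, noiseSD = 0)
  voxVol <- sum(ct@intensities >= 500) * prod(ct@spacing)
  expect_lt(abs(voxVol / meshVolume(ph) - 1), 0.02)
  # away from the mesh everything is background
  expect_equal(ct@intensities[1, 1, 1], -1000)
  # fixed seed reproducible with noise
  a <- voxelizeToCT(ph, spacing = 2, noiseSD = 30, seed = 5L)
  b <- voxelizeToCT(ph, spacing = 2, noiseSD = 30, seed = 5L)
  expect_identical(a@intensities, b@intensities)
  expect_error(voxelizeToCT(ph, spacing = -1), "spacing")
})

test_that("carving an interior ball removes exactly its volume", {
  ph <- smallPhantom()
  # ball fully inside the 5 mm wall: centre on the mid-surface, radius 2
  midR <- smallPhantomSpec()@outerRadii - 2.5
  center <- c(0, 0, midR[3])
  base <- remeshVoxel(ph, 0.25)
  carved <- carveDefect(ph, center, 2, voxel = 0.25)
  deficit <- meshVolume(base) - meshVolume(carved)
  expect_lt(abs(deficit - 4 * pi * 2^3 / 3), 0.01 * 4 * pi * 2^3 / 3 + 0.05)
  # tiny defect leaves the volume essentially unchanged
  surfPoint <- c(0, 0, 28)
  dent <- carveDefect(ph, surfPoint, 0.5, voxel = 0.25)
  expect_lt(abs(meshVolume(dent) - meshVolume(base)), 2)
  # a ball that misses the skull entirely is an error, not a no-op
  expect_error(carveDefect(ph, c(200, 0, 0), 5), "intersect")
})

test_that("a left-side defect breaks the mirror symmetry", {
  def <- smallDefective()
  refl <- mirrorMesh(def, Plane(c(0, 0, 0), c(1, 0, 0)))
  expect_gt(hausdorffDistance(def, refl, n = 2000), 2)
})

test_that("simulated manufacturing realises the requested mean displacement", {
  ph <- smallPhantom()
  expect_identical(simulateManufacturing(ph, 0), ph)
  fab <- simulateManufacturing(ph, 0.3, seed = 3L)
  expect_close(attr(fab, "meanDisplacement"), 0.3, 1e-9)
  # recovery through the deviation statistic
  cloud <- simulateScan(fab, pointsPerMm2 = 0.5, noiseSD = 0, seed = 4L)
  mod <- meanOutwardDeviation(signedDeviation(cloud, ph))
  expect_close(as.numeric(mod), 0.3, 0.05)
  # different seeds: distinct fields, comparable roughness
  fab2 <- simulateManufacturing(ph, 0.3, seed = 8L)
  expect_false(identical(fab@vertices, fab2@vertices))
  expect_lt(abs(attr(fab2, "rmsDisplacement") / attr(fab, "rmsDisplacement") - 1),
            0.10)
})

test_that("simulated scans sample the surface at the requested density", {
  ph <- smallPhantom()
  cloud <- simulateScan(ph, pointsPerMm2 = 0.2, noiseSD = 0, seed = 2L)
  expect_equal(nrow(cloud), ceiling(surfaceArea(ph) * 0.2))
  d <- distanceToMesh(cloud, ph)$distance
  expect_lt(max(d), 1e-9)
  expect_error(simulateScan(ph, pointsPerMm2 = 0), "positive")
})

test_that("VAS simulation respects its distribution contract", {
  expect_true(all(simulateVAS(10, 5, mean = 4, sd = 0) == 4L))
  a <- simulateVAS(10, 5, mean = 3.7, sd = 0.5, seed = 9L)
  b <- simulateVAS(10, 5, mean = 3.7, sd = 0.5, seed = 9L)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 5))
  big <- simulateVAS(200, 5, mean = 3.66, sd = 0.5, seed = 10L)
  expect_close(mean(big), 3.66, 2 * 0.5 / sqrt(length(big)) + 0.02)
  expect_error(simulateVAS(10, 5, sd = -1), "sd")
  expect_error(simulateVAS(0, 5), "at least")
})
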