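# Implant design: template surface extraction, offset shell, rim/core
# partition, diamond scaffold, porosity and pore metrology, screw holes.

test_that("outer-surface extraction returns the skull-conformal patch", {
  rec <- smallRecon()
  patch <- extractOuterSurface(rec$template, rec$defectFree)
  expect_gt(nFaces(patch), 100)
  # open, single-component, outward-oriented patch
  audit <- cranioforge:::cpp_edge_audit(patch@faces)
  expect_gt(audit$n_boundary_edges, 0)
  expect_equal(max(meshComponents(patch)), 1)
  fg <- cranioforge:::.faceGeometry(patch)
  outward <- rowSums(fg$normal * sweep(fg$centroid, 2, c(0, 0, 0))) > 0
  expect_gt(mean(outward), 0.99)
  # the patch hugs the skull surface
  d <- distanceToMesh(fg$centroid, rec$defectFree)$distance
  expect_lt(stats::median(d), 0.1)
  # with an infinite tolerance every face qualifies
  all <- extractOuterSurface(rec$template, rec$defectFree, eps = 1e6, angleDeg = 180)
  expect_equal(nFaces(all), nFaces(rec$template))
})

test_that("offset shell has the closed-form swept volume", {
  # flat square patch: exact prism
  solid <- offsetShell(flatPatch(10, n = 8), 4)
  expect_true(isWatertight(solid))
  expect_lt(abs(meshVolume(solid) - 400) / 400, 0.01)
  expect_setequal(unique(solid@faceTags), c(1L, 2L, 3L))
  # spherical cap: shell-sector closed form (2pi/3)(1 - cos t0)(R^3 - r^3)
  sp <- icosphereMesh(20, subdiv = 4)
  capFaces <- cranioforge:::.faceGeometry(sp)$centroid[, 3] > 0.5 * 20
  cap <- cranioforge:::.subMesh(sp, capFaces)
  capSolid <- offsetShell(cap, 3)
  cosT0 <- 0.5
  exact <- 2 * pi / 3 * (1 - cosT0) * (20^3 - 17^3)
  expect_lt(abs(meshVolume(capSolid) / exact - 1), 0.02)
  expect_error(offsetShell(flatPatch(10), 0), "positive")
  # thickness beyond the curvature radius inverts the sweep
  small <- icosphereMesh(5, subdiv = 3)
  capS <- cranioforge:::.subMesh(small, cranioforge:::.faceGeometry(small)$centroid[, 3] > 2)
  expect_error(offsetShell(capS, 8), "curvature")
})

test_that("rim/core partition is volume-conserving with the right footprint", {
  solid <- offsetShell(diskPatch(30), 4)
  parts <- partitionRimCore(solid, 5, voxel = 0.4)
  vr <- meshVolume(parts$rim)
  vc <- meshVolume(parts$core)
  expect_lt(abs((vr + vc) / meshVolume(solid) - 1), 0.01)
  # disk: core keeps roughly the (r - w)^2 / r^2 footprint
  expect_lt(abs(vc / (vr + vc) - (25 / 30)^2), 0.03)
  # near-zero rim leaves the core almost everything
  p2 <- suppressMessages(partitionRimCore(solid, 0.4, voxel = 0.4))
  expect_gt(meshVolume(p2$core) / meshVolume(solid), 0.93)
  expect_error(partitionRimCore(solid, 40, voxel = 0.5), "consumes")
})

test_that("porosity formula is exact, bounded and scale-invariant", {
  expect_equal(porosity(100, 30), 70)
  expect_equal(porosity(5, 5), 0)
  expect_equal(porosity(5, 0), 100)
  expect_equal(porosity(1000, 300), porosity(10, 3))
  expect_error(porosity(0, 0), "positive")
  expect_error(porosity(10, 11), "v2")
})

test_that("diamond scaffold volume behaves with strut radius", {
  core <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  radii <- c(0.4, 0.6, 0.8)
  vols <- vapply(radii, function(r) {
    meshVolume(generateDiamondLattice(core, LatticeSpec(5, r, 0.5), voxel = 0.1))
  }, numeric(1))
  expect_true(all(diff(vols) > 0)) # strictly increasing in strut radius
  # voxel-counting oracle for the largest radius
  scaf <- generateDiamondLattice(core, LatticeSpec(5, 0.8, 0.5), voxel = 0.1)
  dims <- as.integer(c(104, 104, 104))
  occ <- cranioforge:::cpp_inside_grid(scaf@vertices, scaf@faces,
                                       c(-0.15, -0.15, -0.15), rep(0.1, 3), dims)
  expect_lt(abs(sum(occ) * 0.1^3 / meshVolume(scaf) - 1), 0.03)
  # thin struts leave the core essentially void
  thin <- generateDiamondLattice(core, LatticeSpec(5, 0.15, 0.5), voxel = 0.1)
  expect_lt(meshVolume(thin) / meshVolume(core), 0.03)
  expect_error(generateDiamondLattice(core, LatticeSpec(25, 0.5, 0.5)), "cellSize")
})

test_that("strut radius solving hits the target porosity", {
  core <- cubeMesh(c(0, 0, 0), c(15, 15, 15))
  r <- solveStrutRadius(core, 2.5, 0.70, voxel = 0.12)
  expect_close(attr(r, "porosity"), 70, 0.5)
  expect_lt(attr(r, "iterations"), 31)
  # monotone: a higher porosity target needs a thinner strut
  r2 <- solveStrutRadius(core, 2.5, 0.80, voxel = 0.12)
  expect_lt(as.numeric(r2), as.numeric(r))
  expect_error(solveStrutRadius(core, 2.5, 0.9999, voxel = 0.2), "achievable")
  expect_error(solveStrutRadius(core, 2.5, 1.0), "targetPorosity")
})

test_that("pore diameter matches a fine-grid distance-transform oracle", {
  core <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  spec <- LatticeSpec(2.5, 0.35, 0.7)
  scaf <- generateDiamondLattice(core, spec, voxel = 0.1)
  pores <- measurePoreDiameter(scaf, core, nSamples = 5, seed = 2L)
  # oracle: exhaustive 0.05 mm grid over the interior, max clearance
  segs <- attr(scaf, "segments")
  n <- 121
  xs <- seq(2, 8, length.out = n)
  dmin <- cranioforge:::cpp_segments_dist_grid(segs, c(2, 2, 2), rep(0.05, 3),
                                               c(n, n, n), 3)
  oracle <- 2 * (max(dmin) - 0.35)
  expect_lt(abs(pores$mean / 1000 - oracle) / oracle, 0.10)
  # reproducible under a fixed seed
  again <- measurePoreDiameter(scaf, core, nSamples = 5, seed = 2L)
  expect_identical(pores$samples, again$samples)
  # vanishing struts open up cell-scale voids
  thin <- generateDiamondLattice(core, LatticeSpec(5, 0.15, 0.5), voxel = 0.12)
  big <- measurePoreDiameter(thin, core, nSamples = 3, seed = 3L)
  expect_gt(big$mean / 1000, 2.5)
})

test_that("screw holes are clean through-holes with the expected volume", {
  plate <- offsetShell(flatPatch(30, n = 12), 4)
  centers <- rbind(c(7, 7, 0), c(23, 7, 0), c(7, 23, 0), c(23, 23, 0))
  drilled <- addScrewHoles(plate, centers, 2, voxel = 0.15)
  expect_true(isWatertight(drilled))
  deficit <- meshVolume(plate) - meshVolume(drilled)
  expect_lt(abs(deficit / (4 * pi * 1^2 * 4) - 1), 0.05)
  # through-holes: the hole axis is free space end to end
  probes <- rbind(cbind(centers[, 1], centers[, 2], -2),
                  cbind(centers[, 1], centers[, 2], 2),
                  cbind(centers[, 1], centers[, 2], -6))
  inside <- cranioforge:::cpp_points_in_mesh(drilled@vertices, drilled@faces, probes)
  expect_false(any(inside))
  expect_identical(addScrewHoles(plate, centers, 0), plate)
  expect_error(addScrewHoles(plate, matrix(c(100, 100, 0), 1), 2), "away")
})
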