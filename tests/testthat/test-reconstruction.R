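# Mirror-reconstruction workflow: symmetry plane, split, mirror, wrap,
# boolean subtraction and the signed-volume measure.

test_that("midsagittal plane is recovered on the symmetric phantom", {
  ph <- smallPhantom()
  pl <- fitMidsagittalPlane(ph)
  ang <- acos(min(1, abs(sum(pl@normal * c(1, 0, 0))))) * 180 / pi
  expect_lt(ang, 0.1)
  expect_lt(abs(sum(pl@point * pl@normal)), 0.1)
})

test_that("plane fitting follows a rigid motion of the phantom", {
  ph <- smallPhantom()
  th <- 15 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th))) %*%
    rbind(c(cos(th / 2), -sin(th / 2), 0), c(sin(th / 2), cos(th / 2), 0), c(0, 0, 1))
  tr <- RigidTransform(R, c(4, -7, 2))
  moved <- applyTransform(tr, ph)
  pl <- fitMidsagittalPlane(moved)
  nTrue <- as.vector(R %*% c(1, 0, 0))
  ang <- acos(min(1, abs(sum(pl@normal * nTrue)))) * 180 / pi
  expect_lt(ang, 0.1)
  # the true plane passes through the transformed origin
  expect_lt(abs(sum((pl@point - tr@translation) * pl@normal)), 0.1)
})

test_that("a fully symmetric sphere yields a near-zero symmetry residual", {
  # residual is bounded by the facet sag of the tessellation (~0.005 mm at
  # this subdivision), i.e. zero at the resolution of the surface itself
  sp <- icosphereMesh(20, subdiv = 4)
  pl <- fitMidsagittalPlane(sp)
  expect_lt(attr(pl, "rms"), 0.01)
})

test_that("plane splitting conserves volume and caps both halves", {
  cube <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  halves <- splitByPlane(cube, Plane(c(5, 5, 5), c(1, 0, 0)), voxel = 0.25)
  expect_true(isWatertight(halves$positive))
  expect_lt(abs(meshVolume(halves$positive) - 500) / 500, 0.01)
  expect_lt(abs(meshVolume(halves$positive) + meshVolume(halves$negative) - 1000) /
              1000, 0.005)
  ph <- smallPhantom()
  hp <- splitByPlane(ph, Plane(c(0, 0, 0), c(1, 0, 0)), voxel = 0.4)
  tot <- meshVolume(hp$positive) + meshVolume(hp$negative)
  expect_lt(abs(tot / meshVolume(ph) - 1), 0.005)
  # plane that misses the solid: one empty half, flagged
  expect_message(out <- splitByPlane(cube, Plane(c(50, 0, 0), c(1, 0, 0)),
                                     voxel = 0.5), "empty")
  expect_equal(nFaces(out$positive), 0)
  expect_lt(abs(meshVolume(out$negative) - 1000) / 1000, 0.01)
})

test_that("mirroring is an involution that preserves orientation", {
  ph <- smallPhantom()
  pl <- Plane(c(2, 1, 0), c(0.6, 0.8, 0))
  twice <- mirrorMesh(mirrorMesh(ph, pl), pl)
  expect_lt(max(abs(twice@vertices - ph@vertices)), 1e-9)
  expect_close(meshVolume(mirrorMesh(ph, pl)), meshVolume(ph), 1e-6)
  p <- matrix(c(1, 2, 3), 1)
  m <- mirrorMesh(TriMesh(rbind(p, p + 1, p + 2), matrix(1:3, 1)),
                  Plane(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(as.vector(m@vertices[1, ]), c(-1, 2, 3))
})

test_that("merge + wrap reunites split halves and unions overlapping parts", {
  ph <- smallPhantom()
  pl <- Plane(c(0, 0, 0), c(1, 0, 0))
  halves <- splitByPlane(ph, pl, voxel = 0.4)
  merged <- mergeAndWrap(list(halves$positive, halves$negative), wrapVoxel = 0.6)
  expect_true(isWatertight(merged))
  expect_lt(abs(meshVolume(merged) / meshVolume(ph) - 1), 0.02)
  # near-identity on a single part
  solo <- mergeAndWrap(list(ph), wrapVoxel = 0.6)
  expect_lt(abs(meshVolume(solo) / meshVolume(ph) - 1), 0.01)
  # inclusion-exclusion on two overlapping cubes sharing half their volume
  a <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  b <- cubeMesh(c(5, 0, 0), c(15, 10, 10))
  u <- mergeAndWrap(list(a, b), wrapVoxel = 0.25, closingRadius = 0L)
  expect_lt(abs(meshVolume(u) - 1500) / 1500, 0.02)
})

test_that("boolean subtraction removes exactly the intersected volume", {
  a <- cubeMesh(c(0, 0, 0), c(20, 20, 20))
  b <- cubeMesh(c(5, 5, 5), c(15, 15, 15))
  d <- booleanSubtract(a, b, voxel = 0.25)
  expect_true(isWatertight(d))
  expect_lt(abs(meshVolume(d) - 7000) / 7000, 0.01)
  # disjoint subtrahend: unchanged
  far <- cubeMesh(c(100, 0, 0), c(110, 10, 10))
  same <- booleanSubtract(a, far, voxel = 0.5)
  expect_lt(abs(meshVolume(same) - 8000) / 8000, 0.01)
  # open meshes are rejected
  open <- TriMesh(a@vertices, a@faces[-1, , drop = FALSE])
  expect_error(booleanSubtract(open, b), "watertight")
})

test_that("signed mesh volume follows the divergence theorem", {
  cube <- cubeMesh()
  expect_equal(meshVolume(cube), 1.0)
  sp <- icosphereMesh(10, subdiv = 4)
  expect_lt(abs(meshVolume(sp) - 4 * pi * 1000 / 3) / (4 * pi * 1000 / 3), 0.005)
  inverted <- TriMesh(cube@vertices, cube@faces[, c(1, 3, 2)])
  expect_warning(v <- meshVolume(inverted), "inward")
  expect_equal(v, -1.0)
  open <- TriMesh(cube@vertices, cube@faces[-1, , drop = FALSE])
  expect_error(meshVolume(open), "not closed")
})

test_that("mirror reconstruction restores the clean phantom", {
  ph <- smallPhantom()
  rec <- smallRecon()
  dev <- meanOutwardDeviation(signedDeviation(rec$defectFree, ph, nSample = 10000))
  expect_lt(as.numeric(dev), 0.6) # below the wrap voxel used (0.6 mm)
  expect_true(isWatertight(rec$defectFree))
  # template volume is close to the carved-away wall volume
  deficit <- meshVolume(rec$defectFree) - meshVolume(smallDefective())
  expect_gt(meshVolume(rec$template), 0.5 * deficit)
  expect_lt(meshVolume(rec$template), 1.5 * deficit)
})
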