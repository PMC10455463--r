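# Finite-element verification: patch test, beam benchmark, meshing
# identities, bonded interfaces and the two-level refinement constraints.

uniformMats <- function(E = 3738, nu = 0.4) {
  list(skull = MaterialProps(E, nu, 99.9), implant = MaterialProps(E, nu, 99.9),
       screw = MaterialProps(E, nu, 99.9))
}

test_that("von Mises stress follows its invariants", {
  expect_equal(vonMises(diag(c(7, 7, 7))), 0)
  expect_equal(vonMises(diag(c(5, 0, 0))), 5)
  tau <- 3
  shear <- matrix(0, 3, 3); shear[1, 2] <- shear[2, 1] <- tau
  expect_close(vonMises(shear), sqrt(3) * tau, 1e-12)
  expect_close(vonMises(c(5, 0, 0, 0, 0, 0)), 5, 1e-12)
  expect_error(vonMises(matrix(1:9, 3, 3)), "symmetric")
})

test_that("a single unit voxel meshes into 6 tets of total volume 1", {
  cube <- cubeMesh(c(0, 0, 0), c(1, 1, 1))
  suppressWarnings(fem <- buildFEModel(cube, NULL, voxelSize = 1))
  expect_equal(nrow(fem@elements), 6L)
  vols <- cranioforge:::cpp_tet_volumes(fem@nodes, fem@elements)
  expect_true(all(vols > 0))
  expect_close(sum(vols), 1, 1e-12)
})

test_that("element volumes sum exactly to the voxelised volume", {
  cube <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  fem <- buildFEModel(cube, NULL, voxelSize = 2)
  vols <- cranioforge:::cpp_tet_volumes(fem@nodes, fem@elements)
  expect_lt(abs(sum(vols) - nrow(fem@elements) / 6 * 8) / sum(vols), 1e-12)
})

test_that("uniaxial patch test is exact to solver tolerance", {
  cube <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  fem <- buildFEModel(cube, NULL, voxelSize = 2)
  fem <- applyBCs(fem, fixedSlabHeight = 0.1, totalLoad = 50, loadArea = 1e9,
                  fixMode = "z-rollers")
  res <- solveLinearStatic(fem, uniformMats())
  expect_lt(max(abs(res@elementStress[, 3] + 0.5)), 1e-9)  # szz = -0.5 MPa
  expect_lt(max(abs(res@elementVonMises - 0.5)), 1e-9)
  top <- abs(fem@nodes[, 3] - 10) < 1e-9
  expect_lt(max(abs(res@displacements[top, 3] + 0.5 * 10 / 3738)), 1e-12)
  expect_lt(res@reactionResidual, 1e-9)
})

test_that("patch test stays exact across the two-level grid interface", {
  # same material on both sides of the refinement boundary: the hanging-node
  # constraints must reproduce the uniform strain field exactly
  skull <- cubeMesh(c(0, 0, 0), c(24, 24, 24))
  implant <- cubeMesh(c(8, 8, 8), c(16, 16, 16))
  fem <- buildFEModel(skull, implant, voxelSize = 2, refineMargin = 2)
  expect_gt(nrow(fem@constraints), 0)
  fem <- applyBCs(fem, fixedSlabHeight = 0.1, totalLoad = 100, loadArea = 1e9,
                  fixMode = "z-rollers", loadRegion = "any")
  res <- solveLinearStatic(fem, uniformMats())
  sigma <- 100 / 24^2
  expect_lt(max(abs(res@elementStress[, 3] + sigma)), 1e-8)
  expect_lt(max(abs(res@elementVonMises - sigma)) / sigma, 1e-6)
  expect_lt(res@reactionResidual, 1e-9)
})

test_that("cantilever deflection approaches the Euler-Bernoulli solution", {
  beam <- cubeMesh(c(0, 0, 0), c(100, 10, 10))
  fem <- buildFEModel(beam, NULL, voxelSize = 1)
  root <- which(abs(fem@nodes[, 1]) < 1e-9)
  tip <- which(abs(fem@nodes[, 1] - 100) < 1e-9)
  fem@fixedNodes <- as.integer(root)
  loads <- matrix(0, nrow(fem@nodes), 3)
  loads[tip, 3] <- -10 / length(tip)
  fem@loads <- loads
  res <- solveLinearStatic(fem, uniformMats())
  euler <- 10 * 100^3 / (3 * 3738 * (10 * 10^3 / 12))
  expect_lt(abs(mean(abs(res@displacements[tip, 3])) / euler - 1), 0.15)
  expect_lt(res@reactionResidual, 1e-6)
})

test_that("refining the voxel changes the benchmark deflection modestly", {
  # convergence is governed by elements through the section depth, so a
  # shorter span with the same cross-section keeps the check affordable
  solveBeam <- function(voxel) {
    beam <- cubeMesh(c(0, 0, 0), c(50, 10, 10))
    fem <- buildFEModel(beam, NULL, voxelSize = voxel)
    root <- which(abs(fem@nodes[, 1]) < 1e-9)
    tip <- which(abs(fem@nodes[, 1] - 50) < 1e-9)
    fem@fixedNodes <- as.integer(root)
    loads <- matrix(0, nrow(fem@nodes), 3)
    loads[tip, 3] <- -10 / length(tip)
    fem@loads <- loads
    res <- solveLinearStatic(fem, uniformMats())
    mean(abs(res@displacements[tip, 3]))
  }
  d1 <- solveBeam(1)
  d05 <- solveBeam(0.5)
  expect_lt(abs(d05 / d1 - 1), 0.10)
})

test_that("bonded regions share their interface nodes", {
  skull <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  implant <- cubeMesh(c(10, 0, 0), c(20, 10, 10))
  fem <- buildFEModel(skull, implant, voxelSize = 2, refine = FALSE)
  onPlane <- which(abs(fem@nodes[, 1] - 10) < 1e-9)
  usedBy <- function(region) {
    unique(as.vector(fem@elements[fem@elementRegion == region, ]))
  }
  expect_true(all(onPlane %in% usedBy(1L)))
  expect_true(all(onPlane %in% usedBy(2L)))
})

test_that("the load patch realises total force and target area", {
  plate <- cubeMesh(c(0, 0, 0), c(40, 40, 4))
  fem <- buildFEModel(plate, NULL, voxelSize = 1)
  fem <- applyBCs(fem, fixedSlabHeight = 0.1, totalLoad = 50, loadArea = 200)
  expect_lt(max(abs(colSums(fem@loads) - c(0, 0, -50))), 1e-9)
  expect_lt(abs(attr(fem@loads, "realizedArea") / 200 - 1), 0.10)
  # same total load over a doubled area: unchanged force sum
  fem2 <- applyBCs(fem, fixedSlabHeight = 0.1, totalLoad = 50, loadArea = 400)
  expect_lt(max(abs(colSums(fem2@loads) - c(0, 0, -50))), 1e-9)
})

test_that("a free-floating part is reported, not silently solved", {
  skull <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  floating <- cubeMesh(c(30, 0, 20), c(36, 6, 26))
  fem <- buildFEModel(skull, floating, voxelSize = 2, refine = FALSE)
  fem <- applyBCs(fem, fixedSlabHeight = 2, totalLoad = 10, loadArea = 1e9)
  expect_error(suppressWarnings(solveLinearStatic(fem, uniformMats())),
               "free-floating")
})

test_that("the FEA summary applies yield limits per region", {
  cube <- cubeMesh(c(0, 0, 0), c(10, 10, 10))
  fem <- buildFEModel(cube, NULL, voxelSize = 2)
  fem <- applyBCs(fem, fixedSlabHeight = 0.1, totalLoad = 50, loadArea = 1e9,
                  fixMode = "z-rollers")
  res <- solveLinearStatic(fem)
  s <- summarizeFEA(res, fem)
  expect_true(s$pass)
  expect_close(s$regions$safetyFactor[1], s$regions$yield[1] / res@maxVonMises, 1e-9)
  # zero load: zero state
  fem0 <- fem
  fem0@loads <- matrix(0, nrow(fem@nodes), 3)
  expect_warning(res0 <- solveLinearStatic(fem0), "zero")
  expect_equal(res0@maxVonMises, 0)
  expect_equal(res0@maxDisplacement, 0)
})
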