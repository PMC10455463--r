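# Shared fixtures, built once per test run and cached.  Unit tests use a
# small phantom (fast); the acceptance suite uses the full-size study
# conditions via helper-acceptance.R.

.fx <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# axis-aligned box as a watertight mesh
cubeMesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  TriMesh(v, f)
}

# solid icosphere of radius r
icosphereMesh <- function(r = 10, subdiv = 4) {
  ico <- cranioforge:::.icosphere(subdiv)
  TriMesh(ico$v * r, ico$f)
}

smallPhantomSpec <- function(asym = 0) {
  PhantomSpec(outerRadii = c(40, 32, 28), shellThickness = 5,
              asymmetryAmplitude = asym,
              defectCenter = c(-28, 6, 19), defectRadius = 14, seed = 7L)
}

smallPhantom <- function() .cached("smallPhantom", function() {
  makeSkullPhantom(smallPhantomSpec())
})

smallDefective <- function() .cached("smallDefective", function() {
  sp <- smallPhantomSpec()
  carveDefect(smallPhantom(), sp@defectCenter, sp@defectRadius, voxel = 0.5)
})

smallRecon <- function() .cached("smallRecon", function() {
  reconstructSkull(smallDefective(), plane = Plane(c(0, 0, 0), c(1, 0, 0)),
                   wrapVoxel = 0.6)
})

# flat square patch in the z = 0 plane, outward normal +z, n x n quads
flatPatch <- function(size = 10, n = 10, z = 0) {
  xs <- seq(0, size, length.out = n + 1)
  g <- as.matrix(expand.grid(x = xs, y = xs))
  v <- cbind(g, z)
  idx <- function(i, j) (j - 1) * (n + 1) + i
  f <- NULL
  for (j in 1:n) for (i in 1:n) {
    a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    f <- rbind(f, c(a, b, c), c(a, c, d))
  }
  TriMesh(v, f)
}

# flat disk patch of given radius in the z = 0 plane (fan + rings)
diskPatch <- function(radius = 30, nRings = 12, nSeg = 48) {
  v <- matrix(c(0, 0, 0), 1, 3)
  for (r in seq_len(nRings)) {
    rho <- radius * r / nRings
    th <- seq(0, 2 * pi, length.out = nSeg + 1)[-1]
    v <- rbind(v, cbind(rho * cos(th), rho * sin(th), 0))
  }
  ring <- function(r) if (r == 0) 1 else 1 + (r - 1) * nSeg + seq_len(nSeg)
  f <- NULL
  r1 <- ring(1)
  for (s in seq_len(nSeg)) # central fan
    f <- rbind(f, c(1, r1[s], r1[s %% nSeg + 1]))
  for (r in 2:nRings) {
    a <- ring(r - 1); b <- ring(r)
    for (s in seq_len(nSeg)) {
      s2 <- s %% nSeg + 1
      f <- rbind(f, c(a[s], b[s], b[s2]), c(a[s], b[s2], a[s2]))
    }
  }
  TriMesh(v, f)
}

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
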