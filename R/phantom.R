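# Synthetic skull phantom and simulators: every input the pipeline needs,
# with controlled ground truth.  The phantom is an ellipsoid shell rather
# than an anatomical skull: the design procedures depend only on bilateral
# symmetry and shell topology, and closed-form ellipsoid volumes give exact
# oracles.  Frame convention: x is the lateral axis (left < 0 < right), so
# the midsagittal plane is nominally x = 0; y antero-posterior; z vertical.

# unit icosphere with `subdiv` midpoint subdivisions; vertex set symmetric
# under reflection of any axis
.icosphere <- function(subdiv = 4) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)) + 1
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edgeKey <- function(a, b) ifelse(a < b, a * (nv + 1) + b, b * (nv + 1) + a)
    e1 <- edgeKey(f[, 1], f[, 2])
    e2 <- edgeKey(f[, 2], f[, 3])
    e3 <- edgeKey(f[, 3], f[, 1])
    allKeys <- c(e1, e2, e3)
    uk <- unique(allKeys)
    mid <- match(allKeys, uk)
    # midpoint coordinates per unique edge
    a <- c(f[, 1], f[, 2], f[, 3])
    b <- c(f[, 2], f[, 3], f[, 1])
    mcoord <- matrix(0, length(uk), 3)
    first <- !duplicated(mid)
    mcoord[mid[first], ] <- (v[a[first], ] + v[b[first], ]) / 2
    mcoord <- mcoord / sqrt(rowSums(mcoord^2))
    m1 <- nv + mid[seq_len(nrow(f))]
    m2 <- nv + mid[nrow(f) + seq_len(nrow(f))]
    m3 <- nv + mid[2 * nrow(f) + seq_len(nrow(f))]
    v <- rbind(v, mcoord)
    f <- rbind(cbind(f[, 1], m1, m3), cbind(m1, f[, 2], m2),
               cbind(m3, m2, f[, 3]), cbind(m1, m2, m3))
  }
  storage.mode(f) <- "integer"
  list(v = v, f = f)
}

# smooth one-sided window: 1 on the deep-left side, 0 for x >= 0
.leftWindow <- function(x, width = 10) {
  s <- pmin(pmax(-x / width, 0), 1)
  s * s * (3 - 2 * s)
}

#' Generate the synthetic skull phantom
#'
#' A watertight two-surface ellipsoid shell (outer ellipsoid minus a
#' concentric inner ellipsoid offset by the shell thickness), with an
#' optional smooth random bump field restricted to the left (x < 0) side.
#' With zero asymmetry the mesh is exactly mirror-symmetric about x = 0.
#'
#' @param spec a [PhantomSpec-class]
#' @param subdiv icosphere subdivisions per surface (default 4: 5120
#'   faces/surface, volume within ~0.1% of the closed form)
#' @return watertight [TriMesh-class] (outer surface outward-oriented)
#' @export
makeSkullPhantom <- function(spec, subdiv = 4) {
  validObject(spec)
  ico <- .icosphere(subdiv)
  radiiOut <- spec@outerRadii
  radiiIn <- spec@outerRadii - spec@shellThickness
  vOut <- sweep(ico$v, 2, radiiOut, "*")
  vIn <- sweep(ico$v, 2, radiiIn, "*")
  if (spec@asymmetryAmplitude > 0) {
    bump <- .withSeed(spec@seed, {
      nb <- 12
      centers <- matrix(rnorm(nb * 3), nb, 3)
      centers <- centers / sqrt(rowSums(centers^2))
      centers[, 1] <- -abs(centers[, 1]) # left side only
      coefs <- rnorm(nb)
      list(centers = centers, coefs = coefs, sigma = 0.35)
    })
    fieldAt <- function(v, radii) {
      unit <- v / sqrt(rowSums(sweep(v, 2, radii, "/")^2) + 1e-30)
      u <- sweep(v, 2, radii, "/")
      g <- numeric(nrow(v))
      for (i in seq_len(nrow(bump$centers))) {
        d2 <- rowSums(sweep(u, 2, bump$centers[i, ])^2)
        g <- g + bump$coefs[i] * exp(-d2 / (2 * bump$sigma^2))
      }
      g * .leftWindow(v[, 1])
    }
    gOut <- fieldAt(vOut, radiiOut)
    gIn <- fieldAt(vIn, radiiIn)
    scale <- spec@asymmetryAmplitude / max(sqrt(mean(gOut^2)), 1e-12)
    # displace along the outward surface normal direction of the ellipsoid
    nrmDir <- function(v, radii) {
      n <- sweep(v, 2, radii^2, "/")
      n / sqrt(rowSums(n^2))
    }
    vOut <- vOut + (scale * gOut) * nrmDir(vOut, radiiOut)
    vIn <- vIn + (scale * gIn) * nrmDir(vIn, radiiIn)
  }
  nv <- nrow(vOut)
  fOut <- ico$f
  fIn <- ico$f[, c(1, 3, 2)] + nv # reversed: inner surface faces inward
  mesh <- TriMesh(rbind(vOut, vIn), rbind(fOut, fIn))
  if (cpp_mesh_volume(mesh@vertices, mesh@faces) < 0)
    mesh@faces <- mesh@faces[, c(1, 3, 2)]
  mesh
}

#' Voxelize a solid into a CT-like image volume
#'
#' Voxels whose centres fall inside the mesh receive `boneHU`, all others
#' `backgroundHU`, plus optional Gaussian noise -- the inverse of the
#' segmentation path, with defaults giving a realistic bone/air contrast.
#'
#' @param mesh watertight [TriMesh-class]
#' @param spacing voxel pitch (mm, isotropic or length 3)
#' @param boneHU,backgroundHU,noiseSD intensity model (HU)
#' @param seed RNG seed for the noise
#' @param margin air margin around the mesh bbox (mm)
#' @return an [ImageVolume-class]
#' @export
voxelizeToCT <- function(mesh, spacing = 0.6, boneHU = 1200, backgroundHU = -1000,
                         noiseSD = 30, seed = 1L, margin = 5) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  .requireWatertight(mesh, "mesh")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  bb <- .meshBBox(mesh)
  origin <- bb$min - margin
  dims <- as.integer(ceiling((bb$max - bb$min + 2 * margin) / spacing)) + 1L
  inside <- cpp_inside_grid(mesh@vertices, mesh@faces, origin, spacing, dims)
  intens <- ifelse(inside, boneHU, backgroundHU)
  if (noiseSD > 0)
    intens <- intens + .withSeed(seed, rnorm(length(intens), 0, noiseSD))
  ImageVolume(array(intens, dim = dims), spacing = spacing, origin = origin)
}

#' Carve a spherical segmental defect out of a skull
#'
#' Boolean difference skull minus sphere, evaluated as a signed-field CSG
#' on a voxel grid.  Errors when the ball does not reach the shell at all
#' (a silent no-op would invalidate downstream comparisons).
#'
#' @param skull watertight [TriMesh-class]
#' @param center,radius defect ball (mm)
#' @param voxel boolean grid pitch (mm)
#' @return defective skull [TriMesh-class]
#' @export
carveDefect <- function(skull, center, radius, voxel = 0.5) {
  .requireWatertight(skull, "skull")
  if (radius <= 0) stop("radius must be positive")
  center <- .assertNumeric3(center, "center")
  sd0 <- distanceToMesh(matrix(center, 1), skull, signed = TRUE)$distance
  if (sd0 >= radius)
    stop("defect ball does not intersect the skull (surface distance ",
         sprintf("%.2f", sd0), " mm >= radius)")
  grid <- .gridForMeshes(list(skull), voxel)
  f <- pmax(.meshField(skull, grid), radius - .sphereField(grid, center, 0))
  .fieldMesh(f, grid)
}

#' Simulate the manufacturing of a designed implant
#'
#' Displaces vertices outward along their normals by a smooth random field
#' (Gaussian bumps with the given correlation length), scaled so the
#' area-weighted mean displacement equals `amplitude` -- the known ground
#' truth that the fitting-accuracy stage must recover as its manufacturing
#' component.
#'
#' @param designed watertight [TriMesh-class]
#' @param amplitude target mean outward displacement (mm); 0 returns the
#'   input unchanged
#' @param correlationLength bump length scale (mm)
#' @param seed RNG seed
#' @return the "fabricated" [TriMesh-class]; attributes `meanDisplacement`
#'   and `rmsDisplacement` record the realised field statistics
#' @export
simulateManufacturing <- function(designed, amplitude, correlationLength = 15,
                                  seed = 1L) {
  .requireWatertight(designed, "designed")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(designed)
  v <- designed@vertices
  nrm <- .vertexNormals(designed)
  centers <- sampleSurface(designed, max(24L, ceiling(surfaceArea(designed) /
                                                        correlationLength^2)),
                           seed = seed)
  coefs <- .withSeed(seed + 1L, rnorm(nrow(centers)))
  g <- numeric(nrow(v))
  for (i in seq_len(nrow(centers))) {
    d2 <- (v[, 1] - centers[i, 1])^2 + (v[, 2] - centers[i, 2])^2 +
      (v[, 3] - centers[i, 3])^2
    g <- g + coefs[i] * exp(-d2 / (2 * correlationLength^2))
  }
  disp <- abs(g)
  # area weights: one third of incident face areas per vertex
  fg <- .faceGeometry(designed)
  w <- numeric(nrow(v))
  for (k in 1:3) w <- w + tapplySum(fg$area / 3, designed@faces[, k], nrow(v))
  scale <- amplitude / sum(w * disp) * sum(w)
  disp <- disp * scale
  out <- TriMesh(v + disp * nrm, designed@faces, designed@faceTags)
  attr(out, "meanDisplacement") <- sum(w * disp) / sum(w)
  attr(out, "rmsDisplacement") <- sqrt(sum(w * disp^2) / sum(w))
  out
}

#' Simulate a surface scan as a noisy, rigidly transformed point cloud
#'
#' Area-uniform surface samples with isotropic Gaussian noise, then moved
#' by `pose` -- the stand-in for an articulated-arm laser scan.
#'
#' @param mesh the scanned surface
#' @param pointsPerMm2 sampling density (> 0)
#' @param noiseSD isotropic noise (mm)
#' @param pose a [RigidTransform-class]
#' @param seed RNG seed
#' @return n x 3 point matrix
#' @export
simulateScan <- function(mesh, pointsPerMm2 = 2, noiseSD = 0.05,
                         pose = RigidTransform(), seed = 1L) {
  if (pointsPerMm2 <= 0) stop("pointsPerMm2 must be positive")
  n <- ceiling(surfaceArea(mesh) * pointsPerMm2)
  pts <- sampleSurface(mesh, n, seed = seed)
  if (noiseSD > 0)
    pts <- pts + .withSeed(seed + 1L, matrix(rnorm(3 * n, 0, noiseSD), n, 3))
  applyTransform(pose, unclass(pts)[seq_len(n), , drop = FALSE])
}

#' Simulate an expert VAS score table
#'
#' Integer 1..5 scores from a discretised, clipped normal distribution.
#'
#' @param nExperts,nReplicates table dimensions
#' @param mean,sd target score distribution (1 <= mean <= 5, sd >= 0)
#' @param seed RNG seed
#' @return integer matrix, experts x replicates
#' @export
simulateVAS <- function(nExperts = 10, nReplicates = 5, mean = 3.66, sd = 0.5,
                        seed = 1L) {
  if (nExperts < 1 || nReplicates < 1) stop("table must be at least 1 x 1")
  if (sd < 0) stop("sd must be >= 0")
  if (mean < 1 || mean > 5) stop("mean must lie in [1, 5]")
  raw <- .withSeed(seed, rnorm(nExperts * nReplicates, mean, sd))
  scores <- matrix(as.integer(round(pmin(5, pmax(1, raw)))), nExperts, nReplicates)
  scores
}
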