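# Mirror-reconstruction design workflow: fit the midsagittal plane, split
# the defective skull, mirror the healthy half, merge + wrap into a
# defect-free model, and boolean-subtract to obtain the implant template.

# least-squares rigid motion (Kabsch) mapping P onto Q
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  list(R = R, t = t)
}

#' Fit the midsagittal (symmetry) plane of a roughly bilateral mesh
#'
#' Initialises from the principal axis closest to `initNormal`, then
#' refines by registering the mesh to its own reflection (trimmed
#' iterative-closest-point, so a unilateral defect does not bias the
#' plane).  The returned plane is the fixed plane of the converged
#' reflection.
#'
#' @param mesh a [TriMesh-class]
#' @param initNormal approximate lateral direction (default world x)
#' @param nSamples surface samples driving the registration
#' @param maxIter,tol iteration controls
#' @param trim fraction of best-matching samples kept each iteration
#' @param warnResidual warn when the final RMS symmetry residual (mm)
#'   exceeds this bound
#' @param seed RNG seed for the sampling
#' @return a [Plane-class]; attributes `rms` (final residual) and
#'   `iterations`
#' @export
fitMidsagittalPlane <- function(mesh, initNormal = c(1, 0, 0), nSamples = 3000,
                                maxIter = 30, tol = 1e-9, trim = 0.9,
                                warnResidual = 1.0, seed = 1L) {
  pts <- sampleSurface(mesh, nSamples, seed = seed)
  pts <- unclass(pts)[seq_len(nrow(pts)), , drop = FALSE]
  pca <- prcomp(pts)
  cosines <- abs(as.vector(t(pca$rotation) %*% (initNormal / sqrt(sum(initNormal^2)))))
  n <- pca$rotation[, which.max(cosines)]
  if (sum(n * initNormal) < 0) n <- -n
  p0 <- colMeans(pts)
  qh <- cpp_mesh_query_build(mesh@vertices, mesh@faces)
  faceNormals <- .faceGeometry(mesh)$normal
  iterations <- 0L
  prevRms <- Inf
  for (it in seq_len(maxIter)) {
    iterations <- it
    H <- diag(3) - 2 * tcrossprod(n)
    h <- 2 * sum(p0 * n) * n
    refl <- sweep(pts %*% t(H), 2, h, "+")
    cp <- cpp_mesh_query(qh, refl)
    keep <- cp$distance <= stats::quantile(cp$distance, trim)
    r <- refl[keep, , drop = FALSE]
    q <- cp$point[keep, , drop = FALSE]
    m <- faceNormals[cp$face[keep], , drop = FALSE]
    # point-to-plane update: small rigid correction (omega, t) applied to
    # the reflected points, minimising sum (e + m.(omega x r + t))^2
    e <- rowSums(m * (r - q))
    J <- cbind(r[, 2] * m[, 3] - r[, 3] * m[, 2],
               r[, 3] * m[, 1] - r[, 1] * m[, 3],
               r[, 1] * m[, 2] - r[, 2] * m[, 1],
               m)
    x <- tryCatch(solve(crossprod(J) + 1e-12 * diag(6), -crossprod(J, e)),
                  error = function(err) rep(0, 6))
    omega <- x[1:3]
    tcorr <- x[4:6]
    th <- sqrt(sum(omega^2))
    Rm <- if (th < 1e-14) diag(3) else {
      k <- omega / th
      K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    A <- Rm %*% H
    b <- as.vector(Rm %*% h) + as.vector(tcorr)
    eg <- eigen(A)
    pick <- which.min(Re(eg$values))
    nNew <- Re(eg$vectors[, pick])
    nNew <- nNew / sqrt(sum(nNew^2))
    if (sum(nNew * n) < 0) nNew <- -nNew
    n <- nNew
    p0 <- (sum(nNew * b) / 2) * nNew
    rms <- sqrt(mean(e^2))
    if (abs(prevRms - rms) < tol) break
    prevRms <- rms
  }
  H <- diag(3) - 2 * tcrossprod(n)
  refl <- sweep(pts %*% t(H), 2, 2 * sum(p0 * n) * n, "+")
  res <- cpp_mesh_query(qh, refl)$distance
  rms <- sqrt(mean(sort(res)[seq_len(floor(trim * length(res)))]^2))
  if (rms > warnResidual)
    warning(sprintf("symmetry residual %.3f mm exceeds %.3f mm; mesh may not be bilateral",
                    rms, warnResidual))
  out <- Plane(p0, n)
  attr(out, "rms") <- rms
  attr(out, "iterations") <- iterations
  out
}

#' Split a watertight solid by a plane into two capped solids
#'
#' Signed-field CSG: each half is the intersection of the solid with one
#' half-space, so the cap surfaces coincide and the two volumes sum to the
#' input volume at the grid's accuracy.
#'
#' @param mesh watertight [TriMesh-class]
#' @param plane a [Plane-class]
#' @param voxel grid pitch (mm)
#' @return list with `positive` and `negative` [TriMesh-class] halves (the
#'   side the plane normal points into is "positive"); empty halves are
#'   flagged with a message
#' @export
splitByPlane <- function(mesh, plane, voxel = 0.4) {
  .requireWatertight(mesh, "mesh")
  grid <- .gridForMeshes(list(mesh), voxel)
  f <- .meshField(mesh, grid)
  p <- .planeField(grid, plane)
  pos <- .fieldMesh(pmax(f, -p), grid)
  neg <- .fieldMesh(pmax(f, p), grid)
  if (nFaces(pos) == 0 || nFaces(neg) == 0)
    message("splitByPlane: one side is empty (plane misses the mesh)")
  list(positive = pos, negative = neg)
}

#' Mirror a mesh across a plane
#'
#' Exact vertex reflection with face winding re-inverted, so outward
#' orientation (and signed volume) is preserved; an involution.
#'
#' @param mesh a [TriMesh-class]
#' @param plane a [Plane-class]
#' @return mirrored [TriMesh-class]
#' @export
mirrorMesh <- function(mesh, plane) {
  n <- plane@normal
  d <- as.vector(mesh@vertices %*% n) - sum(plane@point * n)
  v <- mesh@vertices - 2 * outer(d, n)
  TriMesh(v, mesh@faces[, c(1, 3, 2), drop = FALSE], mesh@faceTags)
}

#' Union + wrap a set of parts into a single watertight shell
#'
#' Boolean union on a common signed-field grid followed by a grayscale
#' morphological closing of one voxel radius (the "wrap"), removing the
#' voids and gaps left where parts abut.
#'
#' @param parts list of watertight [TriMesh-class] parts
#' @param wrapVoxel grid pitch of the wrap (mm)
#' @param closingRadius closing radius in voxels
#' @return a [TriMesh-class]; if the result has several connected
#'   components (disjoint parts) it is returned with a warning
#' @export
mergeAndWrap <- function(parts, wrapVoxel = 0.8, closingRadius = 1L) {
  if (!length(parts)) stop("no parts to merge")
  for (p in parts) .requireWatertight(p, "part")
  grid <- .gridForMeshes(parts, wrapVoxel, marginVoxels = 3 + closingRadius)
  f <- Reduce(pmin, lapply(parts, .meshField, grid = grid))
  if (closingRadius > 0) {
    f <- cpp_box_morph(f, grid$dims, as.integer(closingRadius), 0L) # dilate
    f <- cpp_box_morph(f, grid$dims, as.integer(closingRadius), 1L) # erode
  }
  out <- .fieldMesh(f, grid)
  comp <- meshComponents(out)
  if (max(comp) > 2) # a closed shell has 2 surface components (outer + inner)
    warning("wrapped result has ", max(comp), " surface components; parts may be disjoint")
  out
}

#' Boolean difference of two watertight solids
#'
#' Signed-field CSG `a` minus `b` on a voxel grid.  `clearance` enlarges
#' `b` slightly before subtraction -- the standard cut tolerance that
#' prevents paper-thin shells where surfaces of `a` and `b` coincide (as
#' they do when subtracting a defective skull from its reconstruction).
#'
#' @param a,b watertight [TriMesh-class] solids
#' @param voxel grid pitch (mm)
#' @param clearance cut tolerance (mm)
#' @param keep "all" components or "largest" only
#' @return a [TriMesh-class]
#' @export
booleanSubtract <- function(a, b, voxel = 0.4, clearance = 0, keep = c("all", "largest")) {
  keep <- match.arg(keep)
  .requireWatertight(a, "a")
  .requireWatertight(b, "b")
  grid <- .gridForMeshes(list(a), voxel)
  fa <- .meshField(a, grid)
  fb <- .meshField(b, grid)
  out <- .fieldMesh(pmax(fa, clearance - fb), grid)
  if (keep == "largest" && nFaces(out) > 0) {
    comp <- meshComponents(out)
    # keep the component enclosing the largest volume (selected by face set)
    vols <- vapply(seq_len(max(comp)), function(k) {
      sub <- .subMesh(out, comp == k)
      abs(cpp_mesh_volume(sub@vertices, sub@faces))
    }, numeric(1))
    out <- .subMesh(out, comp == which.max(vols))
  }
  out
}

#' Mirror-reconstruct a defect-free skull from a defective one
#'
#' The complete design workflow: fit (or accept) the midsagittal plane,
#' split, drop the defective half, mirror the healthy half, merge + wrap,
#' and boolean-subtract the defective skull to obtain the implant template.
#'
#' @param defective watertight defective-skull [TriMesh-class]
#' @param plane optional user-supplied midsagittal [Plane-class]; fitted
#'   when `NULL`
#' @param wrapVoxel grid pitch of the reconstruction (mm); it bounds the
#'   geometric error of the whole chain
#' @param healthySide "auto" picks the half with the larger volume
#' @param clearance cut tolerance of the final boolean subtraction (mm)
#' @return list: `plane`, `defectFree` (wrapped skull), `template` (implant
#'   template solid, largest component), `healthySide`
#' @export
reconstructSkull <- function(defective, plane = NULL, wrapVoxel = 0.8,
                             healthySide = c("auto", "positive", "negative"),
                             clearance = 0.05) {
  healthySide <- match.arg(healthySide)
  .requireWatertight(defective, "defective")
  if (is.null(plane)) plane <- fitMidsagittalPlane(defective)
  # the whole split / mirror / merge+wrap / subtract chain runs as CSG on
  # one signed-distance grid: one surface sampling, then array operations,
  # which keeps the many-million-triangle intermediate meshes off the path
  grid <- .gridForMeshes(list(defective), wrapVoxel, marginVoxels = 4)
  band <- 3 * wrapVoxel
  f <- .meshField(defective, grid, band = band)
  p <- .planeField(grid, plane)
  if (healthySide == "auto") {
    vpos <- sum(f < 0 & p > 0)
    vneg <- sum(f < 0 & p < 0)
    healthySide <- if (vpos >= vneg) "positive" else "negative"
  }
  s <- if (healthySide == "positive") 1 else -1
  fHealthy <- pmax(f, -s * p)
  # reflection across the plane: x' = H x + h
  n <- plane@normal
  H <- diag(3) - 2 * tcrossprod(n)
  h <- 2 * sum(plane@point * n) * n
  fMirror <- cpp_resample_affine(fHealthy, grid$dims, grid$origin, grid$spacing,
                                 H, h, band)
  fUnion <- pmin(fHealthy, fMirror)
  # wrap: grayscale morphological closing, one voxel radius
  fClosed <- cpp_box_morph(fUnion, grid$dims, 1L, 0L)
  fClosed <- cpp_box_morph(fClosed, grid$dims, 1L, 1L)
  defectFree <- .fieldMesh(fClosed, grid)
  fTemplate <- pmax(fClosed, clearance - f)
  template <- .fieldMesh(fTemplate, grid)
  if (nFaces(template) > 0) {
    comp <- meshComponents(template)
    if (max(comp) > 1) {
      vols <- vapply(seq_len(max(comp)), function(k) {
        sub <- .subMesh(template, comp == k)
        abs(cpp_mesh_volume(sub@vertices, sub@faces))
      }, numeric(1))
      template <- .subMesh(template, comp == which.max(vols))
    }
  }
  list(plane = plane, defectFree = defectFree, template = template,
       healthySide = healthySide)
}
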