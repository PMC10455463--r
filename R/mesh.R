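# TriMesh methods and general mesh utilities.

#' @rdname cranioforge-generics
#' @export
setMethod("vertices", "TriMesh", function(x) x@vertices)

#' @rdname cranioforge-generics
#' @export
setMethod("faces", "TriMesh", function(x) x@faces)

#' @rdname cranioforge-generics
#' @export
setMethod("nVertices", "TriMesh", function(x) nrow(x@vertices))

#' @rdname cranioforge-generics
#' @export
setMethod("nFaces", "TriMesh", function(x) nrow(x@faces))

#' @rdname cranioforge-generics
#' @export
setMethod("surfaceArea", "TriMesh", function(x) cpp_mesh_area(x@vertices, x@faces))

#' @rdname cranioforge-generics
#' @export
setMethod("isWatertight", "TriMesh", function(x) {
  audit <- cpp_edge_audit(x@faces)
  isTRUE(audit$closed) && isTRUE(audit$oriented)
})

#' @rdname meshVolume
#' @export
setMethod("meshVolume", "TriMesh", function(x, ...) {
  audit <- cpp_edge_audit(x@faces)
  if (!isTRUE(audit$closed))
    stop("mesh is not closed (", audit$n_boundary_edges, " boundary edges); ",
         "volume is undefined")
  v <- cpp_mesh_volume(x@vertices, x@faces)
  if (v < 0) warning("mesh is inward-oriented (negative signed volume)")
  v
})

setMethod("show", "TriMesh", function(object) {
  bb <- apply(object@vertices, 2, range)
  cat(sprintf("TriMesh: %d vertices, %d faces\n", nrow(object@vertices),
              nrow(object@faces)))
  cat(sprintf("  bbox [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  if (length(object@faceTags))
    cat("  face tags:", paste(sort(unique(object@faceTags)), collapse = ", "), "\n")
})

#' Drop unreferenced vertices (and optionally degenerate faces)
#'
#' @param mesh a [TriMesh-class]
#' @param dropDegenerate remove faces with repeated vertex indices
#' @return cleaned [TriMesh-class]
#' @export
cleanMesh <- function(mesh, dropDegenerate = TRUE) {
  f <- mesh@faces
  tags <- mesh@faceTags
  if (dropDegenerate && nrow(f) > 0) {
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[keep, , drop = FALSE]
    if (length(tags)) tags <- tags[keep]
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  f2 <- matrix(remap[f], ncol = 3)
  storage.mode(f2) <- "integer"
  TriMesh(mesh@vertices[used, , drop = FALSE], f2, tags)
}

#' Per-face areas, normals and centroids
#' @keywords internal
.faceGeometry <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  nrm <- cr / pmax(area2, 1e-30)
  list(area = area2 / 2, normal = nrm, centroid = (a + b + c_) / 3)
}

#' Angle-agnostic per-vertex normals (area weighted)
#' @keywords internal
.vertexNormals <- function(mesh) {
  fg <- .faceGeometry(mesh)
  n <- matrix(0, nrow(mesh@vertices), 3)
  f <- mesh@faces
  w <- fg$normal * fg$area
  for (k in 1:3) {
    n[, 1] <- n[, 1] + tapplySum(w[, 1], f[, k], nrow(n))
    n[, 2] <- n[, 2] + tapplySum(w[, 2], f[, k], nrow(n))
    n[, 3] <- n[, 3] + tapplySum(w[, 3], f[, k], nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-30)
}

# fast grouped sum into a fixed-length vector
tapplySum <- function(x, index, n) {
  out <- numeric(n)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Area-uniform random samples on a mesh surface
#'
#' @param mesh a [TriMesh-class]
#' @param n number of points
#' @param seed optional RNG seed (isolated from the caller's stream)
#' @return n x 3 matrix of surface points; the source face index is
#'   attached as attribute `"face"`
#' @export
sampleSurface <- function(mesh, n, seed = NULL) {
  .withSeed(seed, {
    fg <- .faceGeometry(mesh)
    cw <- cumsum(fg$area)
    fidx <- findInterval(runif(n) * cw[length(cw)], cw) + 1L
    r1 <- sqrt(runif(n))
    r2 <- runif(n)
    f <- mesh@faces
    a <- mesh@vertices[f[fidx, 1], , drop = FALSE]
    b <- mesh@vertices[f[fidx, 2], , drop = FALSE]
    c_ <- mesh@vertices[f[fidx, 3], , drop = FALSE]
    p <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    attr(p, "face") <- fidx
    p
  })
}

#' Distance from points to a mesh surface
#'
#' Unsigned distance, closest surface point and face index for each query
#' point; `signed = TRUE` negates distances for points inside the (closed)
#' mesh, using an exact ray-parity test.
#'
#' @param points n x 3 matrix
#' @param mesh a [TriMesh-class]
#' @param signed return signed distances (negative inside)
#' @return list with `distance`, `face`, `point` (and `inside` when signed)
#' @export
distanceToMesh <- function(points, mesh, signed = FALSE) {
  points <- as.matrix(points)
  res <- cpp_points_to_mesh(mesh@vertices, mesh@faces, points)
  if (signed) {
    inside <- cpp_points_in_mesh(mesh@vertices, mesh@faces, points)
    res$distance <- ifelse(inside, -res$distance, res$distance)
    res$inside <- inside
  }
  res
}

#' Symmetric Hausdorff distance estimate between two surfaces
#'
#' Sampled approximation: max over dense surface samples of the
#' point-to-surface distance, in both directions.
#'
#' @param meshA,meshB [TriMesh-class] objects
#' @param n samples per direction
#' @param seed RNG seed for the sampling
#' @return distance (mm)
#' @export
hausdorffDistance <- function(meshA, meshB, n = 5000, seed = 1) {
  pa <- rbind(sampleSurface(meshA, n, seed = seed), meshA@vertices)
  pb <- rbind(sampleSurface(meshB, n, seed = seed + 1), meshB@vertices)
  dab <- cpp_points_to_mesh(meshB@vertices, meshB@faces, pa)$distance
  dba <- cpp_points_to_mesh(meshA@vertices, meshA@faces, pb)$distance
  max(c(dab, dba))
}

#' Connected components of a mesh
#'
#' @param mesh a [TriMesh-class]
#' @return integer vector, per-face component id (1 = largest)
#' @export
meshComponents <- function(mesh) {
  cpp_mesh_components(mesh@faces, nrow(mesh@vertices))
}

#' Keep selected faces of a mesh as a (possibly open) submesh
#' @keywords internal
.subMesh <- function(mesh, faceSel) {
  tags <- if (length(mesh@faceTags)) mesh@faceTags[faceSel] else integer(0)
  cleanMesh(TriMesh(mesh@vertices, mesh@faces[faceSel, , drop = FALSE], tags),
            dropDegenerate = FALSE)
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"), function(transform, x) {
  sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "TriMesh"), function(transform, x) {
  TriMesh(applyTransform(transform, x@vertices), x@faces, x@faceTags)
})

#' Compose and invert rigid transforms
#'
#' `composeTransform(a, b)` returns the transform applying `b` first, then
#' `a`; `invertTransform(a)` the inverse motion.
#'
#' @param a,b [RigidTransform-class] objects
#' @return a [RigidTransform-class]
#' @export
composeTransform <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.vector(a@rotation %*% b@translation) + a@translation)
}

#' @rdname composeTransform
#' @export
invertTransform <- function(a) {
  RigidTransform(t(a@rotation), as.vector(-t(a@rotation) %*% a@translation))
}

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2], object@translation[3]))
})
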