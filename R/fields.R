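# Implicit-solid machinery: solids as signed scalar fields (negative inside)
# sampled on regular node grids, combined by min/max CSG and meshed back by
# marching tetrahedra.  This is the voxel boolean backend used by the
# reconstruction and implant-design stages; its accuracy is set by the grid
# pitch (sub-voxel via linear interpolation on exact narrow-band distances).

# grid descriptor: origin (node 0 position), spacing (scalar), dims (nodes).
# The origin is dithered by a fixed irrational sub-voxel offset so that flat
# faces of analytically placed solids never coincide with lattice planes
# (exact zeros on nodes degrade the isosurface to non-manifold pinches).
.makeGrid <- function(bboxMin, bboxMax, voxel, marginVoxels = 3) {
  dither <- c(0.3819660113, 0.2360679775, 0.1458980338) * voxel
  origin <- bboxMin - marginVoxels * voxel - dither
  dims <- ceiling((bboxMax - bboxMin + dither) / voxel) + 2 * marginVoxels + 1
  list(origin = as.numeric(origin), spacing = rep(voxel, 3), dims = as.integer(dims),
       voxel = voxel)
}

.meshBBox <- function(mesh) {
  rng <- apply(mesh@vertices, 2, range)
  list(min = rng[1, ], max = rng[2, ])
}

.gridForMeshes <- function(meshes, voxel, marginVoxels = 3) {
  bb <- lapply(meshes, .meshBBox)
  lo <- do.call(pmin, lapply(bb, `[[`, "min"))
  hi <- do.call(pmax, lapply(bb, `[[`, "max"))
  .makeGrid(lo, hi, voxel, marginVoxels)
}

# signed distance samples of a closed mesh on a grid (narrow band = 3 voxels)
.meshField <- function(mesh, grid, band = 3 * grid$voxel) {
  cpp_sdf_grid(mesh@vertices, mesh@faces, grid$origin, grid$spacing, grid$dims, band)
}

# node world coordinates as an n x 3 matrix (i fastest, matching array layout)
.gridNodes <- function(grid) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  cbind(rep.int(grid$origin[1] + (0:(nx - 1)) * grid$spacing[1], ny * nz),
        rep.int(rep(grid$origin[2] + (0:(ny - 1)) * grid$spacing[2], each = nx), nz),
        rep(grid$origin[3] + (0:(nz - 1)) * grid$spacing[3], each = nx * ny))
}

# signed distance (x - p) . n to a plane, sampled on the grid; callers build
# half-space fields from +/- this
.planeField <- function(grid, plane) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  gx <- grid$origin[1] + (0:(nx - 1)) * grid$spacing[1]
  gy <- grid$origin[2] + (0:(ny - 1)) * grid$spacing[2]
  gz <- grid$origin[3] + (0:(nz - 1)) * grid$spacing[3]
  n <- plane@normal
  d0 <- sum(plane@point * n)
  fx <- gx * n[1]
  fy <- gy * n[2]
  fz <- gz * n[3]
  as.vector(outer(outer(fx, fy, "+"), fz, "+")) - d0
}

# analytic sphere field (negative inside), separable evaluation
.sphereField <- function(grid, center, radius) {
  dx2 <- (grid$origin[1] + (0:(grid$dims[1] - 1)) * grid$spacing[1] - center[1])^2
  dy2 <- (grid$origin[2] + (0:(grid$dims[2] - 1)) * grid$spacing[2] - center[2])^2
  dz2 <- (grid$origin[3] + (0:(grid$dims[3] - 1)) * grid$spacing[3] - center[3])^2
  as.vector(sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))) - radius
}

# capped-cylinder field (negative inside); axis through `base` along unit `axis`
.cylinderField <- function(grid, base, axis, radius, halfLength) {
  nodes <- .gridNodes(grid)
  rel <- sweep(nodes, 2, base)
  t <- as.vector(rel %*% axis)
  rad2 <- rowSums(rel^2) - t^2
  dr <- sqrt(pmax(rad2, 0)) - radius
  dz <- abs(t) - halfLength
  # SDF of a capped cylinder
  outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
  inside <- pmin(pmax(dr, dz), 0)
  outside + inside
}

# mesh a field at level 0 (the mesher already compacts its vertex set)
.fieldMesh <- function(field, grid) {
  mt <- cpp_marching_tets(field, grid$dims, grid$origin, grid$spacing, 0)
  TriMesh(mt$vertices, mt$faces)
}

#' Remesh a solid on a voxel grid
#'
#' Samples the signed distance field of a watertight mesh on a regular grid
#' and re-extracts the isosurface.  Used internally by the boolean stages;
#' exposed because matched-discretisation comparisons are the natural
#' volume oracle for those stages.
#'
#' @param mesh watertight [TriMesh-class]
#' @param voxel grid pitch (mm)
#' @return remeshed [TriMesh-class]
#' @export
remeshVoxel <- function(mesh, voxel) {
  grid <- .gridForMeshes(list(mesh), voxel)
  .fieldMesh(.meshField(mesh, grid), grid)
}

.requireWatertight <- function(mesh, what) {
  audit <- cpp_edge_audit(mesh@faces)
  if (!isTRUE(audit$closed) || !isTRUE(audit$oriented))
    stop(what, " must be a watertight, consistently oriented mesh (",
         audit$n_boundary_edges, " boundary edges, ",
         audit$n_nonmanifold_edges, " non-manifold edges)")
  invisible(TRUE)
}
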