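# Image-processing stage: CT-like volume -> binary mask -> watertight
# surface mesh (threshold segmentation, connected-component region growing,
# isosurface extraction with optional Taubin smoothing).

#' Threshold segmentation
#'
#' Marks voxels with `lower <= intensity <= upper`; the default lower bound
#' of 226 HU is the conventional lower limit for bone in CT.
#'
#' @param volume an [ImageVolume-class]
#' @param lower,upper intensity window (HU)
#' @return a [BinaryMask-class]
#' @export
thresholdSegment <- function(volume, lower = 226, upper = Inf) {
  if (lower > upper) stop("lower must be <= upper")
  m <- volume@intensities >= lower & volume@intensities <= upper
  BinaryMask(m, volume@spacing, volume@origin)
}

#' Region growing on a binary mask
#'
#' Connected-component selection under 26-connectivity: either the largest
#' component or the component containing a seed voxel.
#'
#' @param mask a [BinaryMask-class]
#' @param mode "largest" or "seeded"
#' @param seedVoxel 1-based voxel index triple (for `mode = "seeded"`)
#' @param connectivity 26 (default) or 6
#' @return a [BinaryMask-class] containing a single component
#' @export
regionGrow <- function(mask, mode = c("largest", "seeded"), seedVoxel = NULL,
                       connectivity = 26) {
  mode <- match.arg(mode)
  dims <- dim(mask@mask)
  if (mode == "largest" && !any(mask@mask)) stop("mask is empty")
  labels <- cpp_label_components(as.vector(mask@mask), dims, connectivity)
  labels <- array(labels, dims)
  if (mode == "largest") {
    keep <- labels == 1L
  } else {
    if (is.null(seedVoxel) || length(seedVoxel) != 3)
      stop("seedVoxel (1-based index triple) required for seeded mode")
    lab <- labels[seedVoxel[1], seedVoxel[2], seedVoxel[3]]
    if (lab == 0L) stop("seed voxel is outside the mask")
    keep <- labels == lab
  }
  BinaryMask(keep, mask@spacing, mask@origin)
}

# Taubin lambda/mu smoothing: volume-preserving in the sense that the
# shrinkage of the positive step is compensated by the negative one
.taubinSmooth <- function(mesh, iterations, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0) return(mesh)
  f <- mesh@faces
  n <- nrow(mesh@vertices)
  i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- mesh@vertices
  for (it in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(A %*% v) / deg - v)
    v <- v + mu * (as.matrix(A %*% v) / deg - v)
  }
  TriMesh(v, f, mesh@faceTags)
}

#' Extract a surface mesh from a binary mask
#'
#' Marching-tetrahedra isosurface at 0.5 occupancy (vertices on voxel-edge
#' midpoints), in world coordinates, with optional Taubin smoothing.  The
#' mask is padded with background so the surface is closed even for masks
#' touching the grid boundary.
#'
#' @param mask a [BinaryMask-class]
#' @param smoothIterations Taubin smoothing iterations (0 = none)
#' @return a watertight [TriMesh-class]
#' @export
maskToMesh <- function(mask, smoothIterations = 10) {
  if (!any(mask@mask)) stop("mask is empty")
  dims <- dim(mask@mask)
  padded <- array(0.5, dims + 2L)
  padded[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <-
    ifelse(mask@mask, -0.5, 0.5)
  origin <- mask@origin - mask@spacing
  mt <- cpp_marching_tets(as.vector(padded), dims + 2L, origin, mask@spacing, 0)
  mesh <- cleanMesh(TriMesh(mt$vertices, mt$faces))
  .taubinSmooth(mesh, smoothIterations)
}

#' Voxel-count volume of a mask
#'
#' @param mask a [BinaryMask-class]
#' @return occupied volume (mm^3)
#' @export
maskVolume <- function(mask) {
  sum(mask@mask) * prod(mask@spacing)
}
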