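# File formats: STL (binary write, binary + ASCII read), XYZ point clouds,
# NIfTI volumes (via RNifti), VAS score CSV, and a minimal legacy-VTK
# unstructured-grid writer for FE results.

#' Write a mesh as binary STL
#'
#' @param mesh a [TriMesh-class]
#' @param path output file
#' @export
writeSTL <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 80)), con)
  f <- mesh@faces
  m <- nrow(f)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  fg <- .faceGeometry(mesh)
  v <- mesh@vertices
  # 12 floats + 2-byte attribute per facet
  block <- matrix(0, 12, m)
  block[1:3, ] <- t(fg$normal)
  block[4:6, ] <- t(v[f[, 1], , drop = FALSE])
  block[7:9, ] <- t(v[f[, 2], , drop = FALSE])
  block[10:12, ] <- t(v[f[, 3], , drop = FALSE])
  raw12 <- writeBin(as.vector(block), raw(), size = 4, endian = "little")
  raw12 <- matrix(raw12, nrow = 48)
  attrRaw <- as.raw(c(0, 0))
  out <- vapply(seq_len(m), function(i) c(raw12[, i], attrRaw), raw(50))
  writeBin(as.vector(out), con)
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Vertices are welded exactly (identical coordinates merged) so the
#' connectivity of watertight solids survives the round trip.
#'
#' @param path STL file
#' @return a [TriMesh-class]
#' @export
readSTL <- function(path) {
  hdr <- readBin(path, "raw", n = 512)
  isAscii <- length(hdr) >= 5 && identical(rawToChar(hdr[1:5]), "solid") &&
    any(grepl("facet", suppressWarnings(rawToChar(hdr[-(1:5)])), fixed = TRUE))
  if (isAscii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    m <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    rec <- readBin(con, "raw", n = 50 * m)
    rec <- matrix(rec, nrow = 50)
    floats <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12 * m, size = 4,
                      endian = "little")
    floats <- matrix(floats, nrow = 12)
    coords <- matrix(as.vector(floats[4:12, ]), ncol = 3, byrow = TRUE)
  }
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = "/")
  idx <- match(key, key)
  uniq <- !duplicated(key)
  remap <- integer(length(key))
  remap[uniq] <- seq_len(sum(uniq))
  fidx <- matrix(remap[idx], ncol = 3, byrow = TRUE)
  storage.mode(fidx) <- "integer"
  TriMesh(coords[uniq, , drop = FALSE], fidx)
}

#' Write / read XYZ point clouds (whitespace-separated text)
#'
#' @param points n x 3 matrix
#' @param path file path
#' @export
writeXYZ <- function(points, path) {
  write.table(format(as.matrix(points), digits = 10, trim = TRUE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeXYZ
#' @export
readXYZ <- function(path) {
  as.matrix(read.table(path, col.names = c("x", "y", "z")))
}

#' Write an ImageVolume as NIfTI
#'
#' @param volume an [ImageVolume-class]
#' @param path output path (.nii or .nii.gz)
#' @export
writeVolumeNIfTI <- function(volume, path) {
  img <- RNifti::asNifti(volume@intensities)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into an ImageVolume
#'
#' @param path NIfTI file
#' @param origin world position of voxel (0,0,0); NIfTI orientation headers
#'   beyond pixel spacing are ignored in this desk-scale pipeline
#' @export
readVolumeNIfTI <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  ImageVolume(array(as.numeric(img), dim = dim(img)), spacing = sp[1:3], origin = origin)
}

#' Write / read VAS score tables (experts as rows, replicates as columns)
#'
#' @param scores integer matrix of scores in 1..5
#' @param path CSV path
#' @export
writeVASTable <- function(scores, path) {
  df <- as.data.frame(scores)
  names(df) <- paste0("replicate_", seq_len(ncol(scores)))
  write.csv(cbind(expert = seq_len(nrow(scores)), df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVASTable
#' @export
readVASTable <- function(path) {
  df <- read.csv(path)
  as.matrix(df[, grep("^replicate", names(df)), drop = FALSE])
}

#' Export an FE model + result as a legacy VTK unstructured grid
#'
#' Point displacements and per-cell von Mises stress, readable by ParaView.
#'
#' @param model an [FEModel-class]
#' @param result an [FEAResult-class] (optional)
#' @param path output .vtk path
#' @export
writeVTK <- function(model, result = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(model@nodes)
  m <- nrow(model@elements)
  writeLines(c("# vtk DataFile Version 3.0", "cranioforge FE mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  write.table(model@nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  write.table(cbind(4L, model@elements - 1L), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(model@elementRegion), con)
  if (!is.null(result)) {
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(result@elementVonMises, digits = 8), con)
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS displacement double", con)
    write.table(result@displacements, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
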