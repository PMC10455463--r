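# Implant design: outer-surface template extraction, inward offset shell,
# rim/core partition, diamond-lattice scaffold solved to a target porosity,
# screw holes, and pore-size metrology.

#' Extract the outer (skull-conformal) surface patch of an implant template
#'
#' Selects template faces whose centroids lie within `eps` of the skull
#' surface with agreeing outward normals, then keeps the connected patch
#' farthest from the skull's interior -- the outer table of the implant-bone
#' model, which acts as the implant template surface.
#'
#' @param template implant-template solid (defect-free minus defective skull)
#' @param skull the (defect-free) skull the template derives from
#' @param eps face-to-skull distance tolerance (mm)
#' @param angleDeg maximum normal disagreement (degrees)
#' @return an open [TriMesh-class] patch, outward-oriented
#' @export
extractOuterSurface <- function(template, skull, eps = 0.8, angleDeg = 50) {
  fg <- .faceGeometry(template)
  cp <- cpp_points_to_mesh(skull@vertices, skull@faces, fg$centroid)
  sg <- .faceGeometry(skull)
  nSkull <- sg$normal[cp$face, , drop = FALSE]
  agree <- rowSums(fg$normal * nSkull)
  cand <- cp$distance < eps & agree > cos(angleDeg * pi / 180)
  if (!any(cand)) stop("no template faces lie on the skull surface (empty patch)")
  # close pin-holes: a face most of whose edge-neighbours are candidates
  # joins the patch (local normal jitter on voxel meshes fails the angle
  # test in isolated spots)
  nb <- .faceNeighbours(template)
  for (pass in 1:3) {
    nnb <- (cand[nb[, 1]] & nb[, 1] > 0) + (cand[nb[, 2]] & nb[, 2] > 0) +
      (cand[nb[, 3]] & nb[, 3] > 0)
    cand <- cand | nnb >= 2
  }
  sub <- .subMesh(template, cand)
  comp <- cpp_mesh_components(sub@faces, nrow(sub@vertices))
  skullCenter <- colMeans(skull@vertices)
  sfg <- .faceGeometry(sub)
  radial <- sqrt(rowSums(sweep(sfg$centroid, 2, skullCenter)^2))
  compArea <- vapply(seq_len(max(comp)), function(k) sum(sfg$area[comp == k]),
                     numeric(1))
  compMean <- vapply(seq_len(max(comp)), function(k) {
    w <- sfg$area[comp == k]
    sum(radial[comp == k] * w) / sum(w)
  }, numeric(1))
  # the outer table: farthest substantial patch from the skull centre
  # (tiny slivers left by the cut tolerance are excluded by the area gate)
  substantial <- which(compArea >= 0.2 * max(compArea))
  pick <- substantial[which.max(compMean[substantial])]
  .subMesh(sub, comp == pick)
}

# edge-neighbour face ids (m x 3; 0 = boundary edge)
.faceNeighbours <- function(mesh) {
  f <- mesh@faces
  m <- nrow(f)
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  fid <- rep(seq_len(m), 3)
  ord <- order(key)
  keyS <- key[ord]
  fidS <- fid[ord]
  first <- !duplicated(keyS)
  grp <- cumsum(first)
  # for each half-edge, the other face sharing its undirected edge (0 if none)
  other <- integer(length(keyS))
  idx <- seq_along(keyS)
  lo <- idx[first]
  sizes <- tabulate(grp)
  a <- lo[sizes == 2]
  other[a] <- fidS[a + 1]
  other[a + 1] <- fidS[a]
  out <- integer(length(key))
  out[ord] <- other
  matrix(out, m, 3)
}

# directed boundary edges (a -> b as traversed by their face) of an open mesh
.boundaryEdges <- function(mesh) {
  f <- mesh@faces
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  cnt <- table(key)
  onBoundary <- cnt[key] == 1
  cbind(a = ea[onBoundary], b = eb[onBoundary])
}

# Split "bowtie" boundary vertices (two face fans touching at one vertex)
# into one vertex per fan, so the swept side walls stay manifold.
.splitBoundaryBowties <- function(mesh) {
  be <- .boundaryEdges(mesh)
  if (nrow(be) == 0) return(mesh)
  deg <- table(c(be[, "a"], be[, "b"]))
  bow <- as.integer(names(deg)[deg > 2])
  if (!length(bow)) return(mesh)
  f <- mesh@faces
  v <- mesh@vertices
  for (bv in bow) {
    incident <- which(f[, 1] == bv | f[, 2] == bv | f[, 3] == bv)
    # group incident faces into fans: faces sharing an edge through bv
    othersOf <- lapply(incident, function(ff) setdiff(f[ff, ], bv))
    grp <- seq_along(incident)
    repeat {
      changed <- FALSE
      for (a in seq_along(incident)) for (b in seq_along(incident)) {
        if (grp[a] != grp[b] && length(intersect(othersOf[[a]], othersOf[[b]]))) {
          grp[grp == grp[b]] <- grp[a]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    fans <- unique(grp)
    if (length(fans) <= 1) next
    for (fi in fans[-1]) {
      v <- rbind(v, v[bv, , drop = FALSE])
      nid <- nrow(v)
      for (ff in incident[grp == fi]) f[ff, f[ff, ] == bv] <- nid
    }
  }
  TriMesh(v, f, mesh@faceTags)
}

#' Sweep an open surface patch into a solid shell of given thickness
#'
#' Offsets every vertex inward along its (area-weighted) normal and caps
#' the side walls along the boundary loop, producing a watertight solid.
#' Faces are tagged 1 = outer (original patch), 2 = inner (offset), 3 =
#' side wall; the tags drive the rim/core partition.
#'
#' @param patch open, outward-oriented [TriMesh-class]
#' @param thickness offset distance (mm, > 0)
#' @param normalSmoothing Laplacian smoothing iterations applied to the
#'   vertex-normal field before sweeping; keeps the sweep direction smooth
#'   on finely triangulated (voxel-extracted) patches
#' @return watertight [TriMesh-class] with `faceTags`
#' @export
offsetShell <- function(patch, thickness, normalSmoothing = 25) {
  if (thickness <= 0) stop("thickness must be positive (degenerate shell)")
  patch <- cleanMesh(patch, dropDegenerate = FALSE)
  patch <- .splitBoundaryBowties(patch)
  v <- patch@vertices
  n <- .vertexNormals(patch)
  if (normalSmoothing > 0) {
    f <- patch@faces
    i <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
    j <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nrow(v), nrow(v)))
    deg <- pmax(Matrix::rowSums(A), 1)
    for (it in seq_len(normalSmoothing)) {
      n <- n + 0.7 * (as.matrix(A %*% n) / deg - n)
      n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
    }
  }
  vIn <- v - thickness * n
  nv <- nrow(v)
  top <- patch@faces
  bottom <- patch@faces[, c(1, 3, 2), drop = FALSE] + nv
  # self-intersection diagnostic: offset faces flipping against their
  # originals over a substantial area mean the local curvature radius is
  # below the thickness; isolated sliver flips (voxel-mesh artefacts at
  # far-sub-voxel scale) are tolerated -- the downstream signed-field CSG
  # is parity-based and heals them
  fgTop <- .faceGeometry(patch)
  fgBot <- .faceGeometry(TriMesh(vIn, patch@faces))
  flipped <- rowSums(fgTop$normal * fgBot$normal) < 0
  # a genuine curvature violation flips a large contiguous share of the
  # area; isolated voxel-artefact slivers stay in the low percent range
  flippedFrac <- sum(fgTop$area[flipped]) / sum(fgTop$area)
  if (flippedFrac > 0.05)
    stop(sprintf("%.1f%% of the offset area inverts: thickness %g mm exceeds the local curvature radius of the patch",
                 100 * flippedFrac, thickness))
  be <- .boundaryEdges(patch)
  if (nrow(be) == 0) stop("patch has no boundary; offsetShell expects an open patch")
  wall1 <- cbind(be[, "b"], be[, "a"], be[, "a"] + nv)
  wall2 <- cbind(be[, "b"], be[, "a"] + nv, be[, "b"] + nv)
  fAll <- rbind(top, bottom, wall1, wall2)
  storage.mode(fAll) <- "integer"
  tags <- c(rep(1L, nrow(top)), rep(2L, nrow(bottom)), rep(3L, 2 * nrow(be)))
  out <- TriMesh(rbind(v, vIn), fAll, tags)
  audit <- cpp_edge_audit(out@faces)
  if (!isTRUE(audit$closed) || !isTRUE(audit$oriented))
    stop("offset shell is not watertight (", audit$n_boundary_edges,
         " boundary edges); the patch boundary may be non-manifold")
  if (cpp_mesh_volume(out@vertices, out@faces) < 0)
    stop("offset shell came out inverted; check patch orientation")
  out
}

#' Partition a shell solid into a solid rim band and an inner core
#'
#' The rim is the part of the solid within `rimWidth` of the side wall
#' (kept solid for screw fixation); the core is the remainder, destined to
#' become the porous scaffold.  Complementary cuts on a common grid, so
#' the two volumes sum to the solid's volume.
#'
#' @param solid shell from [offsetShell()] (wall faces tagged 3), or any
#'   watertight solid plus an explicit `wall` submesh
#' @param rimWidth band width (mm)
#' @param voxel grid pitch (mm)
#' @param wall optional open [TriMesh-class] of the side-wall surface
#' @return list with `rim` and `core` [TriMesh-class] solids
#' @export
partitionRimCore <- function(solid, rimWidth, voxel = 0.25, wall = NULL) {
  .requireWatertight(solid, "solid")
  if (is.null(wall)) {
    if (!length(solid@faceTags)) stop("solid has no face tags; supply `wall`")
    wall <- .subMesh(solid, solid@faceTags == 3L)
  }
  if (nFaces(wall) == 0) stop("wall surface is empty")
  grid <- .gridForMeshes(list(solid), voxel)
  f <- .meshField(solid, grid)
  clamp <- rimWidth + 4 * voxel
  dwall <- cpp_tris_dist_grid(wall@vertices, wall@faces, grid$origin, grid$spacing,
                              grid$dims, clamp)
  rim <- .fieldMesh(pmax(f, dwall - rimWidth), grid)
  core <- .fieldMesh(pmax(f, rimWidth - dwall), grid)
  if (nFaces(core) == 0)
    stop("rimWidth ", rimWidth, " mm consumes the whole solid; no core remains")
  if (nFaces(rim) == 0) message("partitionRimCore: rim is empty (rimWidth ~ 0)")
  list(rim = rim, core = core)
}

# strut segments of a diamond lattice tiling a bounding box (conventional
# cubic cell of edge `a`: FCC sites + basis, bonds along the 4 tetrahedral
# directions; each bond emitted once from its A-sublattice end)
.diamondSegments <- function(bboxMin, bboxMax, a) {
  lo <- floor(bboxMin / a) - 1
  hi <- ceiling(bboxMax / a) + 1
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  bonds <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / 4
  cells <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  atoms <- matrix(0, nrow(cells) * 4, 3)
  for (s in 1:4)
    atoms[seq_len(nrow(cells)) + (s - 1) * nrow(cells), ] <-
      (cells + matrix(fcc[s, ], nrow(cells), 3, byrow = TRUE)) * a
  segs <- matrix(0, nrow(atoms) * 4, 6)
  for (bnd in 1:4) {
    idx <- seq_len(nrow(atoms)) + (bnd - 1) * nrow(atoms)
    segs[idx, 1:3] <- atoms
    segs[idx, 4:6] <- atoms + matrix(bonds[bnd, ] * a, nrow(atoms), 3, byrow = TRUE)
  }
  # drop segments entirely outside the (expanded) box
  keep <- segs[, 1] > bboxMin[1] - a & segs[, 1] < bboxMax[1] + a &
    segs[, 2] > bboxMin[2] - a & segs[, 2] < bboxMax[2] + a &
    segs[, 3] > bboxMin[3] - a & segs[, 3] < bboxMax[3] + a
  segs[keep, , drop = FALSE]
}

#' Generate a diamond-lattice scaffold inside a core solid
#'
#' The unit cell is the diamond crystal bond network: cylindrical struts of
#' `strutRadius` along the tetrahedral bond directions connecting the two
#' interpenetrating FCC sublattices, tiled over the core's bounding box,
#' unioned (as capsules) and intersected with the core.
#'
#' @param core watertight [TriMesh-class]
#' @param spec a [LatticeSpec-class]
#' @param voxel grid pitch for the CSG (mm)
#' @return watertight scaffold [TriMesh-class]; attributes `segments` (the
#'   strut endpoints) and `strutRadius` support pore metrology
#' @export
generateDiamondLattice <- function(core, spec, voxel = 0.15) {
  .requireWatertight(core, "core")
  validObject(spec)
  bb <- .meshBBox(core)
  if (spec@cellSize > max(bb$max - bb$min))
    stop("cellSize ", spec@cellSize, " mm exceeds the core extent")
  grid <- .gridForMeshes(list(core), voxel)
  f <- .meshField(core, grid)
  segs <- .diamondSegments(bb$min, bb$max, spec@cellSize)
  clamp <- spec@strutRadius + 4 * voxel
  dseg <- cpp_segments_dist_grid(segs, grid$origin, grid$spacing, grid$dims, clamp)
  out <- .fieldMesh(pmax(f, dseg - spec@strutRadius), grid)
  attr(out, "segments") <- segs
  attr(out, "strutRadius") <- spec@strutRadius
  out
}

#' Porosity from bulk and scaffold volumes
#'
#' `(V1 - V2) / V1 * 100`, the void percentage of a scaffold of material
#' volume `v2` occupying a solid envelope of volume `v1`.  Exact and
#' scale-invariant.
#'
#' @param v1 bulk (envelope) volume, mm^3
#' @param v2 scaffold (material) volume, mm^3
#' @return porosity in percent
#' @export
porosity <- function(v1, v2) {
  if (v1 <= 0) stop("v1 must be positive")
  if (v2 < 0 || v2 > v1) stop("v2 must lie in [0, v1]")
  (v1 - v2) / v1 * 100
}

#' Solve the strut radius achieving a target porosity
#'
#' Bisection on the strut radius of the diamond scaffold inside `core`
#' until the achieved porosity (V1 = core volume, V2 = scaffold volume,
#' both measured on the same CSG grid) is within `tol` of the target.
#'
#' @param core watertight [TriMesh-class]
#' @param cellSize diamond cell edge (mm)
#' @param targetPorosity void fraction in (0, 1)
#' @param voxel CSG grid pitch (mm)
#' @param tol porosity tolerance (fraction; default 0.005 = 0.5 points)
#' @param maxIter bisection cap
#' @return strut radius (mm); attributes `porosity` (achieved, percent),
#'   `V1`, `V2` (mm^3) and `iterations`
#' @export
solveStrutRadius <- function(core, cellSize, targetPorosity, voxel = 0.15,
                             tol = 0.005, maxIter = 30) {
  .requireWatertight(core, "core")
  if (targetPorosity <= 0 || targetPorosity >= 1)
    stop("targetPorosity must be in (0, 1)")
  grid <- .gridForMeshes(list(core), voxel)
  f <- .meshField(core, grid)
  v1mesh <- .fieldMesh(f, grid)
  V1 <- meshVolume(v1mesh)
  bb <- .meshBBox(core)
  segs <- .diamondSegments(bb$min, bb$max, cellSize)
  rLo <- 0.02 * cellSize
  rHi <- 0.25 * cellSize
  clamp <- rHi + 4 * voxel
  dseg <- cpp_segments_dist_grid(segs, grid$origin, grid$spacing, grid$dims, clamp)
  porAt <- function(r) {
    scaf <- .fieldMesh(pmax(f, dseg - r), grid)
    V2 <- if (nFaces(scaf) == 0) 0 else meshVolume(scaf)
    list(p = (V1 - V2) / V1, V2 = V2)
  }
  pLo <- porAt(rLo) # thin struts: high porosity
  pHi <- porAt(rHi)
  if (targetPorosity > pLo$p || targetPorosity < pHi$p)
    stop(sprintf("target porosity %.1f%% outside achievable range [%.1f%%, %.1f%%] for cell %g mm",
                 100 * targetPorosity, 100 * pHi$p, 100 * pLo$p, cellSize))
  r <- NA
  achieved <- NA
  V2 <- NA
  iterations <- 0L
  for (it in seq_len(maxIter)) {
    iterations <- it
    r <- (rLo + rHi) / 2
    cur <- porAt(r)
    achieved <- cur$p
    V2 <- cur$V2
    if (abs(achieved - targetPorosity) < tol) break
    if (achieved > targetPorosity) rLo <- r else rHi <- r # porosity decreases with r
  }
  structure(r, porosity = 100 * achieved, V1 = V1, V2 = V2, iterations = iterations)
}

#' Measure the scaffold pore diameter
#'
#' At random interior void points, the diameter of the largest locally
#' inscribed sphere not intersecting the struts: clearance (distance to the
#' strut surface) is maximised from each random start by Nelder-Mead, and
#' the pore diameter is twice the converged clearance.
#'
#' @param scaffold scaffold mesh from [generateDiamondLattice()] (carrying
#'   strut segments), or any mesh (surface-distance fallback)
#' @param core the core solid bounding the void space
#' @param nSamples number of probe pores (default 5)
#' @param seed RNG seed
#' @return list: `mean` and `samples`, in micrometres
#' @export
measurePoreDiameter <- function(scaffold, core, nSamples = 5, seed = 1L) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  segs <- attr(scaffold, "segments")
  r <- attr(scaffold, "strutRadius")
  clearance <- if (!is.null(segs) && !is.null(r)) {
    function(p) cpp_points_segments_dist(matrix(p, 1), segs) - r
  } else {
    qhS <- cpp_mesh_query_build(scaffold@vertices, scaffold@faces)
    function(p) cpp_mesh_query(qhS, matrix(p, 1))$distance
  }
  qhCore <- cpp_mesh_query_build(core@vertices, core@faces)
  inCore <- cpp_inside_query_build(core@vertices, core@faces)
  bb <- .meshBBox(core)
  # random interior void starts, well inside the core
  starts <- .withSeed(seed, {
    found <- matrix(NA_real_, nSamples, 3)
    got <- 0L
    for (try in seq_len(5000L)) {
      p <- runif(3, bb$min, bb$max)
      if (!cpp_inside_query(inCore, matrix(p, 1))) next
      depth <- cpp_mesh_query(qhCore, matrix(p, 1))$distance
      if (depth < 1 || clearance(p) <= 0.05) next
      got <- got + 1L
      found[got, ] <- p
      if (got == nSamples) break
    }
    if (got < nSamples) stop("could not find ", nSamples, " interior void points; ",
                             "scaffold may have no void space")
    found
  })
  diam <- vapply(seq_len(nSamples), function(i) {
    # inscribed-sphere clearance, valid only inside the core: exterior
    # probes are rejected so the ascent cannot escape the void space
    obj <- function(p) {
      if (!cpp_inside_query(inCore, matrix(p, 1))) return(1e6)
      depth <- cpp_mesh_query(qhCore, matrix(p, 1))$distance
      -min(clearance(p), depth)
    }
    opt <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-8))
    2 * (-opt$value)
  }, numeric(1))
  list(mean = mean(diam) * 1000, samples = diam * 1000)
}

# Intersecting the strut network with the core leaves small strut fragments
# cut off at the boundary.  Fragments touching the solid rim are supported
# (the printed part is one piece); truly floating ones are dropped.  The
# retained scaffold keeps the strut-segment attributes.
.dropFloatingFragments <- function(scaffold, rim, tol = 0.5) {
  comp <- meshComponents(scaffold)
  if (max(comp) == 1) return(scaffold)
  fg <- .faceGeometry(scaffold)
  qh <- cpp_mesh_query_build(rim@vertices, rim@faces)
  nComp <- max(comp)
  vols <- vapply(seq_len(nComp), function(k) {
    sel <- comp == k
    f <- scaffold@faces[sel, , drop = FALSE]
    abs(cpp_mesh_volume(scaffold@vertices, f))
  }, numeric(1))
  main <- which.max(vols)
  keep <- logical(nComp)
  keep[main] <- TRUE
  for (k in seq_len(nComp)) {
    if (k == main) next
    cen <- fg$centroid[comp == k, , drop = FALSE]
    keep[k] <- min(cpp_mesh_query(qh, cen)$distance) < tol
  }
  if (all(keep)) return(scaffold)
  out <- .subMesh(scaffold, keep[comp])
  attr(out, "segments") <- attr(scaffold, "segments")
  attr(out, "strutRadius") <- attr(scaffold, "strutRadius")
  attr(out, "droppedVolume") <- sum(vols[!keep])
  out
}

#' Drill screw holes through the rim
#'
#' Subtracts through-cylinders normal to the local outer surface at each
#' centre.  A zero diameter is a no-op; a centre away from the rim is an
#' error.
#'
#' @param rim watertight rim [TriMesh-class]
#' @param centers k x 3 matrix of hole centres (on or near the rim surface)
#' @param diameter hole diameter (mm)
#' @param voxel CSG grid pitch (mm)
#' @return rim with holes, watertight [TriMesh-class]
#' @export
addScrewHoles <- function(rim, centers, diameter, voxel = 0.2) {
  .requireWatertight(rim, "rim")
  if (diameter == 0) return(rim)
  if (diameter < 0) stop("diameter must be >= 0")
  centers <- as.matrix(centers)
  cp <- cpp_points_to_mesh(rim@vertices, rim@faces, centers)
  if (any(cp$distance > 3))
    stop("screw-hole centre ", which.max(cp$distance), " lies ",
         sprintf("%.1f", max(cp$distance)), " mm away from the rim")
  fg <- .faceGeometry(rim)
  grid <- .gridForMeshes(list(rim), voxel)
  f <- .meshField(rim, grid)
  for (i in seq_len(nrow(centers))) {
    axis <- fg$normal[cp$face[i], ]
    cyl <- .cylinderField(grid, cp$point[i, ], axis, diameter / 2, 25)
    f <- pmax(f, -cyl)
  }
  .fieldMesh(f, grid)
}

#' Design the complete porous implant from a template
#'
#' The full implant-design stage: extract the outer surface patch, offset
#' it inward into a shell, partition into rim and core, solve the diamond
#' lattice to the target porosity, drill screw holes, and assemble the
#' volumes entering the porosity formula.
#'
#' @param template implant-template solid
#' @param skull the defect-free skull the template derives from
#' @param thickness offset-shell thickness (mm; default 4)
#' @param rimWidth solid rim band width (mm)
#' @param cellSize diamond cell edge (mm)
#' @param targetPorosity void fraction
#' @param screwDiameter screw-hole diameter (mm)
#' @param voxel CSG pitch for shell operations (mm)
#' @param latticeVoxel CSG pitch for lattice operations (mm)
#' @return an [ImplantModel-class]; attribute `design` carries the solved
#'   parameters and achieved metrics
#' @export
designImplant <- function(template, skull, thickness = 4, rimWidth = 6,
                          cellSize = 2.5, targetPorosity = 0.70,
                          screwDiameter = 2, voxel = 0.3, latticeVoxel = 0.15) {
  patch <- extractOuterSurface(template, skull)
  solid <- offsetShell(patch, thickness)
  parts <- partitionRimCore(solid, rimWidth, voxel = voxel)
  rStrut <- solveStrutRadius(parts$core, cellSize, targetPorosity, voxel = latticeVoxel)
  spec <- LatticeSpec(cellSize = cellSize, strutRadius = as.numeric(rStrut),
                      targetPorosity = targetPorosity)
  scaffold <- generateDiamondLattice(parts$core, spec, voxel = latticeVoxel)
  scaffold <- .dropFloatingFragments(scaffold, parts$rim)
  # four screw centres: boundary quadrant points pulled half a rim width
  # toward the patch interior, then projected back onto the rim surface
  be <- .boundaryEdges(patch)
  bpts <- patch@vertices[be[, "a"], , drop = FALSE]
  pc <- colMeans(patch@vertices)
  rel <- sweep(bpts, 2, pc)
  basis <- svd(rel)$v
  ang <- atan2(rel %*% basis[, 2], rel %*% basis[, 1])
  targets <- c(-3, -1, 1, 3) * pi / 4
  sel <- vapply(targets, function(a) which.min(abs(as.numeric(ang) - a)), integer(1))
  inward <- bpts[sel, ] + 0.5 * rimWidth * sweep(-rel[sel, , drop = FALSE], 1,
                                                 sqrt(rowSums(rel[sel, , drop = FALSE]^2)), "/")
  centers <- cpp_points_to_mesh(parts$rim@vertices, parts$rim@faces, inward)$point
  rim <- addScrewHoles(parts$rim, centers, screwDiameter)
  V1 <- attr(rStrut, "V1")
  V2 <- meshVolume(scaffold) # after dropping unsupported fragments
  model <- new("ImplantModel", solidRim = rim, porousCore = parts$core,
               scaffold = scaffold, screwHoleCenters = centers,
               bulkVolume = V1, scaffoldVolume = V2, lattice = spec)
  attr(model, "design") <- list(
    strutRadius = as.numeric(rStrut),
    corePorosityPercent = porosity(V1, V2),
    V1 = V1, V2 = V2,
    rimVolume = meshVolume(rim),
    implantPorosityPercent = porosity(V1 + meshVolume(rim), V2 + meshVolume(rim)),
    thickness = thickness, rimWidth = rimWidth, cellSize = cellSize)
  model
}

setMethod("show", "ImplantModel", function(object) {
  cat(sprintf("ImplantModel: V1 (bulk) %.2f mm^3, V2 (scaffold) %.2f mm^3, porosity %.2f%%\n",
              object@bulkVolume, object@scaffoldVolume,
              porosity(object@bulkVolume, object@scaffoldVolume)))
  cat(sprintf("  lattice: diamond, cell %.2f mm, strut radius %.3f mm\n",
              object@lattice@cellSize, object@lattice@strutRadius))
  cat(sprintf("  %d screw holes\n", nrow(object@screwHoleCenters)))
})
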