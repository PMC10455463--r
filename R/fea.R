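# Linear static finite-element strength check of the skull + implant +
# screws assembly.  Voxel-conforming tet4 meshing on a shared grid realises
# the bonded interface condition by node sharing; the solver is a direct
# sparse Cholesky factorisation (mm-N-MPa units).

#' Material table for the assembly
#'
#' PEEK implant, cortical-bone skull and titanium screws (Young's modulus
#' MPa, Poisson ratio, yield strength MPa).
#'
#' @return named list of [MaterialProps-class]: skull, implant, screw
#' @export
defaultMaterials <- function() {
  list(skull = MaterialProps(13700, 0.3, 122),
       implant = MaterialProps(3738, 0.4, 99.9),
       screw = MaterialProps(120000, 0.3, 930))
}

# region codes at the given sample points (priority screw > implant > skull)
.regionAt <- function(solids, origin, spacing, dims) {
  region <- integer(prod(dims))
  for (k in seq_along(solids)) {
    if (is.null(solids[[k]])) next
    occ <- cpp_inside_grid(solids[[k]]@vertices, solids[[k]]@faces, origin,
                           rep(spacing, 3), dims)
    region[occ] <- k
  }
  region
}

#' Build the voxel-conforming tet4 model of the assembly
#'
#' A voxel grid is laid over the whole assembly; every voxel whose centre
#' falls inside a solid is split into 6 tetrahedra, with region priority
#' screw > implant > skull where solids overlap.  Because all regions mesh
#' the same grid, interface nodes are shared -- the bonded contact
#' condition.  With `refine = TRUE` (the default when an implant is
#' given), `voxelSize` is used inside an implant-centred box and twice the
#' pitch elsewhere; fine nodes on the box boundary are tied to their two
#' coarse master nodes (mid-edge / face-diagonal averages), which is
#' exactly conforming for this cube-to-tetrahedra split.
#'
#' @param skull watertight [TriMesh-class] solid
#' @param implant watertight implant solid, or `NULL` for a single-region
#'   model (benchmarks)
#' @param screws list of watertight screw solids (may be empty)
#' @param voxelSize fine grid pitch (mm); values outside 0.5..3 mm warn
#' @param refine use the two-level grid (fine box around the implant)
#' @param refineMargin box margin around the implant bbox (mm)
#' @return an [FEModel-class] (no boundary conditions yet)
#' @export
buildFEModel <- function(skull, implant = NULL, screws = list(), voxelSize = 1.5,
                         refine = TRUE, refineMargin = 6) {
  if (voxelSize < 0.5 || voxelSize > 3)
    warning("voxelSize ", voxelSize, " mm is outside the intended 0.5..3 mm range")
  solids <- c(list(skull, implant), screws)
  for (s in solids) if (!is.null(s)) .requireWatertight(s, "solid")
  if (is.null(implant)) refine <- FALSE
  labels <- c("skull", "implant", if (length(screws)) paste0("screw_", seq_along(screws)))
  v <- voxelSize
  present <- !vapply(solids, is.null, logical(1))
  bb <- lapply(solids[present], .meshBBox)
  lo <- do.call(pmin, lapply(bb, `[[`, "min")) - 2 * v
  hi <- do.call(pmax, lapply(bb, `[[`, "max")) + 2 * v

  if (!refine) {
    dims <- as.integer(ceiling((hi - lo) / v))
    region <- .regionAt(solids, lo + v / 2, v, dims)
    if (!any(region == 1L)) stop("skull region is empty at this voxel size")
    if (!is.null(implant) && !any(region == 2L))
      stop("implant region is empty at this voxel size")
    gt <- cpp_grid_tets(region, dims, lo, rep(v, 3))
    return(new("FEModel", nodes = gt$nodes, elements = gt$elements,
               elementRegion = as.integer(gt$region), regionLabels = labels,
               fixedNodes = integer(0), fixedDofs = integer(0),
               loads = matrix(0, nrow(gt$nodes), 3),
               voxelSize = v, constraints = matrix(0L, 0, 3),
               refineBox = numeric(0)))
  }

  V <- 2 * v
  dimsC <- as.integer(ceiling((hi - lo) / V))
  dimsF <- 2L * dimsC
  # refinement box (coarse-lattice aligned) around implant + screws
  ibb <- .meshBBox(implant)
  for (s in screws) {
    sb <- .meshBBox(s)
    ibb$min <- pmin(ibb$min, sb$min)
    ibb$max <- pmax(ibb$max, sb$max)
  }
  cLo <- pmax(0L, as.integer(floor((ibb$min - refineMargin - lo) / V)))
  cHi <- pmin(dimsC, as.integer(ceiling((ibb$max + refineMargin - lo) / V)))

  regionF <- .regionAt(solids, lo + v / 2, v, dimsF)
  regionC <- .regionAt(solids, lo + V / 2, V, dimsC)
  # fine voxels only inside the box, coarse only outside
  fi <- arrayInd(seq_len(prod(dimsF)), dimsF) - 1L
  inBoxF <- fi[, 1] >= 2L * cLo[1] & fi[, 1] < 2L * cHi[1] &
    fi[, 2] >= 2L * cLo[2] & fi[, 2] < 2L * cHi[2] &
    fi[, 3] >= 2L * cLo[3] & fi[, 3] < 2L * cHi[3]
  regionF[!inBoxF] <- 0L
  ci <- arrayInd(seq_len(prod(dimsC)), dimsC) - 1L
  inBoxC <- ci[, 1] >= cLo[1] & ci[, 1] < cHi[1] &
    ci[, 2] >= cLo[2] & ci[, 2] < cHi[2] &
    ci[, 3] >= cLo[3] & ci[, 3] < cHi[3]
  regionC[inBoxC] <- 0L
  rm(fi, ci)
  if (!any(regionF > 0L) && !any(regionC > 0L)) stop("assembly is empty")
  if (!any(regionF == 2L)) stop("implant region is empty at this voxel size")
  occC <- array(regionC > 0L, dimsC)

  gtF <- cpp_grid_tets(regionF, dimsF, lo, rep(v, 3))
  gtC <- cpp_grid_tets(regionC, dimsC, lo, rep(V, 3))

  # merge node sets on the fine lattice
  latKey <- function(nodes, pitch) {
    idx <- round(sweep(nodes, 2, lo) / pitch)
    idx[, 1] + (dimsF[1] + 1) * (idx[, 2] + (dimsF[2] + 1) * idx[, 3])
  }
  keyF <- latKey(gtF$nodes, v)
  keyC <- latKey(gtC$nodes, v) # coarse nodes already sit on the fine lattice
  keys <- c(keyF, keyC)
  first <- !duplicated(keys)
  map <- match(keys, keys[first])
  nodes <- rbind(gtF$nodes, gtC$nodes)[first, , drop = FALSE]
  elems <- rbind(matrix(map[as.vector(gtF$elements)], nrow(gtF$elements), 4),
                 matrix(map[nrow(gtF$nodes) + as.vector(gtC$elements)],
                        nrow(gtC$elements), 4))
  storage.mode(elems) <- "integer"
  region <- c(gtF$region, gtC$region)

  # hanging nodes: fine-lattice nodes on a box face with >= 1 odd index,
  # backed by an occupied coarse voxel on the outside of that face
  idxF <- round(sweep(gtF$nodes, 2, lo) / v)
  mergedIdF <- map[seq_len(nrow(gtF$nodes))]
  odd <- idxF %% 2L
  lim <- rbind(2L * cLo, 2L * cHi)
  onFace <- matrix(FALSE, nrow(idxF), 3)
  for (d in 1:3)
    onFace[, d] <- (idxF[, d] == lim[1, d] | idxF[, d] == lim[2, d])
  cand <- which(rowSums(odd) > 0 & rowSums(onFace & (odd == 0)) > 0)
  nodeKeySet <- keys[first]
  lookup <- function(ix) { # merged node id from fine lattice index triple
    k <- ix[, 1] + (dimsF[1] + 1) * (ix[, 2] + (dimsF[2] + 1) * ix[, 3])
    match(k, nodeKeySet)
  }
  consA <- integer(0); consB <- integer(0); consN <- integer(0)
  if (length(cand)) {
    occAt <- function(cix) { # coarse voxel occupied? (0-based index triple)
      ok <- cix[, 1] >= 0 & cix[, 1] < dimsC[1] &
        cix[, 2] >= 0 & cix[, 2] < dimsC[2] &
        cix[, 3] >= 0 & cix[, 3] < dimsC[3]
      res <- logical(nrow(cix))
      if (any(ok))
        res[ok] <- occC[cbind(cix[ok, 1] + 1L, cix[ok, 2] + 1L, cix[ok, 3] + 1L)]
      res
    }
    for (q in cand) {
      ix <- idxF[q, ]
      o <- odd[q, ] == 1L
      # coarse voxels outside the box touching this node
      rng <- lapply(1:3, function(d) {
        if (o[d]) (ix[d] - 1L) %/% 2L
        else unique(pmax(0L, c(ix[d] %/% 2L - 1L, ix[d] %/% 2L)))
      })
      touching <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      outside <- !(touching[, 1] >= cLo[1] & touching[, 1] < cHi[1] &
                     touching[, 2] >= cLo[2] & touching[, 2] < cHi[2] &
                     touching[, 3] >= cLo[3] & touching[, 3] < cHi[3])
      if (!any(occAt(touching[outside, , drop = FALSE]))) next
      mA <- ix; mB <- ix
      mA[o] <- mA[o] - 1L
      mB[o] <- mB[o] + 1L
      a <- lookup(matrix(mA, 1)); b <- lookup(matrix(mB, 1))
      if (is.na(a) || is.na(b)) next
      consN <- c(consN, mergedIdF[q]); consA <- c(consA, a); consB <- c(consB, b)
    }
  }
  constraints <- cbind(node = consN, masterA = consA, masterB = consB)
  storage.mode(constraints) <- "integer"
  new("FEModel", nodes = nodes, elements = elems,
      elementRegion = as.integer(region), regionLabels = labels,
      fixedNodes = integer(0), fixedDofs = integer(0),
      loads = matrix(0, nrow(nodes), 3),
      voxelSize = v, constraints = constraints,
      refineBox = c(lo + V * cLo, lo + V * cHi))
}

#' Apply boundary conditions: basal fixation and a central pressure patch
#'
#' Fixes all degrees of freedom of nodes within a basal slab (lowest z),
#' and applies the total load as consistent nodal forces from a uniform
#' pressure over a circular patch of the implant's upper outer surface:
#' faces are gathered around the patch centre until the requested load
#' area is covered, and each face contributes `pressure * area / 3` per
#' node along its inward normal.
#'
#' @param model an [FEModel-class]
#' @param fixedSlabHeight basal slab height (mm)
#' @param totalLoad total force (N; default 50, the resting head weight)
#' @param loadArea target patch area (mm^2; default 200)
#' @param loadCenter optional (x, y) patch centre; defaults to the implant
#'   top-surface centroid
#' @param fixMode "all" clamps every dof of the basal slab (the assembly
#'   anchoring); "z-rollers" fixes only vertical dofs plus a statically
#'   determinate lateral restraint (verification problems)
#' @param loadRegion "auto" loads the implant's outer surface (the skull's
#'   when no implant region exists); "any" loads every upward-facing
#'   boundary face (uniform-traction verification problems)
#' @return the model with `fixedNodes` and `loads` set; attributes
#'   `realizedArea` and `patchCenter` on the loads matrix
#' @export
applyBCs <- function(model, fixedSlabHeight = 5, totalLoad = 50, loadArea = 200,
                     loadCenter = NULL, fixMode = c("all", "z-rollers"),
                     loadRegion = c("auto", "any")) {
  fixMode <- match.arg(fixMode)
  loadRegion <- match.arg(loadRegion)
  z <- model@nodes[, 3]
  fixed <- which(z <= min(z) + fixedSlabHeight)
  if (!length(fixed)) stop("empty fixed set; increase fixedSlabHeight")
  bf <- cpp_boundary_faces(model@nodes, model@elements)
  faceRegion <- model@elementRegion[bf$element]
  v1 <- model@nodes[bf$faces[, 1], , drop = FALSE]
  v2 <- model@nodes[bf$faces[, 2], , drop = FALSE]
  v3 <- model@nodes[bf$faces[, 3], , drop = FALSE]
  cr <- cbind((v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) - (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
              (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) - (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
              (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) - (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1]))
  area <- sqrt(rowSums(cr^2)) / 2
  nrm <- cr / pmax(2 * area, 1e-30)
  centroid <- (v1 + v2 + v3) / 3
  # faces lying on the refinement-box planes are internal fine/coarse
  # interface, not free surface; exclude them from load candidates
  internal <- rep(FALSE, nrow(centroid))
  if (length(model@refineBox) == 6) {
    bLo <- model@refineBox[1:3]
    bHi <- model@refineBox[4:6]
    inRect <- centroid[, 1] >= bLo[1] - 1e-9 & centroid[, 1] <= bHi[1] + 1e-9 &
      centroid[, 2] >= bLo[2] - 1e-9 & centroid[, 2] <= bHi[2] + 1e-9 &
      centroid[, 3] >= bLo[3] - 1e-9 & centroid[, 3] <= bHi[3] + 1e-9
    onPlane <- abs(centroid[, 1] - bLo[1]) < 1e-9 | abs(centroid[, 1] - bHi[1]) < 1e-9 |
      abs(centroid[, 2] - bLo[2]) < 1e-9 | abs(centroid[, 2] - bHi[2]) < 1e-9 |
      abs(centroid[, 3] - bLo[3]) < 1e-9 | abs(centroid[, 3] - bHi[3]) < 1e-9
    internal <- inRect & onPlane
  }
  upper <- if (loadRegion == "any") !internal & nrm[, 3] > 0.3
  else {
    reg <- if (any(model@elementRegion == 2L)) 2L else 1L
    !internal & faceRegion == reg & nrm[, 3] > 0.3
  }
  if (!any(upper)) stop("no upward-facing surface found for the load patch")
  if (is.null(loadCenter)) {
    loadCenter <- c(sum(centroid[upper, 1] * area[upper]),
                    sum(centroid[upper, 2] * area[upper])) / sum(area[upper])
  }
  d2 <- (centroid[, 1] - loadCenter[1])^2 + (centroid[, 2] - loadCenter[2])^2
  cand <- which(upper)
  cand <- cand[order(d2[cand])]
  cum <- cumsum(area[cand])
  nPatch <- max(1L, sum(cum < loadArea) + 1L)
  nPatch <- min(nPatch, length(cand))
  patch <- cand[seq_len(nPatch)]
  realized <- sum(area[patch])
  pressure <- totalLoad / realized
  loads <- matrix(0, nrow(model@nodes), 3)
  for (q in patch) {
    fvec <- -nrm[q, ] * pressure * area[q] / 3
    for (k in 1:3) loads[bf$faces[q, k], ] <- loads[bf$faces[q, k], ] + fvec
  }
  if (fixMode == "all") {
    model@fixedNodes <- as.integer(fixed)
    model@fixedDofs <- integer(0)
  } else {
    # rollers: z fixed over the slab, plus a statically determinate set of
    # lateral restraints so uniform fields stay stress-free laterally
    model@fixedNodes <- integer(0)
    a <- fixed[which.min(model@nodes[fixed, 1] + model@nodes[fixed, 2])]
    b <- fixed[which.max(abs(model@nodes[fixed, 1] - model@nodes[a, 1]))]
    model@fixedDofs <- as.integer(c(3L * (fixed - 1L) + 3L,
                                    3L * (a - 1L) + 1L, 3L * (a - 1L) + 2L,
                                    3L * (b - 1L) + 2L))
  }
  model@loads <- loads
  attr(model@loads, "realizedArea") <- realized
  attr(model@loads, "patchCenter") <- loadCenter
  model
}

# per-element material vectors from region codes
.elementMaterials <- function(model, materials) {
  reg <- model@elementRegion
  key <- ifelse(reg == 1L, "skull", ifelse(reg == 2L, "implant", "screw"))
  E <- vapply(key, function(k) materials[[k]]@youngsModulus, numeric(1))
  nu <- vapply(key, function(k) materials[[k]]@poissonRatio, numeric(1))
  list(E = unname(E), nu = unname(nu), key = unname(key))
}

#' Solve the linear static problem
#'
#' Assembles the tet4 isotropic stiffness, eliminates the fixed degrees of
#' freedom, solves the sparse symmetric positive-definite system by
#' Cholesky factorisation, and recovers per-element constant stress, von
#' Mises stress and the global equilibrium residual.
#'
#' @param model an [FEModel-class] with boundary conditions applied
#' @param materials material table (see [defaultMaterials()])
#' @return an [FEAResult-class]
#' @export
solveLinearStatic <- function(model, materials = defaultMaterials()) {
  if (!length(model@fixedNodes) && !length(model@fixedDofs))
    stop("model has no fixed dofs; apply BCs first")
  if (!any(model@loads != 0)) warning("load vector is identically zero")
  n <- nrow(model@nodes)
  mat <- .elementMaterials(model, materials)
  # dof expansion T: fixed dofs map to nothing, hanging dofs to their two
  # masters with weight 1/2, every other dof to itself
  fixedDofMask <- logical(3L * n)
  if (length(model@fixedNodes))
    fixedDofMask[rep((model@fixedNodes - 1L) * 3L, each = 3) + 1:3] <- TRUE
  if (length(model@fixedDofs)) fixedDofMask[model@fixedDofs] <- TRUE
  hangDofMask <- logical(3L * n)
  cons <- model@constraints
  if (nrow(cons)) hangDofMask[rep((cons[, 1] - 1L) * 3L, each = 3) + 1:3] <- TRUE
  freeDof <- !fixedDofMask & !hangDofMask
  redOfDof <- integer(3L * n)
  redOfDof[freeDof] <- seq_len(sum(freeDof))
  nFree <- sum(freeDof)
  # CSR rows over global dofs (node-major, components 1..3)
  cnt <- integer(3L * n)
  cnt[freeDof] <- 1L
  if (nrow(cons)) {
    for (comp in 1:3) {
      hdof <- (cons[, 1] - 1L) * 3L + comp
      cnt[hdof] <- freeDof[(cons[, 2] - 1L) * 3L + comp] +
        freeDof[(cons[, 3] - 1L) * 3L + comp]
    }
  }
  expStart <- c(0L, cumsum(cnt))
  expIdx <- integer(expStart[length(expStart)])
  expW <- numeric(length(expIdx))
  pos <- expStart[which(freeDof)] + 1L
  expIdx[pos] <- redOfDof[freeDof]
  expW[pos] <- 1
  if (nrow(cons)) {
    for (r in seq_len(nrow(cons))) {
      for (comp in 1:3) {
        d <- (cons[r, 1] - 1L) * 3L + comp
        p <- expStart[d] + 1L
        for (m in 2:3) {
          md <- (cons[r, m] - 1L) * 3L + comp
          if (!freeDof[md]) next
          expIdx[p] <- redOfDof[md]
          expW[p] <- 0.5
          p <- p + 1L
        }
      }
    }
  }
  # chunked assembly keeps the raw triplet lists bounded; duplicate entries
  # are summed on conversion, and the chunk sums accumulate sparse
  ne <- nrow(model@elements)
  chunk <- 150000L
  K <- NULL
  for (start in seq(1L, ne, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ne)
    tr <- cpp_tet_assemble(model@nodes, model@elements[idx, , drop = FALSE],
                           mat$E[idx], mat$nu[idx], expStart, expIdx, expW)
    Kc <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                               dims = c(nFree, nFree), symmetric = TRUE)
    rm(tr)
    K <- if (is.null(K)) Kc else K + Kc
    rm(Kc)
  }
  gc(FALSE)
  # reduced load vector f_red = T' f
  la <- as.vector(t(model@loads))
  nper <- diff(expStart)
  srcDof <- rep.int(seq_len(3L * n), nper)
  f <- tapplySum(expW * la[srcDof], expIdx, nFree)
  u <- tryCatch(
    as.vector(Matrix::solve(Matrix::Cholesky(K, LDL = FALSE, super = TRUE), f)),
    error = function(e)
      stop("stiffness factorisation failed (", conditionMessage(e),
           "); a part of the assembly may be free-floating", call. = FALSE))
  rm(K)
  # full displacement field u_full = T u_red
  U <- tapplySum(expW * u[expIdx], srcDof, 3L * n)
  U <- matrix(U, n, 3, byrow = TRUE)
  st <- cpp_tet_stress(model@nodes, model@elements, mat$E, mat$nu, U)
  Fint <- cpp_internal_forces(model@nodes, model@elements, mat$E, mat$nu, U)
  applied <- colSums(model@loads)
  rm_ <- Fint - model@loads
  fixedMat <- matrix(fixedDofMask, n, 3, byrow = TRUE)
  reactions <- colSums(rm_ * fixedMat)
  denom <- max(sqrt(sum(applied^2)), 1e-12)
  residual <- sqrt(sum((reactions + applied)^2)) / denom
  disp <- sqrt(rowSums(U^2))
  new("FEAResult", displacements = U, elementStress = st$stress,
      elementVonMises = st$von_mises, maxVonMises = max(st$von_mises),
      maxDisplacement = max(disp), reactionResidual = residual)
}

#' Von Mises equivalent stress
#'
#' @param stress a symmetric 3 x 3 stress tensor, or a length-6 vector
#'   (xx, yy, zz, xy, yz, zx), MPa
#' @return scalar MPa
#' @export
vonMises <- function(stress) {
  if (is.matrix(stress)) {
    if (!all(dim(stress) == c(3, 3)) || max(abs(stress - t(stress))) > 1e-8)
      stop("stress must be a symmetric 3 x 3 tensor")
    s <- c(stress[1, 1], stress[2, 2], stress[3, 3],
           stress[1, 2], stress[2, 3], stress[3, 1])
  } else {
    if (length(stress) != 6) stop("stress vector must have 6 components")
    s <- stress
  }
  sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2) +
         3 * (s[4]^2 + s[5]^2 + s[6]^2))
}

#' Summarise an FE solution against material limits
#'
#' Per-region maximum von Mises stress, safety factor (yield / max stress)
#' and pass/fail, plus the global maximum displacement.
#'
#' @param result an [FEAResult-class]
#' @param model the [FEModel-class] it was solved from
#' @param materials material table
#' @return a list: per-region rows in `$regions`, global `$maxDisplacement`,
#'   overall `$pass`
#' @export
summarizeFEA <- function(result, model, materials = defaultMaterials()) {
  mat <- .elementMaterials(model, materials)
  regs <- sort(unique(model@elementRegion))
  rows <- lapply(regs, function(r) {
    sel <- model@elementRegion == r
    key <- mat$key[which(sel)[1]]
    mx <- if (any(sel)) max(result@elementVonMises[sel]) else 0
    yield <- materials[[key]]@yieldStrength
    data.frame(region = r,
               label = if (r <= length(model@regionLabels)) model@regionLabels[r] else key,
               material = key, maxVonMises = mx, yield = yield,
               safetyFactor = if (mx > 0) yield / mx else Inf,
               pass = mx < yield)
  })
  regions <- do.call(rbind, rows)
  list(regions = regions, maxDisplacement = result@maxDisplacement,
       equilibriumResidual = result@reactionResidual,
       pass = all(regions$pass))
}

setMethod("show", "FEModel", function(object) {
  cat(sprintf("FEModel: %d nodes, %d tet4 elements, voxel %.2f mm\n",
              nrow(object@nodes), nrow(object@elements), object@voxelSize))
  tab <- table(object@elementRegion)
  lbl <- object@regionLabels[as.integer(names(tab))]
  cat("  regions:", paste(sprintf("%s=%d", lbl, tab), collapse = ", "), "\n")
  cat(sprintf("  fixed nodes: %d, loaded nodes: %d\n", length(object@fixedNodes),
              sum(rowSums(abs(object@loads)) > 0)))
})

setMethod("show", "FEAResult", function(object) {
  cat(sprintf("FEAResult: max von Mises %.3f MPa, max displacement %.4g mm\n",
              object@maxVonMises, object@maxDisplacement))
  cat(sprintf("  equilibrium residual: %.2e\n", object@reactionResidual))
})
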