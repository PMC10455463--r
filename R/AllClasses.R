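#' Triangle surface mesh
#'
#' The currency of every geometry stage: vertices in mm, 1-based face
#' indices, per-face outward orientation for closed solids.  `faceTags`
#' optionally labels faces by provenance (e.g. the offset shell tags its
#' top / bottom / side-wall faces) and is either empty or one integer per
#' face.
#'
#' @slot vertices numeric matrix, n x 3, mm
#' @slot faces integer matrix, m x 3, 1-based vertex indices
#' @slot faceTags integer vector of length 0 or m
#' @export
setClass("TriMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  faceTags = "integer"
))

setValidity("TriMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3) return("vertices must be an n x 3 numeric matrix")
  if (!is.integer(f) || ncol(f) != 3) return("faces must be an m x 3 integer matrix")
  if (anyNA(v) || any(!is.finite(v))) return("vertices contain non-finite values")
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v)) return("face indices out of range")
  }
  if (length(object@faceTags) != 0 && length(object@faceTags) != nrow(f))
    return("faceTags must be empty or one per face")
  TRUE
})

#' Construct a TriMesh
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param faces m x 3 matrix of 1-based vertex indices
#' @param faceTags optional integer vector, one tag per face
#' @return a [TriMesh-class] object
#' @export
TriMesh <- function(vertices, faces, faceTags = integer(0)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("TriMesh", vertices = vertices, faces = faces, faceTags = as.integer(faceTags))
}

#' CT-like image volume
#'
#' A scalar voxel grid with physical geometry: `world = origin + index *
#' spacing` with 0-based voxel indices, intensities on a Hounsfield-unit-like
#' scale.
#'
#' @slot intensities 3-d numeric array
#' @slot spacing mm per voxel along each axis (all > 0)
#' @slot origin world position (mm) of the centre of voxel (0,0,0)
#' @export
setClass("ImageVolume", representation(
  intensities = "array",
  spacing = "numeric",
  origin = "numeric"
))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@intensities)) != 3) return("intensities must be a 3-d array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be three positive values")
  if (length(object@origin) != 3) return("origin must be length 3")
  TRUE
})

#' @rdname ImageVolume-class
#' @param intensities 3-d numeric array
#' @param spacing mm per voxel (length 3, or scalar recycled)
#' @param origin world mm of voxel (0,0,0) centre
#' @export
ImageVolume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("ImageVolume", intensities = intensities, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Binary segmentation mask aligned to an ImageVolume
#'
#' @slot mask 3-d logical array
#' @slot spacing,origin grid geometry, identical to the source volume
#' @export
setClass("BinaryMask", representation(
  mask = "array",
  spacing = "numeric",
  origin = "numeric"
))

setValidity("BinaryMask", function(object) {
  if (length(dim(object@mask)) != 3) return("mask must be a 3-d array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be three positive values")
  TRUE
})

#' @rdname BinaryMask-class
#' @param mask 3-d logical array
#' @param spacing,origin grid geometry
#' @export
BinaryMask <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("BinaryMask", mask = mask, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Oriented plane (point + unit normal)
#'
#' @slot point a point on the plane (mm)
#' @slot normal unit normal
#' @export
setClass("Plane", representation(point = "numeric", normal = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@point) != 3 || length(object@normal) != 3)
    return("point and normal must be length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be unit length")
  TRUE
})

#' @rdname Plane-class
#' @param point a point on the plane
#' @param normal plane normal (normalised internally)
#' @export
Plane <- function(point, normal) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("normal must be non-zero")
  new("Plane", point = as.numeric(point), normal = normal / nn)
}

#' Rigid-body transform (proper rotation + translation)
#'
#' @slot rotation 3 x 3 orthonormal matrix with det = +1
#' @slot translation mm triple
#' @export
setClass("RigidTransform", representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation must be orthonormal")
  if (det(R) < 0) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3) return("translation must be length 3")
  TRUE
})

#' @rdname RigidTransform-class
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 translation (mm)
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Synthetic skull phantom specification
#'
#' An ellipsoid shell standing in for a clean, bilaterally symmetric skull:
#' outer semi-axes, uniform shell thickness, an optional smooth asymmetry
#' bump field restricted to the left (x < 0) side, and the segmental defect
#' to be carved.  With `asymmetryAmplitude = 0` the phantom is exactly
#' mirror-symmetric about the plane x = 0, which is the property the mirror
#' reconstruction stage exploits.
#'
#' @slot outerRadii ellipsoid semi-axes (mm): lateral, antero-posterior, vertical
#' @slot shellThickness uniform wall thickness (mm)
#' @slot asymmetryAmplitude RMS amplitude of the left-side bump field (mm)
#' @slot defectCenter,defectRadius the spherical resection (mm)
#' @slot seed integer seed controlling the bump field
#' @export
setClass("PhantomSpec", representation(
  outerRadii = "numeric",
  shellThickness = "numeric",
  asymmetryAmplitude = "numeric",
  defectCenter = "numeric",
  defectRadius = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  if (length(object@outerRadii) != 3 || any(object@outerRadii <= 0))
    return("outerRadii must be three positive semi-axes")
  if (object@shellThickness <= 0 || object@shellThickness >= min(object@outerRadii))
    return("shellThickness must be positive and smaller than the smallest semi-axis")
  if (object@asymmetryAmplitude < 0) return("asymmetryAmplitude must be >= 0")
  if (object@defectRadius <= 0) return("defectRadius must be positive")
  if (length(object@defectCenter) != 3) return("defectCenter must be length 3")
  TRUE
})

#' @rdname PhantomSpec-class
#' @param outerRadii,shellThickness,asymmetryAmplitude,defectCenter,defectRadius,seed
#'   see the class slots
#' @export
PhantomSpec <- function(outerRadii = c(90, 70, 60), shellThickness = 6,
                        asymmetryAmplitude = 0,
                        defectCenter = c(-65, 15, 39), defectRadius = 30,
                        seed = 1L) {
  new("PhantomSpec", outerRadii = as.numeric(outerRadii),
      shellThickness = as.numeric(shellThickness),
      asymmetryAmplitude = as.numeric(asymmetryAmplitude),
      defectCenter = as.numeric(defectCenter),
      defectRadius = as.numeric(defectRadius), seed = as.integer(seed))
}

#' Diamond-lattice specification
#'
#' Unit-cell parameters of the porous scaffold: a diamond (tetrahedral bond
#' topology) cell of edge `cellSize`, cylindrical struts of `strutRadius`,
#' aiming at `targetPorosity` void fraction.
#'
#' @slot cellType only "diamond" is supported
#' @slot cellSize unit-cell edge (mm)
#' @slot strutRadius strut cylinder radius (mm)
#' @slot targetPorosity void fraction in (0, 1)
#' @export
setClass("LatticeSpec", representation(
  cellType = "character",
  cellSize = "numeric",
  strutRadius = "numeric",
  targetPorosity = "numeric"
))

setValidity("LatticeSpec", function(object) {
  if (!identical(object@cellType, "diamond")) return("cellType must be 'diamond'")
  if (object@cellSize <= 0) return("cellSize must be positive")
  if (object@strutRadius <= 0 || object@strutRadius >= object@cellSize / 2)
    return("strutRadius must satisfy 0 < strutRadius < cellSize / 2")
  if (object@targetPorosity <= 0 || object@targetPorosity >= 1)
    return("targetPorosity must be in (0, 1)")
  TRUE
})

#' @rdname LatticeSpec-class
#' @param cellSize,strutRadius,targetPorosity see the class slots
#' @export
LatticeSpec <- function(cellSize = 2.5, strutRadius = 0.5, targetPorosity = 0.70) {
  new("LatticeSpec", cellType = "diamond", cellSize = as.numeric(cellSize),
      strutRadius = as.numeric(strutRadius), targetPorosity = as.numeric(targetPorosity))
}

#' Designed implant model
#'
#' The assembled implant: solid fixation rim, porous (diamond scaffold)
#' core, screw-hole centres, and the two volumes entering the porosity
#' formula -- `bulkVolume` (V1, solid envelope of the scaffolded region) and
#' `scaffoldVolume` (V2, material actually present).
#'
#' @slot solidRim,porousCore,scaffold TriMesh parts
#' @slot screwHoleCenters 4 x 3 matrix (mm)
#' @slot bulkVolume,scaffoldVolume mm^3
#' @slot lattice the LatticeSpec actually used (solved strut radius)
#' @export
setClass("ImplantModel", representation(
  solidRim = "TriMesh",
  porousCore = "TriMesh",
  scaffold = "TriMesh",
  screwHoleCenters = "matrix",
  bulkVolume = "numeric",
  scaffoldVolume = "numeric",
  lattice = "LatticeSpec"
))

setValidity("ImplantModel", function(object) {
  if (object@bulkVolume <= 0) return("bulkVolume must be positive")
  if (object@scaffoldVolume <= 0) return("scaffoldVolume must be positive")
  if (object@scaffoldVolume >= object@bulkVolume)
    return("scaffoldVolume must be smaller than bulkVolume")
  TRUE
})

#' Isotropic material properties (mm-N-MPa unit system)
#'
#' @slot youngsModulus MPa
#' @slot poissonRatio dimensionless, in (0, 0.5)
#' @slot yieldStrength MPa
#' @export
setClass("MaterialProps", representation(
  youngsModulus = "numeric",
  poissonRatio = "numeric",
  yieldStrength = "numeric"
))

setValidity("MaterialProps", function(object) {
  if (object@youngsModulus <= 0) return("youngsModulus must be positive")
  if (object@poissonRatio <= 0 || object@poissonRatio >= 0.5)
    return("poissonRatio must be in (0, 0.5)")
  if (object@yieldStrength <= 0) return("yieldStrength must be positive")
  TRUE
})

#' @rdname MaterialProps-class
#' @param youngsModulus,poissonRatio,yieldStrength see the class slots
#' @export
MaterialProps <- function(youngsModulus, poissonRatio, yieldStrength) {
  new("MaterialProps", youngsModulus = as.numeric(youngsModulus),
      poissonRatio = as.numeric(poissonRatio), yieldStrength = as.numeric(yieldStrength))
}

#' Tetrahedral finite-element model
#'
#' Linear (tet4) elasticity problem: node coordinates, elements, per-element
#' region labels (1 = skull, 2 = implant, 3+ = screws), Dirichlet set and
#' nodal load vector.  Regions meshed on the common voxel grid share
#' interface nodes, realising bonded contact.
#'
#' @slot nodes n x 3 mm
#' @slot elements m x 4 integer, 1-based
#' @slot elementRegion integer per element
#' @slot regionLabels names for region codes
#' @slot fixedNodes integer node indices (all dof fixed)
#' @slot fixedDofs integer global dof indices (3*(node-1)+component) fixed
#'   individually, e.g. roller supports in verification problems
#' @slot loads n x 3 nodal forces (N)
#' @slot voxelSize fine grid pitch used (mm)
#' @slot constraints k x 3 integer matrix of hanging-node ties (node,
#'   masterA, masterB): each hanging node on the fine/coarse interface is
#'   constrained to the average of its two master nodes, which reproduces
#'   the coarse element's linear field exactly
#' @slot refineBox numeric of length 0 (uniform grid) or 6 (lo, hi corners
#'   of the fine-grid box, mm); faces on its planes are internal interface,
#'   not free surface
#' @export
setClass("FEModel", representation(
  nodes = "matrix",
  elements = "matrix",
  elementRegion = "integer",
  regionLabels = "character",
  fixedNodes = "integer",
  fixedDofs = "integer",
  loads = "matrix",
  voxelSize = "numeric",
  constraints = "matrix",
  refineBox = "numeric"
))

setValidity("FEModel", function(object) {
  if (ncol(object@nodes) != 3) return("nodes must be n x 3")
  if (ncol(object@elements) != 4) return("elements must be m x 4")
  if (length(object@elementRegion) != nrow(object@elements))
    return("one region label per element")
  if (nrow(object@loads) != 0 && nrow(object@loads) != nrow(object@nodes))
    return("loads must be empty or n x 3")
  if (anyNA(object@loads) || any(!is.finite(object@loads)))
    return("loads must be finite")
  TRUE
})

#' Finite-element solution
#'
#' @slot displacements n x 3 mm
#' @slot elementStress m x 6 MPa (xx, yy, zz, xy, yz, zx)
#' @slot elementVonMises MPa per element
#' @slot maxVonMises,maxDisplacement scalars
#' @slot reactionResidual relative equilibrium residual
#' @export
setClass("FEAResult", representation(
  displacements = "matrix",
  elementStress = "matrix",
  elementVonMises = "numeric",
  maxVonMises = "numeric",
  maxDisplacement = "numeric",
  reactionResidual = "numeric"
))

#' Fitting-accuracy deviation report
#'
#' Mean outward deviation statistics and the decomposition of total fitting
#' accuracy into a modeling (mirror-reconstruction) and a manufacturing
#' component.  `totalAsSum` is modeling + manufacturing (the decomposition
#' convention); `totalDirect` is the directly measured scanned-vs-clean
#' deviation.
#'
#' @slot meanOutward,meanSigned,fractionPositive summary statistics (mm)
#' @slot modelingComponent,manufacturingComponent,totalAsSum,totalDirect mm
#' @slot roiDeviation mm (NA when not computed)
#' @slot deviations per-point signed distances (mm)
#' @export
setClass("DeviationReport", representation(
  meanOutward = "numeric",
  meanSigned = "numeric",
  fractionPositive = "numeric",
  modelingComponent = "numeric",
  manufacturingComponent = "numeric",
  totalAsSum = "numeric",
  totalDirect = "numeric",
  roiDeviation = "numeric",
  deviations = "numeric"
))

#' Gap-analysis report
#'
#' Axis-aligned extents of the implant and of the defect cavity opening,
#' and the per-axis gap (cavity minus implant).
#'
#' @slot implantExtent,cavityExtent,gap named numeric (x, y), mm
#' @export
setClass("GapReport", representation(
  implantExtent = "numeric",
  cavityExtent = "numeric",
  gap = "numeric"
))

#' Mean-aesthetic-score hypothesis test result
#'
#' One-sided one-sample t-test of H0: MAS <= mu0 against Ha: MAS > mu0.
#'
#' @slot mas grand mean aesthetic score
#' @slot tStatistic,pValue test quantities (p one-sided upper tail)
#' @slot rejectNull decision at the chosen alpha
#' @slot n number of observations (experts by default)
#' @slot alpha,mu0 test settings
#' @slot degenerate TRUE when the scores had zero variance
#' @export
setClass("MASResult", representation(
  mas = "numeric",
  tStatistic = "numeric",
  pValue = "numeric",
  rejectNull = "logical",
  n = "integer",
  alpha = "numeric",
  mu0 = "numeric",
  degenerate = "logical"
))
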