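#' @name cranioforge-generics
#' @title Generics for mesh and volume objects
#' @description Accessors and basic measures for the geometry classes.
#' @param x object
#' @param ... further arguments for methods
NULL

#' @rdname cranioforge-generics
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname cranioforge-generics
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname cranioforge-generics
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname cranioforge-generics
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname cranioforge-generics
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))

#' @rdname cranioforge-generics
#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' Signed volume of a closed triangle mesh
#'
#' Divergence-theorem volume; positive for consistently outward-oriented
#' solids.  Errors on open meshes; a negative value (inverted orientation)
#' is returned with a warning so callers can flag it.
#'
#' @param x a [TriMesh-class]
#' @param ... unused
#' @return volume in mm^3
#' @export
setGeneric("meshVolume", function(x, ...) standardGeneric("meshVolume"))

#' Apply a rigid transform
#'
#' @param transform a [RigidTransform-class]
#' @param x points (n x 3 matrix) or a [TriMesh-class]
#' @return transformed object of the same kind
#' @export
setGeneric("applyTransform", function(transform, x) standardGeneric("applyTransform"))
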