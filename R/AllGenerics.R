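#' @import methods
NULL

#' Voxel spacing accessor
#'
#' Physical voxel spacing in micrometers, one value per axis (x, y, z).
#'
#' @param x A \linkS4class{Volume3D}, \linkS4class{BinaryMask} or derived
#'   object.
#' @return Numeric vector of length 3 (micrometers).
#' @export
setGeneric("spacingUm", function(x) standardGeneric("spacingUm"))

#' Voxel data accessor
#'
#' The underlying 3D array of a volume-like object (numeric for grayscale
#' volumes and distance/radius maps, logical for masks and skeletons).
#'
#' @param x A \linkS4class{Volume3D}, \linkS4class{BinaryMask} or derived
#'   object.
#' @return A 3D array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Graph component accessors
#'
#' @param x A \linkS4class{VesselGraph} or \linkS4class{GroundTruthGraph}.
#' @return \code{graphNodes} and \code{graphSegments} return data frames;
#'   \code{segmentPolylines} returns a list of per-segment centerline
#'   coordinate matrices.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graph-accessors
#' @export
setGeneric("graphSegments", function(x) standardGeneric("graphSegments"))

#' @rdname graph-accessors
#' @export
setGeneric("segmentPolylines", function(x) standardGeneric("segmentPolylines"))
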