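# Central S4 classes for the morphometry pipeline.

.checkSpacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing))
    return("spacing must be a numeric vector of length 3 (x, y, z)")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    return("all voxel spacings must be finite and > 0")
  NULL
}

#' Volume3D: a 3D grayscale image volume
#'
#' A 3D scalar intensity grid with per-axis voxel spacing in micrometers.
#' Axes are (x, y, z) with z the rostro-caudal (longitudinal) axis; physical
#' position of a voxel is its 0-based index times the spacing (voxel-center
#' convention).
#'
#' @slot values 3D numeric array of intensities.
#' @slot spacing Numeric length-3, voxel spacing in micrometers per axis.
#' @export
setClass("Volume3D",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L)
      return("values must be a 3D array")
    if (!is.numeric(object@values))
      return("values must be numeric")
    msg <- .checkSpacing(object@spacing)
    if (!is.null(msg)) return(msg)
    if (anyNA(object@values) || any(!is.finite(object@values)))
      return("intensities must all be finite")
    TRUE
  }
)

#' @describeIn Volume3D Constructor.
#' @param values 3D numeric array.
#' @param spacingUm voxel spacing in micrometers; a scalar is recycled to all
#'   three axes. Default 3.7 um isotropic.
#' @return A \code{Volume3D} object.
#' @export
Volume3D <- function(values, spacingUm = 3.7) {
  if (length(spacingUm) == 1L) spacingUm <- rep(spacingUm, 3L)
  new("Volume3D", values = values, spacing = as.numeric(spacingUm))
}

#' BinaryMask: a 3D boolean vessel/background mask
#'
#' @slot values 3D logical array (TRUE = vessel / foreground).
#' @slot spacing Numeric length-3, voxel spacing in micrometers.
#' @export
setClass("BinaryMask",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L)
      return("values must be a 3D array")
    if (!is.logical(object@values))
      return("mask values must be logical")
    if (anyNA(object@values))
      return("mask values must not contain NA")
    msg <- .checkSpacing(object@spacing)
    if (!is.null(msg)) return(msg)
    TRUE
  }
)

#' @describeIn BinaryMask Constructor.
#' @param values 3D logical array.
#' @param spacingUm voxel spacing in micrometers (scalar recycled).
#' @return A \code{BinaryMask} object.
#' @export
BinaryMask <- function(values, spacingUm = 3.7) {
  if (length(spacingUm) == 1L) spacingUm <- rep(spacingUm, 3L)
  storage.mode(values) <- "logical"
  new("BinaryMask", values = values, spacing = as.numeric(spacingUm))
}

#' DistanceMap: Euclidean distance to the background
#'
#' A \linkS4class{Volume3D} whose values are, at every foreground voxel, the
#' Euclidean distance (micrometers) from the voxel center to the nearest
#' background voxel center; zero on background.
#' @export
setClass("DistanceMap", contains = "Volume3D")

#' Skeleton3D: a one-voxel-thick centerline set
#'
#' A \linkS4class{BinaryMask} produced by topology-preserving thinning; TRUE
#' voxels form the vascular centerlines.
#' @export
setClass("Skeleton3D", contains = "BinaryMask")

#' RadiusMap: per-skeleton-voxel radius
#'
#' A \linkS4class{Volume3D} holding, at every skeleton voxel, the local
#' vessel radius in micrometers (the distance-map value there) and zero
#' elsewhere.
#' @export
setClass("RadiusMap", contains = "Volume3D")

#' ROI3D: an axis-aligned region of interest
#'
#' Voxel box, half-open on every axis: voxel index i (0-based) is inside iff
#' \code{lo[a] <= i[a] < hi[a]} for all axes. Tiling a volume with disjoint
#' ROIs therefore partitions its voxels exactly.
#'
#' @slot lo Integer length-3, inclusive lower corner (0-based voxel index).
#' @slot hi Integer length-3, exclusive upper corner.
#' @export
setClass("ROI3D",
  representation(lo = "integer", hi = "integer"),
  validity = function(object) {
    if (length(object@lo) != 3L || length(object@hi) != 3L)
      return("lo and hi must have length 3")
    if (any(object@lo < 0L)) return("lo must be >= 0")
    if (any(object@lo >= object@hi)) return("lo must be < hi on every axis")
    TRUE
  }
)

#' @describeIn ROI3D Constructor.
#' @param lo,hi integer corners (0-based, half-open \code{[lo, hi)}).
#' @return An \code{ROI3D} object.
#' @export
ROI3D <- function(lo, hi) {
  new("ROI3D", lo = as.integer(lo), hi = as.integer(hi))
}

#' ThresholdResult: outcome of iterative thresholding
#'
#' @slot threshold Final threshold gray value.
#' @slot iterations Number of update iterations performed.
#' @slot history Numeric vector of thresholds per iteration (starting value
#'   included).
#' @export
setClass("ThresholdResult",
  representation(threshold = "numeric", iterations = "integer",
                 history = "numeric"))

#' PhantomSpec: parameters of the synthetic vascular phantom
#'
#' Describes a branching, contrast-perfused vascular tree on a darker
#' parenchymal background, emulating synchrotron micro-CT angiography of the
#' spinal cord: a longitudinal trunk vessel (rostro-caudal, +z = rostral)
#' that bifurcates into progressively thinner lateral branches.
#'
#' @slot gridShape Integer length-3, voxel counts per axis.
#' @slot spacingUm Numeric length-3, voxel spacing (default 3.7 isotropic).
#' @slot trunkRadiusUm Radius of the main longitudinal vessel, micrometers.
#' @slot branchLevels Integer depth of the bifurcating tree (0 = trunk only).
#' @slot branchAngleDeg Nominal parent-child angle per level, degrees.
#' @slot taperRatio Child/parent radius ratio per level, in (0, 1].
#' @slot radiusRangeUm Admissible radii; default c(3.7, 50) so diameters span
#'   7.4-100 um.
#' @slot foregroundIntensity,backgroundIntensity Gray values of vessel and
#'   parenchyma.
#' @slot noiseSigma SD of additive Gaussian noise (gray values).
#' @slot blurSigmaUm Partial-volume smoothing scale, micrometers.
#' @slot angleJitterDeg Half-width of the seeded uniform jitter added to each
#'   branch angle, degrees.
#' @slot seed Integer RNG seed for jitter and noise.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacingUm = "numeric",
                 trunkRadiusUm = "numeric", branchLevels = "integer",
                 branchAngleDeg = "numeric", taperRatio = "numeric",
                 radiusRangeUm = "numeric",
                 foregroundIntensity = "numeric",
                 backgroundIntensity = "numeric",
                 noiseSigma = "numeric", blurSigmaUm = "numeric",
                 angleJitterDeg = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
      return("gridShape must be 3 voxel counts, each >= 4")
    msg <- .checkSpacing(object@spacingUm)
    if (!is.null(msg)) return(msg)
    if (object@taperRatio <= 0 || object@taperRatio > 1)
      return("taperRatio must be in (0, 1]")
    if (length(object@radiusRangeUm) != 2L ||
        object@radiusRangeUm[1] > object@radiusRangeUm[2])
      return("radiusRangeUm must be an increasing pair")
    if (object@radiusRangeUm[1] < min(object@spacingUm))
      return("minimum admissible radius must be >= 1 voxel spacing")
    if (object@trunkRadiusUm < object@radiusRangeUm[1] ||
        object@trunkRadiusUm > object@radiusRangeUm[2])
      return("trunkRadiusUm outside radiusRangeUm")
    if (object@foregroundIntensity <= object@backgroundIntensity)
      return("foregroundIntensity must exceed backgroundIntensity")
    if (object@noiseSigma < 0 || object@blurSigmaUm < 0)
      return("noiseSigma and blurSigmaUm must be >= 0")
    if (object@branchLevels < 0L)
      return("branchLevels must be >= 0")
    TRUE
  }
)

#' InjurySpec: parameters of the cavity/displacement injury model
#'
#' Models contusion injury as a prolate ellipsoidal avascular cavity
#' elongated along the cord (spindle shape) plus a signed tilt of branches
#' near the epicenter: branches rostral of the epicenter are rotated
#' rostrally (+), branches caudal of it caudally (-).
#'
#' @slot epicenterUm Numeric length-3, cavity center in micrometers.
#' @slot cavitySemiaxesUm Numeric length-3 ellipsoid semi-axes (x, y, z);
#'   the axial (z) semi-axis must be >= the transverse ones (spindle shape),
#'   or all three zero for a no-op injury.
#' @slot tiltDeg Signed tilt added to branch directions, degrees.
#' @slot tiltExtentUm Longitudinal range around the epicenter over which the
#'   tilt applies, micrometers.
#' @export
setClass("InjurySpec",
  representation(epicenterUm = "numeric", cavitySemiaxesUm = "numeric",
                 tiltDeg = "numeric", tiltExtentUm = "numeric"),
  validity = function(object) {
    if (length(object@epicenterUm) != 3L ||
        length(object@cavitySemiaxesUm) != 3L)
      return("epicenterUm and cavitySemiaxesUm must have length 3")
    ax <- object@cavitySemiaxesUm
    if (any(ax < 0)) return("cavity semi-axes must be >= 0")
    if (any(ax > 0) && ax[3] < max(ax[1:2]))
      return("axial (z) semi-axis must be >= transverse semi-axes (spindle)")
    if (!is.finite(object@tiltDeg)) return("tiltDeg must be finite")
    if (object@tiltExtentUm < 0) return("tiltExtentUm must be >= 0")
    TRUE
  }
)

#' GroundTruthGraph: the phantom's exact vessel tree
#'
#' Known topology and geometry of a generated phantom: the oracle for
#' parameter-recovery tests. Positions are in micrometers.
#'
#' @slot nodes Data frame: id, x, y, z (um), kind ("endpoint"/"bifurcation").
#' @slot segments Data frame: id, from, to (node ids), radius_um, length_um,
#'   angle_deg (signed angle to the rostral trunk axis; + rostral, - caudal),
#'   level (0 = trunk).
#' @slot polylines Named list (by segment id) of n x 3 centerline coordinate
#'   matrices in micrometers.
#' @export
setClass("GroundTruthGraph",
  representation(nodes = "data.frame", segments = "data.frame",
                 polylines = "list"),
  validity = function(object) {
    if (nrow(object@segments) != length(object@polylines))
      return("one polyline per segment required")
    for (i in seq_along(object@polylines)) {
      P <- object@polylines[[i]]
      if (!is.matrix(P) || ncol(P) != 3L)
        return("polylines must be n x 3 matrices")
      L <- if (nrow(P) > 1)
        sum(sqrt(rowSums((P[-1, , drop = FALSE] -
                          P[-nrow(P), , drop = FALSE])^2))) else 0
      if (abs(L - object@segments$length_um[i]) > 1e-6)
        return(sprintf("segment %s: length_um differs from arc length",
                       object@segments$id[i]))
    }
    TRUE
  }
)

#' VesselGraph: the extracted vessel-tree model
#'
#' Nodes are skeleton endpoints and junction clusters; segments are
#' centerline polylines between nodes carrying length L (um), mean radius and
#' diameter VD (um). Vessel number VN is the segment count and vessel node
#' number VNN the junction count.
#'
#' @slot nodes Data frame: id, kind ("endpoint"/"junction"), degree, x, y, z
#'   (um, cluster centroid), nvox.
#' @slot segments Data frame: id, from, to, nvox, length_um, mean_radius_um,
#'   diameter_um, cyclic.
#' @slot polylines List of n x 3 integer matrices of 1-based voxel indices,
#'   one per segment, ordered from node \code{from} to node \code{to}.
#' @slot spacing Voxel spacing in micrometers.
#' @export
setClass("VesselGraph",
  representation(nodes = "data.frame", segments = "data.frame",
                 polylines = "list", spacing = "numeric"),
  validity = function(object) {
    if (nrow(object@segments) != length(object@polylines))
      return("one polyline per segment required")
    msg <- .checkSpacing(object@spacing)
    if (!is.null(msg)) return(msg)
    TRUE
  }
)

#' MorphometryReport: all morphometric read-outs for one volume/ROI
#'
#' @slot roi The \linkS4class{ROI3D} the metrics refer to.
#' @slot vvFraction Vessel volume as fractional occupancy of the ROI.
#' @slot vvMm3 Vessel volume in cubic millimeters.
#' @slot vn Vessel number (segment count).
#' @slot vnn Vessel node number (junction count).
#' @slot histBreaks,histCounts Diameter histogram (bin edges in um; per-
#'   segment counts, half-open bins).
#' @slot angles Data frame of signed bifurcation angles per segment (degrees).
#' @slot segments Per-segment table (id, length, diameter, angle, end nodes).
#' @slot cyclic TRUE if the skeleton contained node-free cycles.
#' @export
setClass("MorphometryReport",
  representation(roi = "ROI3D", vvFraction = "numeric", vvMm3 = "numeric",
                 vn = "integer", vnn = "integer", histBreaks = "numeric",
                 histCounts = "integer", angles = "data.frame",
                 segments = "data.frame", cyclic = "logical"),
  validity = function(object) {
    if (object@vvFraction < 0 || object@vvFraction > 1)
      return("vvFraction must lie in [0, 1]")
    if (object@vn < 0L || object@vnn < 0L)
      return("vn and vnn must be >= 0")
    if (length(object@histCounts) &&
        sum(object@histCounts) > object@vn)
      return("histogram counts cannot exceed the segment count")
    TRUE
  }
)
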