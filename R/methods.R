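# Accessors and show methods.

#' @rdname spacingUm
#' @export
setMethod("spacingUm", "Volume3D", function(x) x@spacing)

#' @rdname spacingUm
#' @export
setMethod("spacingUm", "BinaryMask", function(x) x@spacing)

#' @rdname spacingUm
#' @export
setMethod("spacingUm", "VesselGraph", function(x) x@spacing)

#' @rdname voxelData
#' @export
setMethod("voxelData", "Volume3D", function(x) x@values)

#' @rdname voxelData
#' @export
setMethod("voxelData", "BinaryMask", function(x) x@values)

#' @export
setMethod("dim", "Volume3D", function(x) dim(x@values))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@values))

#' @rdname graph-accessors
#' @export
setMethod("graphNodes", "VesselGraph", function(x) x@nodes)

#' @rdname graph-accessors
#' @export
setMethod("graphNodes", "GroundTruthGraph", function(x) x@nodes)

#' @rdname graph-accessors
#' @export
setMethod("graphSegments", "VesselGraph", function(x) x@segments)

#' @rdname graph-accessors
#' @export
setMethod("graphSegments", "GroundTruthGraph", function(x) x@segments)

#' @rdname graph-accessors
#' @export
setMethod("segmentPolylines", "VesselGraph", function(x) x@polylines)

#' @rdname graph-accessors
#' @export
setMethod("segmentPolylines", "GroundTruthGraph", function(x) x@polylines)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  foreground voxels: %d (%.3g%%)\n", sum(object@values),
              100 * mean(object@values)))
})

setMethod("show", "ROI3D", function(object) {
  cat(sprintf("ROI3D: [%d, %d) x [%d, %d) x [%d, %d) voxels\n",
              object@lo[1], object@hi[1], object@lo[2], object@hi[2],
              object@lo[3], object@hi[3]))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: T = %.6g after %d iterations\n",
              object@threshold, object@iterations))
})

setMethod("show", "VesselGraph", function(object) {
  nj <- sum(object@nodes$kind == "junction")
  cat(sprintf("VesselGraph: %d nodes (%d junctions), %d segments (VN = %d, VNN = %d)\n",
              nrow(object@nodes), nj, nrow(object@segments),
              nrow(object@segments), nj))
})

setMethod("show", "GroundTruthGraph", function(object) {
  cat(sprintf("GroundTruthGraph: %d nodes, %d segments, radii %.3g-%.3g um\n",
              nrow(object@nodes), nrow(object@segments),
              if (nrow(object@segments)) min(object@segments$radius_um) else NA,
              if (nrow(object@segments)) max(object@segments$radius_um) else NA))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: grid %d x %d x %d @ %.3g um, trunk r = ",
                     "%.3g um, %d branch levels @ %.3g deg, taper %.3g\n"),
              object@gridShape[1], object@gridShape[2], object@gridShape[3],
              object@spacingUm[1], object@trunkRadiusUm, object@branchLevels,
              object@branchAngleDeg, object@taperRatio))
})

setMethod("show", "InjurySpec", function(object) {
  cat(sprintf("InjurySpec: cavity %.3g x %.3g x %.3g um at (%.4g, %.4g, %.4g), tilt %+.3g deg over %.4g um\n",
              object@cavitySemiaxesUm[1], object@cavitySemiaxesUm[2],
              object@cavitySemiaxesUm[3], object@epicenterUm[1],
              object@epicenterUm[2], object@epicenterUm[3],
              object@tiltDeg, object@tiltExtentUm))
})

setMethod("show", "MorphometryReport", function(object) {
  cat("MorphometryReport\n")
  cat(sprintf("  VV: %.4g (fraction), %.6g mm^3\n",
              object@vvFraction, object@vvMm3))
  cat(sprintf("  VN: %d   VNN: %d%s\n", object@vn, object@vnn,
              if (object@cyclic) "   [cyclic skeleton]" else ""))
})
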