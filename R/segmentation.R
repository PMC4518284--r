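# Vessel segmentation: iterative (isodata / Ridler-Calvard) gray-level
# thresholding followed by a 3D size filter.

#' Iterative (isodata) gray-level threshold
#'
#' Ridler-Calvard iteration: starting from the global mean, the threshold is
#' repeatedly replaced by the average of the means of the two classes it
#' induces, \eqn{T_{k+1} = (mean(I \le T_k) + mean(I > T_k)) / 2}, until the
#' change drops below \code{tol}.
#'
#' The default tolerance is 0.5 gray value when all intensities are integral
#' (guaranteeing termination on quantized data) and \code{1e-4} times the
#' intensity range otherwise.
#'
#' @param vol A \linkS4class{Volume3D} (or plain numeric array).
#' @param tol convergence tolerance on the threshold change; \code{NULL} for
#'   the default above.
#' @param maxIter maximum number of iterations.
#' @return A \linkS4class{ThresholdResult}.
#' @export
isodataThreshold <- function(vol, tol = NULL, maxIter = 200L) {
  v <- if (is(vol, "Volume3D")) vol@values else vol
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant volume: no threshold exists")
  if (is.null(tol)) {
    tol <- if (all(v == round(v))) 0.5 else 1e-4 * (rng[2] - rng[1])
  }
  t0 <- mean(v)
  history <- t0
  for (k in seq_len(maxIter)) {
    lower <- v <= t0
    t1 <- (mean(v[lower]) + mean(v[!lower])) / 2
    if (!is.finite(t1)) t1 <- t0  # one class empty: stationary
    history <- c(history, t1)
    if (abs(t1 - t0) < tol) {
      return(new("ThresholdResult", threshold = t1, iterations = k,
                 history = history))
    }
    t0 <- t1
  }
  stop(sprintf(paste0("isodata threshold did not converge in %d iterations ",
                      "(last thresholds: %s)"), maxIter,
               paste(sprintf("%.6g", utils::tail(history, 5)), collapse = ", ")))
}

#' Binarize a volume at a threshold
#'
#' Foreground iff intensity is strictly greater than the threshold.
#'
#' @param vol A \linkS4class{Volume3D}.
#' @param threshold gray value; either a number or a
#'   \linkS4class{ThresholdResult}.
#' @return A \linkS4class{BinaryMask}.
#' @export
binarize <- function(vol, threshold) {
  stopifnot(is(vol, "Volume3D"))
  if (is(threshold, "ThresholdResult")) threshold <- threshold@threshold
  BinaryMask(vol@values > threshold, vol@spacing)
}

#' 3D connected components
#'
#' Deterministic labeling: components are numbered in raster-scan order of
#' their first voxel.
#'
#' @param mask A \linkS4class{BinaryMask} (or logical array).
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full).
#' @return A list: \code{labels} (integer array, 0 = background) and
#'   \code{sizes} (integer vector, voxel count per label).
#' @export
connectedComponents <- function(mask, connectivity = 26L) {
  v <- if (is(mask, "BinaryMask")) mask@values else mask
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  lab <- .label3d_cpp(as.logical(v), dim(v), as.integer(connectivity))
  lab <- array(lab, dim = dim(v))
  n <- max(lab)
  sizes <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  list(labels = lab, sizes = sizes)
}

#' 3D size filter
#'
#' Removes isolated foreground components smaller than \code{minVoxels}
#' voxels (26-connectivity) and then fills background cavities smaller than
#' \code{minVoxels} voxels (6-connectivity) -- the standard dual connectivity
#' pairing. "Smaller than" is strict: components of exactly \code{minVoxels}
#' voxels survive. The operation is idempotent.
#'
#' @param mask A \linkS4class{BinaryMask}.
#' @param minVoxels minimum component size kept (default 3).
#' @param fgConnectivity,bgConnectivity connectivities for the foreground
#'   removal and background fill passes.
#' @return A filtered \linkS4class{BinaryMask}.
#' @export
sizeFilter <- function(mask, minVoxels = 3L, fgConnectivity = 26L,
                       bgConnectivity = 6L) {
  stopifnot(is(mask, "BinaryMask"), minVoxels >= 1L)
  v <- mask@values
  cc <- connectedComponents(v, fgConnectivity)
  small <- which(cc$sizes < minVoxels)
  if (length(small)) v[cc$labels %in% small] <- FALSE
  ccb <- connectedComponents(!v, bgConnectivity)
  smallb <- which(ccb$sizes < minVoxels)
  if (length(smallb)) v[ccb$labels %in% smallb] <- TRUE
  BinaryMask(v, mask@spacing)
}

#' Segment a volume end to end
#'
#' Convenience wrapper: optional Gaussian pre-smoothing (denoising), isodata
#' thresholding, binarization and the 3-voxel size filter.
#'
#' @param vol A \linkS4class{Volume3D}.
#' @param presmoothSigmaUm SD of an optional Gaussian denoising filter in
#'   micrometers (0 = off). For noisy tomograms a value near one voxel
#'   suppresses single-voxel noise excursions before thresholding.
#' @param minVoxels size-filter threshold (default 3).
#' @param threshold optional fixed threshold; \code{NULL} to use isodata.
#' @param ... passed to \code{\link{isodataThreshold}}.
#' @return A list: \code{mask} (\linkS4class{BinaryMask}), \code{threshold}
#'   (\linkS4class{ThresholdResult} or the fixed value), and
#'   \code{smoothed} (the volume actually thresholded).
#' @export
segmentVolume <- function(vol, presmoothSigmaUm = 0, minVoxels = 3L,
                          threshold = NULL, ...) {
  stopifnot(is(vol, "Volume3D"))
  v <- vol
  if (presmoothSigmaUm > 0) {
    d <- dim(vol@values)
    sig <- presmoothSigmaUm / vol@spacing
    v <- Volume3D(array(.gaussian_blur3d_cpp(as.numeric(vol@values), d, sig),
                        dim = d), vol@spacing)
  }
  thr <- if (is.null(threshold)) isodataThreshold(v, ...) else threshold
  mask <- binarize(v, thr)
  mask <- sizeFilter(mask, minVoxels = minVoxels)
  list(mask = mask, threshold = thr, smoothed = v)
}
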