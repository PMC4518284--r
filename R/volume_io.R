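# Volume, graph and table IO.
#
# Conventions: array axes are (x, y, z), z = rostro-caudal; a TIFF page
# stores one z slice with rows = y and columns = x; physical position of a
# voxel is its 0-based index times the spacing (voxel-center convention).
# Masks on disk are 8-bit with 0 = background, 255 = vessel. TIFF carries
# spacing in a JSON sidecar ("<file>.meta.json"); NIfTI carries it in the
# header (pixdim); raw binary requires a "<file>.json" sidecar. NIfTI
# orientation metadata beyond spacing is ignored.

.metaPath <- function(path) paste0(path, ".meta.json")

#' Read a 3D volume
#'
#' Supported formats by extension: multi-page TIFF (\code{.tif/.tiff}),
#' NIfTI (\code{.nii/.nii.gz}), and raw binary (\code{.raw}) with a JSON
#' sidecar \code{<file>.json} holding \code{shape}, \code{dtype}
#' (\code{"uint8"}, \code{"uint16"} or \code{"float64"}) and
#' \code{spacing_um}.
#'
#' @param path input file.
#' @param spacingOverrideUm optional spacing in micrometers that wins over
#'   any header/sidecar value (scalar recycled to 3).
#' @return A \linkS4class{Volume3D}.
#' @export
readVolume <- function(path, spacingOverrideUm = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  spacing <- NULL
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    shp <- lapply(pages, dim)
    if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L)
      stop(sprintf("inconsistent slice shapes in TIFF stack %s", path))
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    v <- array(0, dim = c(nx, ny, nz))
    for (k in seq_len(nz)) v[, , k] <- t(pages[[k]])
    if (file.exists(.metaPath(path))) {
      meta <- jsonlite::read_json(.metaPath(path), simplifyVector = TRUE)
      spacing <- meta$spacing_um
    }
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    v <- array(as.numeric(img), dim = dim(img))
    if (length(dim(v)) != 3L)
      stop(sprintf("expected a 3D NIfTI volume: %s", path))
    spacing <- RNifti::pixdim(img)[1:3]
  } else if (ext == "raw") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop(sprintf("raw volume %s requires the sidecar %s", path, sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    shape <- as.integer(meta$shape)
    n <- prod(shape)
    v <- switch(meta$dtype,
      uint8 = as.numeric(readBin(path, "integer", n, size = 1,
                                 signed = FALSE)),
      uint16 = as.numeric(readBin(path, "integer", n, size = 2,
                                  signed = FALSE, endian = "little")),
      float64 = readBin(path, "double", n, size = 8, endian = "little"),
      stop(sprintf("unsupported raw dtype '%s'", meta$dtype)))
    if (length(v) != n)
      stop(sprintf("raw file %s is truncated (%d of %d voxels)",
                   path, length(v), n))
    v <- array(v, dim = shape)
    spacing <- meta$spacing_um
  } else {
    stop(sprintf("unsupported volume format '.%s'", ext))
  }
  if (!is.null(spacingOverrideUm)) spacing <- spacingOverrideUm
  if (is.null(spacing)) spacing <- 3.7
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  Volume3D(v, as.numeric(spacing))
}

#' Write a 3D volume
#'
#' TIFF output is lossless for integer grids (8-bit when the range fits in
#' [0, 255], 16-bit up to [0, 65535]) and stores the spacing in a JSON
#' sidecar; non-integer data must go to NIfTI or raw. A
#' \linkS4class{BinaryMask} is written as 8-bit 0/255.
#'
#' @param vol A \linkS4class{Volume3D} or \linkS4class{BinaryMask}.
#' @param path output file (.tif/.tiff, .nii, or .raw).
#' @return The path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  if (is(vol, "BinaryMask")) {
    vals <- array(ifelse(vol@values, 255, 0), dim = dim(vol@values))
    spacing <- vol@spacing
  } else {
    stopifnot(is(vol, "Volume3D"))
    vals <- vol@values
    spacing <- vol@spacing
  }
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    if (any(vals != round(vals)) || min(vals) < 0 || max(vals) > 65535)
      stop("TIFF output requires integer values in [0, 65535]; use .nii or .raw")
    bits <- if (max(vals) <= 255) 8L else 16L
    scale <- 2^bits - 1
    pages <- lapply(seq_len(dim(vals)[3]),
                    function(k) t(vals[, , k]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
    jsonlite::write_json(list(spacing_um = spacing, bits = bits),
                         .metaPath(path), auto_unbox = FALSE, digits = NA)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else if (ext == "raw") {
    isInt <- all(vals == round(vals)) && min(vals) >= 0
    dtype <- if (isInt && max(vals) <= 255) "uint8"
             else if (isInt && max(vals) <= 65535) "uint16"
             else "float64"
    con <- file(path, "wb")
    on.exit(close(con))
    switch(dtype,
      uint8 = writeBin(as.integer(vals), con, size = 1),
      uint16 = writeBin(as.integer(vals), con, size = 2, endian = "little"),
      float64 = writeBin(as.numeric(vals), con, size = 8, endian = "little"))
    jsonlite::write_json(list(shape = dim(vals), dtype = dtype,
                              spacing_um = spacing, byte_order = "little"),
                         paste0(path, ".json"), auto_unbox = FALSE,
                         digits = NA)
  } else {
    stop(sprintf("unsupported volume format '.%s'", ext))
  }
  invisible(path)
}

#' Extract a line profile from a 2D image
#'
#' Samples \code{n} points linearly spaced between two pixel positions with
#' bilinear interpolation, and reports the integral optical density (IOD):
#' the trapezoidal integral of intensity along the line (intensity times
#' micrometers), used to compare the grayscale structure of projection
#' images.
#'
#' @param image 2D numeric matrix, dims (x, y).
#' @param p0,p1 endpoints in 0-based pixel coordinates (x, y).
#' @param n number of samples (>= 2).
#' @param pixelSizeUm physical pixel pitch in micrometers.
#' @return A list: \code{position_px}, \code{position_um} (distance along
#'   the line), \code{intensity}, and \code{iod}.
#' @export
extractLineProfile <- function(image, p0, p1, n = 100L, pixelSizeUm = 3.7) {
  stopifnot(is.matrix(image), n >= 2L)
  d <- dim(image)
  if (all(p0 == p1)) stop("line endpoints coincide")
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > d[1] - 1 || p[2] < 0 || p[2] > d[2] - 1)
      stop("line endpoint outside the image")
  t <- seq(0, 1, length.out = n)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  x0 <- pmin(floor(xs), d[1] - 2); x1 <- x0 + 1
  y0 <- pmin(floor(ys), d[2] - 2); y1 <- y0 + 1
  fx <- xs - x0; fy <- ys - y0
  at <- function(ix, iy) image[cbind(ix + 1L, iy + 1L)]
  vals <- (1 - fx) * (1 - fy) * at(x0, y0) + fx * (1 - fy) * at(x1, y0) +
    (1 - fx) * fy * at(x0, y1) + fx * fy * at(x1, y1)
  lenPx <- sqrt(sum((p1 - p0)^2))
  posPx <- t * lenPx
  posUm <- posPx * pixelSizeUm
  stepUm <- posUm[2] - posUm[1]
  iod <- stepUm * (sum(vals) - (vals[1] + vals[n]) / 2)
  list(position_px = posPx, position_um = posUm, intensity = vals, iod = iod)
}

#' Write a vessel graph
#'
#' GraphML (via igraph) and/or a documented JSON schema with \code{nodes[]}
#' and \code{segments[]} (polylines in micrometers for ground-truth graphs,
#' voxel indices plus spacing for extracted graphs).
#'
#' @param graph A \linkS4class{VesselGraph} or \linkS4class{GroundTruthGraph}.
#' @param path output file; format chosen by extension (.graphml or .json).
#' @return The path, invisibly.
#' @export
writeGraph <- function(graph, path) {
  ext <- tolower(sub(".*\\.", "", path))
  nodes <- graphNodes(graph)
  segs <- graphSegments(graph)
  if (ext == "graphml") {
    acyc <- segs[!is.na(segs$from) & !is.na(segs$to), , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      acyc[, c("from", "to", setdiff(names(acyc), c("from", "to")))],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else if (ext == "json") {
    polys <- segmentPolylines(graph)
    obj <- list(nodes = nodes,
                segments = segs,
                polylines = lapply(polys, function(P)
                  unname(apply(P, 1, as.numeric, simplify = FALSE))))
    if (is(graph, "VesselGraph")) {
      obj$spacing_um <- graph@spacing
      obj$polyline_units <- "voxel_index_1based"
    } else {
      obj$polyline_units <- "um"
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    stop(sprintf("unsupported graph format '.%s'", ext))
  }
  invisible(path)
}

#' Write per-segment and summary morphometry tables
#'
#' @param report A \linkS4class{MorphometryReport}.
#' @param segmentsCsv,summaryCsv output CSV paths (\code{NULL} to skip one).
#' @return Invisibly, a list with the two data frames.
#' @export
writeMorphometryCsv <- function(report, segmentsCsv = NULL,
                                summaryCsv = NULL) {
  stopifnot(is(report, "MorphometryReport"))
  segs <- report@segments
  keep <- c("id", "from", "to", "length_um", "mean_radius_um",
            "diameter_um", "theta_deg", "cyclic")
  segs <- segs[, intersect(keep, names(segs)), drop = FALSE]
  meanTheta <- if (nrow(report@angles)) mean(report@angles$theta_deg) else NA
  summary <- data.frame(
    vv_fraction = report@vvFraction, vv_mm3 = report@vvMm3,
    vn = report@vn, vnn = report@vnn,
    mean_diameter_um = if (nrow(segs)) mean(segs$diameter_um, na.rm = TRUE)
                       else NA_real_,
    mean_theta_deg = meanTheta,
    cyclic = report@cyclic)
  if (!is.null(segmentsCsv))
    utils::write.csv(segs, segmentsCsv, row.names = FALSE)
  if (!is.null(summaryCsv))
    utils::write.csv(summary, summaryCsv, row.names = FALSE)
  invisible(list(segments = segs, summary = summary))
}
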