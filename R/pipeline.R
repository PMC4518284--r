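# End-to-end pipeline: phantom (or input volume) -> segmentation ->
# skeletonization -> vessel graph -> morphometry report, with on-disk
# artifacts and a provenance record for reproducible runs.

#' Default pipeline configuration
#'
#' A nested list with one section per stage; every parameter has a default.
#' Configs round-trip unchanged through YAML/JSON
#' (\code{\link{readRunConfig}}).
#'
#' @return A named list.
#' @export
defaultRunConfig <- function() {
  list(
    input = list(kind = "phantom", path = NULL, spacing_um = NULL),
    phantom = list(grid_shape = 128L, spacing_um = 3.7,
                   trunk_radius_um = 18.5, branch_levels = 2L,
                   branch_angle_deg = 45, taper_ratio = 0.8,
                   radius_range_um = c(3.7, 50),
                   foreground_intensity = 200, background_intensity = 50,
                   noise_sigma = 30, blur_sigma_um = 3.7,
                   angle_jitter_deg = 5, degrade = TRUE),
    injury = list(enabled = FALSE, epicenter_um = NULL,
                  cavity_semiaxes_um = c(70, 70, 110), tilt_deg = 19,
                  tilt_extent_um = 150),
    segmentation = list(presmooth_sigma_um = 5.55, min_voxels = 3L,
                        threshold = NULL),
    skeleton = list(chamfer = FALSE, prune_length_um = 0),
    graph = list(k = 10L, trim_voxels = 2L,
                 bin_edges_um = seq(0, 100, by = 10)),
    roi = NULL,
    trunk_axis = c(0, 0, 1),
    seed = 1L
  )
}

#' Read a pipeline configuration from disk
#'
#' YAML or JSON; values present in the file override the defaults section by
#' section.
#'
#' @param path a .yaml/.yml or .json config file.
#' @return A config list (defaults merged with the file).
#' @export
readRunConfig <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path,
                                                      simplifyVector = TRUE)
          else stop(sprintf("unsupported config format '.%s'", ext))
  cfg <- defaultRunConfig()
  for (sec in names(user)) {
    if (is.list(cfg[[sec]]) && is.list(user[[sec]]))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

.phantomSpecFromConfig <- function(cfg, seed) {
  p <- cfg$phantom
  phantomSpec(gridShape = p$grid_shape, spacingUm = p$spacing_um,
              trunkRadiusUm = p$trunk_radius_um,
              branchLevels = p$branch_levels,
              branchAngleDeg = p$branch_angle_deg,
              taperRatio = p$taper_ratio, radiusRangeUm = p$radius_range_um,
              foregroundIntensity = p$foreground_intensity,
              backgroundIntensity = p$background_intensity,
              noiseSigma = p$noise_sigma, blurSigmaUm = p$blur_sigma_um,
              angleJitterDeg = p$angle_jitter_deg, seed = seed)
}

#' Run the full morphometry pipeline
#'
#' Stages: input (synthetic phantom or a volume from disk), segmentation
#' (optional denoising, isodata threshold, 3-voxel size filter), Euclidean
#' distance map, topology-preserving thinning, radius assignment, vessel
#' graph, and the morphometry report. With \code{outDir} set, writes the
#' mask, skeleton, distance and radius maps, graph (GraphML + JSON),
#' per-segment and summary CSVs, a provenance record, and a run log. The
#' same config and seed always produce byte-identical summary output.
#'
#' @param config a config list (see \code{\link{defaultRunConfig}}) or a
#'   path to a YAML/JSON config.
#' @param outDir output directory (created if needed); \code{NULL} writes
#'   nothing.
#' @param seed overrides \code{config$seed} when not \code{NULL}.
#' @return A list: \code{report} (\linkS4class{MorphometryReport}),
#'   \code{graph}, \code{mask}, \code{skeleton}, \code{threshold},
#'   \code{truth} (ground-truth graph for phantom inputs), \code{config}.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- utils::modifyList(defaultRunConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  logLines <- character(0)
  t00 <- proc.time()[["elapsed"]]
  logf <- function(fmt, ...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t00,
                    sprintf(fmt, ...))
    logLines <<- c(logLines, line)
    message(line)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  if (identical(cfg$input$kind, "phantom")) {
    spec <- .phantomSpecFromConfig(cfg, cfg$seed)
    injury <- NULL
    if (isTRUE(cfg$injury$enabled)) {
      epi <- cfg$injury$epicenter_um
      if (is.null(epi)) {
        # default epicenter: midpoint of the first gray-matter branch, so
        # the cavity destroys one sulcal subtree (lateralized contusion)
        g0 <- stage("phantom", generateTree(spec))
        lev1 <- which(graphSegments(g0)$level == 1L)
        epi <- if (length(lev1)) {
          P <- segmentPolylines(g0)[[lev1[1]]]
          (P[1, ] + P[nrow(P), ]) / 2
        } else (spec@gridShape - 1) * spec@spacingUm / 2
      }
      injury <- injurySpec(epicenterUm = epi,
                           cavitySemiaxesUm = cfg$injury$cavity_semiaxes_um,
                           tiltDeg = cfg$injury$tilt_deg,
                           tiltExtentUm = cfg$injury$tilt_extent_um)
    }
    ph <- stage("phantom",
                generatePhantom(spec, injury,
                                degrade = isTRUE(cfg$phantom$degrade)))
    vol <- ph$volume
    truth <- ph$graph
    logf("phantom: %d ground-truth segments, %d^3-equivalent grid",
         nrow(graphSegments(truth)), round(prod(dim(vol))^(1 / 3)))
  } else {
    vol <- stage("input", readVolume(cfg$input$path, cfg$input$spacing_um))
    logf("input: read %s (%s voxels)", cfg$input$path,
         paste(dim(vol), collapse = " x "))
  }

  seg <- stage("segmentation",
               segmentVolume(vol,
                             presmoothSigmaUm = cfg$segmentation$presmooth_sigma_um,
                             minVoxels = cfg$segmentation$min_voxels,
                             threshold = cfg$segmentation$threshold))
  mask <- seg$mask
  thr <- if (is(seg$threshold, "ThresholdResult")) seg$threshold@threshold
         else seg$threshold
  logf("segmentation: threshold %.4g, %d foreground voxels", thr,
       sum(voxelData(mask)))

  edm <- stage("distance-map",
               euclideanDistanceMap(mask, chamfer = isTRUE(cfg$skeleton$chamfer)))
  skel <- stage("thinning", skeletonize3D(mask))
  logf("thinning: %d skeleton voxels", sum(voxelData(skel)))
  radii <- stage("radius-map", radiusFromEDM(skel, edm))
  graph <- stage("graph",
                 buildVesselGraph(skel, radii,
                                  trimVoxels = cfg$graph$trim_voxels))
  if (cfg$skeleton$prune_length_um > 0)
    graph <- stage("prune", pruneSpurs(graph, cfg$skeleton$prune_length_um))
  logf("graph: VN = %d, VNN = %d", nrow(graphSegments(graph)),
       sum(graphNodes(graph)$kind == "junction"))

  roi <- if (!is.null(cfg$roi)) ROI3D(cfg$roi$lo, cfg$roi$hi) else NULL
  report <- stage("report",
                  summarizeROI(mask, graph, roi = roi,
                               binEdgesUm = cfg$graph$bin_edges_um,
                               trunkAxis = cfg$trunk_axis,
                               k = cfg$graph$k))
  logf("report: VV fraction %.5g, VN %d, VNN %d", report@vvFraction,
       report@vn, report@vnn)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage("write", {
      writeVolume(mask, file.path(outDir, "mask.tif"))
      writeVolume(skel, file.path(outDir, "skeleton.tif"))
      writeVolume(edm, file.path(outDir, "edm.nii"))
      writeVolume(radii, file.path(outDir, "radii.nii"))
      writeGraph(graph, file.path(outDir, "graph.graphml"))
      writeGraph(graph, file.path(outDir, "graph.json"))
      if (!is.null(truth)) writeGraph(truth, file.path(outDir, "truth.json"))
      writeMorphometryCsv(report,
                          segmentsCsv = file.path(outDir, "segments.csv"),
                          summaryCsv = file.path(outDir, "summary.csv"))
      prov <- list(package = "vasculometry",
                   version = as.character(utils::packageVersion("vasculometry")),
                   seed = cfg$seed, config = cfg)
      jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      writeLines(logLines, file.path(outDir, "run.log"))
    })
  }

  list(report = report, graph = graph, mask = mask, skeleton = skel,
       edm = edm, radii = radii, threshold = seg$threshold, truth = truth,
       config = cfg)
}
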