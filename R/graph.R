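# Vessel-tree model: convert a skeleton into nodes (endpoints, junction
# clusters) and segments (centerline polylines with length L and diameter
# VD), and compute the morphometric read-outs VV, VN, VNN, the diameter
# distribution and signed bifurcation angles.

.offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Classify skeleton voxels
#'
#' Labels every skeleton voxel by its number of skeleton 26-neighbors:
#' 1 neighbor = endpoint, 2 = slab (interior of a segment), 3 or more =
#' junction. Isolated voxels (0 neighbors) are treated as endpoints by
#' convention and reported via a message.
#'
#' @param skel A \linkS4class{Skeleton3D}.
#' @return A list: \code{labels} (integer array: 0 background, 1 endpoint,
#'   2 slab, 3 junction) and \code{counts} (named totals).
#' @export
classifySkeletonVoxels <- function(skel) {
  stopifnot(is(skel, "Skeleton3D"))
  v <- skel@values
  nc <- array(.neighbor_count26_cpp(as.logical(v), dim(v)), dim = dim(v))
  lab <- array(0L, dim = dim(v))
  lab[v & nc <= 1L] <- 1L
  lab[v & nc == 2L] <- 2L
  lab[v & nc >= 3L] <- 3L
  iso <- sum(v & nc == 0L)
  if (iso > 0)
    message(sprintf("%d isolated skeleton voxel(s) classified as endpoints",
                    iso))
  list(labels = lab,
       counts = c(endpoint = sum(lab == 1L), slab = sum(lab == 2L),
                  junction = sum(lab == 3L)))
}

#' Build the vessel graph from a skeleton
#'
#' 26-connected clusters of junction voxels are merged into single junction
#' nodes (centroid position) -- thinning produces junction clusters, and
#' counting their voxels individually would inflate the node number.
#' Segments are traced through slab voxels between nodes; node-free cycles
#' are kept as cyclic segments. Traversal is in raster-scan order, so the
#' output is deterministic.
#'
#' Segment length L is the polyline arc length (spacing-aware). Diameter
#' VD is twice the mean centerline radius along the segment; when a segment
#' has more than 6 voxels the 2 voxels nearest each end are excluded from
#' the mean, because the distance map is inflated where segments meet.
#'
#' @param skel A \linkS4class{Skeleton3D}.
#' @param radii Optional \linkS4class{RadiusMap}; without it, radius and
#'   diameter columns are NA.
#' @param trimVoxels voxels trimmed from each end for the radius mean
#'   (applied when the segment has more than \code{3 * trimVoxels} voxels).
#' @return A \linkS4class{VesselGraph}.
#' @export
buildVesselGraph <- function(skel, radii = NULL, trimVoxels = 2L) {
  stopifnot(is(skel, "Skeleton3D"))
  if (!is.null(radii)) stopifnot(is(radii, "RadiusMap"))
  v <- skel@values
  d <- dim(v)
  sp <- skel@spacing
  cls <- suppressMessages(classifySkeletonVoxels(skel))
  lab <- cls$labels

  # --- nodes: junction clusters first, then endpoints, in raster order
  jmask <- lab == 3L
  jcc <- connectedComponents(jmask, 26L)
  nJ <- if (length(jcc$sizes)) length(jcc$sizes) else 0L
  epIdx <- which(lab == 1L)
  nodeArr <- array(0L, dim = d)
  if (nJ > 0) nodeArr[jmask] <- jcc$labels[jmask]
  if (length(epIdx)) nodeArr[epIdx] <- nJ + seq_along(epIdx)
  nNodes <- nJ + length(epIdx)

  coordsOf <- function(idx) {
    idx0 <- idx - 1L
    cbind(idx0 %% d[1], (idx0 %/% d[1]) %% d[2],
          idx0 %/% (d[1] * d[2])) + 1L
  }
  nodes <- data.frame(id = integer(0), kind = character(0),
                      degree = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), nvox = integer(0),
                      stringsAsFactors = FALSE)
  if (nNodes > 0) {
    kinds <- c(rep("junction", nJ), rep("endpoint", length(epIdx)))
    pos <- matrix(NA_real_, nNodes, 3)
    nv <- integer(nNodes)
    if (nJ > 0) {
      jIdx <- which(jmask)
      jl <- jcc$labels[jIdx]
      C <- (coordsOf(jIdx) - 1L) * matrix(sp, length(jIdx), 3, byrow = TRUE)
      for (a in 1:3) pos[1:nJ, a] <- tapply(C[, a], jl, mean)
      nv[1:nJ] <- tabulate(jl, nbins = nJ)
    }
    if (length(epIdx)) {
      pos[nJ + seq_along(epIdx), ] <-
        (coordsOf(epIdx) - 1L) * matrix(sp, length(epIdx), 3, byrow = TRUE)
      nv[nJ + seq_along(epIdx)] <- 1L
    }
    nodes <- data.frame(id = seq_len(nNodes), kind = kinds, degree = 0L,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3], nvox = nv,
                        stringsAsFactors = FALSE)
  }

  nbrsOf <- function(idx) {
    co <- coordsOf(idx)[1, ]
    nb <- .offsets26 + matrix(co, 26, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    sort(lin[v[lin]])
  }

  visited <- array(FALSE, dim = d)
  segFrom <- integer(0); segTo <- integer(0); segCyc <- logical(0)
  polys <- list()
  edgeSeen <- new.env(hash = TRUE)

  addSegment <- function(from, to, pathIdx, cyclic = FALSE) {
    k <- length(polys) + 1L
    polys[[k]] <<- coordsOf(pathIdx)
    segFrom[k] <<- from; segTo[k] <<- to; segCyc[k] <<- cyclic
  }

  nodeVox <- which(nodeArr != 0L)
  for (nv0 in nodeVox) {
    startNode <- nodeArr[nv0]
    for (w in nbrsOf(nv0)) {
      wn <- nodeArr[w]
      if (wn != 0L) {
        if (wn == startNode) next  # intra-cluster adjacency
        key <- paste(min(nv0, w), max(nv0, w))
        if (!is.null(edgeSeen[[key]])) next
        edgeSeen[[key]] <- TRUE
        addSegment(startNode, wn, c(nv0, w))
        next
      }
      if (visited[w]) next
      # trace through slab voxels
      path <- c(nv0, w)
      visited[w] <- TRUE
      prev <- nv0; cur <- w
      repeat {
        nb <- setdiff(nbrsOf(cur), prev)
        nbNode <- nb[nodeArr[nb] != 0L]
        nbSlab <- nb[nodeArr[nb] == 0L & !visited[nb]]
        # prefer leaving toward a different node; avoid bouncing straight
        # back into the start cluster when a slab continuation exists
        nbOther <- nbNode[nodeArr[nbNode] != startNode]
        if (length(nbOther)) {
          path <- c(path, nbOther[1]); endNode <- nodeArr[nbOther[1]]; break
        }
        if (length(nbSlab)) {
          prev <- cur; cur <- nbSlab[1]
          visited[cur] <- TRUE
          path <- c(path, cur)
          next
        }
        if (length(nbNode)) {  # self-loop back to the start cluster
          path <- c(path, nbNode[1]); endNode <- nodeArr[nbNode[1]]; break
        }
        endNode <- NA_integer_  # dead end inside a visited region
        break
      }
      addSegment(startNode, endNode, path)
    }
  }

  # node-free cycles: remaining unvisited slab voxels
  cyc <- FALSE
  remaining <- which(lab == 2L & !visited & nodeArr == 0L)
  for (s0 in remaining) {
    if (visited[s0]) next
    cyc <- TRUE
    path <- s0
    visited[s0] <- TRUE
    prev <- NA_integer_; cur <- s0
    repeat {
      nb <- nbrsOf(cur)
      nb <- nb[nodeArr[nb] == 0L & !visited[nb]]
      if (!is.na(prev)) nb <- setdiff(nb, prev)
      if (!length(nb)) break
      prev <- cur; cur <- nb[1]
      visited[cur] <- TRUE
      path <- c(path, cur)
    }
    path <- c(path, s0)  # close the loop
    addSegment(NA_integer_, NA_integer_, path, cyclic = TRUE)
  }

  nSeg <- length(polys)
  lengthUm <- numeric(nSeg); meanR <- rep(NA_real_, nSeg)
  if (nSeg > 0) {
    rv <- if (!is.null(radii)) radii@values else NULL
    for (k in seq_len(nSeg)) {
      P <- polys[[k]]
      if (nrow(P) > 1) {
        steps <- (P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]) *
          matrix(sp, nrow(P) - 1L, 3, byrow = TRUE)
        lengthUm[k] <- sum(sqrt(rowSums(steps^2)))
      }
      if (!is.null(rv)) {
        lin <- P[, 1] + (P[, 2] - 1L) * d[1] + (P[, 3] - 1L) * d[1] * d[2]
        vals <- rv[lin]
        vals <- vals[vals > 0]  # node voxels inside junction clusters may be
                                # off-skeleton in the radius map support
        if (length(vals) > 3L * trimVoxels) {
          vals <- vals[(trimVoxels + 1L):(length(vals) - trimVoxels)]
        }
        if (length(vals)) meanR[k] <- mean(vals)
      }
    }
  }

  segments <- data.frame(id = seq_len(nSeg), from = segFrom, to = segTo,
                         nvox = if (nSeg) vapply(polys, nrow, 1L) else integer(0),
                         length_um = lengthUm, mean_radius_um = meanR,
                         diameter_um = 2 * meanR, cyclic = segCyc,
                         stringsAsFactors = FALSE)
  if (nNodes > 0 && nSeg > 0) {
    degTab <- table(factor(c(segments$from, segments$to),
                           levels = nodes$id))
    nodes$degree <- as.integer(degTab)
  }
  new("VesselGraph", nodes = nodes, segments = segments,
      polylines = polys, spacing = sp)
}

#' Vessel volume within an ROI
#'
#' Fractional occupancy of the binary vasculature in the ROI, and the same
#' volume in cubic millimeters (foreground voxels times the physical voxel
#' volume; 1e9 cubic micrometers per cubic millimeter).
#'
#' @param mask A \linkS4class{BinaryMask}.
#' @param roi An \linkS4class{ROI3D}; \code{NULL} for the whole volume.
#' @return A list: \code{fraction} and \code{mm3}.
#' @export
vesselVolume <- function(mask, roi = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mask@values
  d <- dim(v)
  if (is.null(roi)) roi <- ROI3D(c(0L, 0L, 0L), d)
  if (any(roi@hi > d))
    stop("ROI exceeds the mask bounds")
  sub <- v[(roi@lo[1] + 1L):roi@hi[1], (roi@lo[2] + 1L):roi@hi[2],
           (roi@lo[3] + 1L):roi@hi[3], drop = FALSE]
  nFg <- sum(sub)
  voxVolUm3 <- prod(mask@spacing)
  list(fraction = nFg / length(sub), mm3 = nFg * voxVolUm3 * 1e-9)
}

#' Diameter distribution of a vessel graph
#'
#' Counts segments (not voxels) per diameter bin. Bins are half-open
#' \code{[edge_i, edge_{i+1})}; diameters outside the edges are not counted.
#'
#' @param graph A \linkS4class{VesselGraph}.
#' @param binEdgesUm increasing bin edges in micrometers.
#' @return A list: \code{breaks} and integer \code{counts} (length
#'   \code{length(breaks) - 1}).
#' @export
diameterDistribution <- function(graph, binEdgesUm = seq(0, 100, by = 10)) {
  stopifnot(is(graph, "VesselGraph"), !is.unsorted(binEdgesUm, strictly = TRUE))
  dia <- graph@segments$diameter_um
  dia <- dia[!is.na(dia)]
  nb <- length(binEdgesUm) - 1L
  idx <- findInterval(dia, binEdgesUm, left.open = FALSE)  # [edge, next)
  idx <- idx[idx >= 1L & idx <= nb & dia < binEdgesUm[nb + 1L]]
  list(breaks = binEdgesUm, counts = tabulate(idx, nbins = nb))
}

.branchDirection <- function(P, sp, k, skipUm, nodePos) {
  # Fit the branch direction from k voxels beyond the junction-inflated
  # zone: skeleton voxels within one parent-vessel radius of the junction
  # centroid lie inside the merged blob of the two tubes, where the thinned
  # centerline shortcuts and biases shallow angles steep, so they are
  # skipped before the principal-axis fit.
  pos <- (P - 1) * matrix(sp, nrow(P), 3, byrow = TRUE)
  dist <- sqrt(rowSums((pos - matrix(nodePos, nrow(P), 3, byrow = TRUE))^2))
  skip <- 0L
  while (skip + 1L <= nrow(P) && dist[skip + 1L] <= skipUm) skip <- skip + 1L
  if (nrow(P) < skip + k) return(NULL)
  pts <- pos[(skip + 1L):(skip + k), , drop = FALSE]
  ctr <- sweep(pts, 2, colMeans(pts))
  u <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  if (sum(u * (colMeans(pts) - nodePos)) < 0) u <- -u
  u
}

#' Signed bifurcation angles
#'
#' For every segment attached to a junction node, the angle between the
#' branch direction (pointing away from the junction) and the
#' rostrally-oriented trunk axis. The direction is a principal-axis fit of
#' \code{k} skeleton voxels beyond the junction-inflated zone (voxels within
#' one local vessel radius of the junction centroid are skipped: there the
#' thinned centerline runs inside the merged tube blob and biases shallow
#' angles steep; a single voxel step would instead quantize angles to the 26
#' lattice directions). Reported with the anatomical sign convention: a
#' branch pointing rostrally makes an angle of at most 90 degrees and is
#' positive; a branch pointing caudally is reported as the negative of its
#' supplement, so the magnitude never exceeds 90 degrees.
#'
#' @param graph A \linkS4class{VesselGraph}.
#' @param trunkAxis unit vector of the trunk, oriented rostrally (default
#'   +z).
#' @param k number of voxels used for the direction fit (default 10).
#' @return Data frame: \code{segment}, \code{node}, \code{theta_deg}.
#'   Branches with fewer than \code{k} usable voxels beyond the junction
#'   zone are omitted with a warning.
#' @export
bifurcationAngles <- function(graph, trunkAxis = c(0, 0, 1), k = 10L) {
  stopifnot(is(graph, "VesselGraph"))
  t <- trunkAxis / sqrt(sum(trunkAxis^2))
  segs <- graph@segments
  out <- list()
  short <- 0L
  for (i in seq_len(nrow(segs))) {
    if (segs$cyclic[i]) next
    fromJ <- !is.na(segs$from[i]) &&
      graph@nodes$kind[match(segs$from[i], graph@nodes$id)] == "junction"
    toJ <- !is.na(segs$to[i]) &&
      graph@nodes$kind[match(segs$to[i], graph@nodes$id)] == "junction"
    if (!fromJ && !toJ) next
    P <- graph@polylines[[i]]
    if (!fromJ) {  # measure from the 'to' end
      P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
      nodeId <- segs$to[i]
    } else nodeId <- segs$from[i]
    nrow_ <- match(nodeId, graph@nodes$id)
    nodePos <- as.numeric(graph@nodes[nrow_, c("x", "y", "z")])
    touching <- segs$from == nodeId | segs$to == nodeId
    rJ <- suppressWarnings(max(segs$mean_radius_um[touching], na.rm = TRUE))
    if (!is.finite(rJ)) rJ <- 0
    u <- .branchDirection(P, graph@spacing, k, rJ, nodePos)
    if (is.null(u)) { short <- short + 1L; next }
    theta <- .signedAngleToTrunk(u, t)
    out[[length(out) + 1L]] <- data.frame(segment = segs$id[i],
                                          node = nodeId,
                                          theta_deg = theta)
  }
  if (short > 0)
    warning(sprintf("%d branch(es) shorter than %d voxels beyond the junction: angle omitted",
                    short, k))
  if (length(out)) do.call(rbind, out)
  else data.frame(segment = integer(0), node = integer(0),
                  theta_deg = numeric(0))
}

#' Morphometry report for one volume / ROI
#'
#' Assembles vessel volume (VV), vessel number (VN), vessel node number
#' (VNN), the diameter histogram, signed bifurcation angles and the
#' per-segment table. Segments touching the ROI (any centerline voxel
#' inside) are counted in VN without edge correction; junction nodes are
#' counted when their centroid lies inside the ROI.
#'
#' @param mask A \linkS4class{BinaryMask}.
#' @param graph The matching \linkS4class{VesselGraph}.
#' @param roi An \linkS4class{ROI3D}; \code{NULL} for the whole volume.
#' @param binEdgesUm diameter histogram edges (micrometers).
#' @param trunkAxis rostrally-oriented trunk axis for the angles.
#' @param k direction-fit length for \code{\link{bifurcationAngles}}.
#' @return A \linkS4class{MorphometryReport}.
#' @export
summarizeROI <- function(mask, graph, roi = NULL,
                         binEdgesUm = seq(0, 100, by = 10),
                         trunkAxis = c(0, 0, 1), k = 10L) {
  stopifnot(is(mask, "BinaryMask"), is(graph, "VesselGraph"))
  d <- dim(mask@values)
  if (is.null(roi)) roi <- ROI3D(c(0L, 0L, 0L), d)
  vv <- vesselVolume(mask, roi)
  segs <- graph@segments
  inRoi <- function(P) {
    any(P[, 1] > roi@lo[1] & P[, 1] <= roi@hi[1] &
        P[, 2] > roi@lo[2] & P[, 2] <= roi@hi[2] &
        P[, 3] > roi@lo[3] & P[, 3] <= roi@hi[3])
  }
  segIn <- if (nrow(segs)) vapply(graph@polylines, inRoi, TRUE) else logical(0)
  # junction centroid in voxel units, 0-based
  nodesIn <- logical(nrow(graph@nodes))
  if (nrow(graph@nodes)) {
    cvox <- sweep(as.matrix(graph@nodes[, c("x", "y", "z")]), 2,
                  graph@spacing, "/")
    nodesIn <- cvox[, 1] >= roi@lo[1] & cvox[, 1] < roi@hi[1] &
      cvox[, 2] >= roi@lo[2] & cvox[, 2] < roi@hi[2] &
      cvox[, 3] >= roi@lo[3] & cvox[, 3] < roi@hi[3]
  }
  vn <- sum(segIn)
  vnn <- sum(nodesIn & graph@nodes$kind == "junction")
  sub <- segs[segIn, , drop = FALSE]
  dsub <- new("VesselGraph", nodes = graph@nodes, segments = sub,
              polylines = graph@polylines[segIn], spacing = graph@spacing)
  hist <- diameterDistribution(dsub, binEdgesUm)
  ang <- suppressWarnings(bifurcationAngles(dsub, trunkAxis, k))
  segTab <- sub
  segTab$theta_deg <- ang$theta_deg[match(segTab$id, ang$segment)]
  new("MorphometryReport", roi = roi, vvFraction = vv$fraction,
      vvMm3 = vv$mm3, vn = as.integer(vn), vnn = as.integer(vnn),
      histBreaks = hist$breaks, histCounts = as.integer(hist$counts),
      angles = ang, segments = segTab,
      cyclic = any(segs$cyclic))
}

#' Prune short spur segments
#'
#' Removes endpoint-terminated segments shorter than a length threshold.
#' Off by default in the pipeline (no pruning is applied unless requested).
#'
#' @param graph A \linkS4class{VesselGraph}.
#' @param minLengthUm spurs strictly shorter than this are removed.
#' @return A pruned \linkS4class{VesselGraph}.
#' @export
pruneSpurs <- function(graph, minLengthUm) {
  stopifnot(is(graph, "VesselGraph"))
  segs <- graph@segments
  isEp <- function(id) {
    !is.na(id) & graph@nodes$kind[match(id, graph@nodes$id)] == "endpoint"
  }
  spur <- !segs$cyclic & segs$length_um < minLengthUm &
    (isEp(segs$from) | isEp(segs$to))
  keep <- !spur
  segs <- segs[keep, , drop = FALSE]
  g <- new("VesselGraph", nodes = graph@nodes, segments = segs,
           polylines = graph@polylines[keep], spacing = graph@spacing)
  if (nrow(g@nodes) && nrow(segs)) {
    degTab <- table(factor(c(segs$from, segs$to), levels = g@nodes$id))
    g@nodes$degree <- as.integer(degTab)
  }
  g
}
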