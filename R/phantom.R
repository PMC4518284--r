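# Synthetic vascular phantom: a bifurcating tube tree with exactly known
# geometry, rasterized onto a gray-value grid and degraded with partial-
# volume blur plus additive noise, emulating contrast-perfused spinal cord
# vasculature in synchrotron micro-CT.

#' Construct a phantom specification
#'
#' Defaults emulate the study conditions of high-resolution micro-CT
#' angiography of the rodent spinal cord: 3.7 um isotropic voxels, a
#' longitudinal trunk vessel of 18.5 um radius bifurcating over two levels at
#' a nominal 45 degrees with taper 0.8, vessel radii admissible in
#' [3.7, 50] um (diameters 7.4-100 um), bright vessels (200) on darker
#' parenchyma (50) with one-voxel partial-volume blur and additive Gaussian
#' noise of SD 30 (contrast-to-noise ratio 5).
#'
#' @param gridShape voxel counts per axis (scalar recycled). Default 128.
#' @param spacingUm voxel spacing in um (scalar recycled). Default 3.7.
#' @param trunkRadiusUm trunk vessel radius in um. Default 18.5 (5 voxels).
#' @param branchLevels depth of the bifurcating tree; 0 = trunk only.
#' @param branchAngleDeg nominal parent-child angle per level, degrees.
#' @param taperRatio child/parent radius ratio per level, in (0, 1].
#' @param radiusRangeUm admissible radii in um.
#' @param foregroundIntensity,backgroundIntensity vessel and parenchyma gray
#'   values.
#' @param noiseSigma SD of additive Gaussian noise (gray values).
#' @param blurSigmaUm partial-volume smoothing scale in um.
#' @param angleJitterDeg half-width of the seeded uniform angular jitter.
#' @param seed integer RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = 128L, spacingUm = 3.7,
                        trunkRadiusUm = 18.5, branchLevels = 2L,
                        branchAngleDeg = 45, taperRatio = 0.8,
                        radiusRangeUm = c(3.7, 50),
                        foregroundIntensity = 200,
                        backgroundIntensity = 50,
                        noiseSigma = 30, blurSigmaUm = 3.7,
                        angleJitterDeg = 5, seed = 1L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  if (length(spacingUm) == 1L) spacingUm <- rep(spacingUm, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingUm = as.numeric(spacingUm), trunkRadiusUm = trunkRadiusUm,
      branchLevels = as.integer(branchLevels),
      branchAngleDeg = branchAngleDeg, taperRatio = taperRatio,
      radiusRangeUm = as.numeric(radiusRangeUm),
      foregroundIntensity = foregroundIntensity,
      backgroundIntensity = backgroundIntensity, noiseSigma = noiseSigma,
      blurSigmaUm = blurSigmaUm, angleJitterDeg = angleJitterDeg,
      seed = as.integer(seed))
}

#' Construct an injury specification
#'
#' @param epicenterUm cavity center in um. In the pipeline the default
#'   places it at the midpoint of the first gray-matter branch (the first
#'   level-1 segment), emulating a lateralized contusion that destroys one
#'   sulcal-artery subtree -- the scale of loss reported for contusive cord
#'   injury (roughly a quarter to a half of VV/VN/VNN).
#' @param cavitySemiaxesUm ellipsoid semi-axes (x, y, z) in um; z (axial)
#'   must be the largest (spindle shape). The default (70, 70, 110) encloses
#'   one level-1 branch of the default phantom.
#' @param tiltDeg signed tilt of branches near the epicenter, degrees. The
#'   default 19 mirrors the reported rostro-caudal displacement of surviving
#'   branches.
#' @param tiltExtentUm longitudinal range of the tilt, um.
#' @return An \linkS4class{InjurySpec}.
#' @export
injurySpec <- function(epicenterUm, cavitySemiaxesUm = c(70, 70, 110),
                       tiltDeg = 19, tiltExtentUm = 150) {
  new("InjurySpec", epicenterUm = as.numeric(epicenterUm),
      cavitySemiaxesUm = as.numeric(cavitySemiaxesUm),
      tiltDeg = tiltDeg, tiltExtentUm = tiltExtentUm)
}

# run code with a private, restored RNG state
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

.rodrigues <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.signedAngleToTrunk <- function(u, trunkAxis = c(0, 0, 1)) {
  u <- u / sqrt(sum(u^2))
  raw <- acos(max(-1, min(1, sum(u * trunkAxis)))) * 180 / pi
  if (raw > 90) -(180 - raw) else raw
}

#' Generate the ground-truth vessel tree of a phantom
#'
#' Builds a connected, acyclic tube tree: a trunk along +z (rostro-caudal
#' axis, +z = rostral) that bifurcates \code{branchLevels} times into two
#' children per node. Children alternate left/right around the parent with
#' the nominal branch angle plus a seeded uniform jitter; radii taper
#' geometrically. Deterministic for a fixed spec (including its seed).
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @return A \linkS4class{GroundTruthGraph}.
#' @export
generateTree <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  sp <- spec@spacingUm
  ext <- (spec@gridShape - 1) * sp  # physical extent, um

  # reject specs whose deepest branches taper below one voxel
  minVox <- min(sp)
  for (lev in seq_len(spec@branchLevels)) {
    r <- spec@trunkRadiusUm * spec@taperRatio^lev
    if (r < minVox || r < spec@radiusRangeUm[1])
      stop(sprintf(paste0("tapered radius at branch level %d is %.3g um, ",
                          "below the admissible minimum (%.3g um)"),
                   lev, r, max(minVox, spec@radiusRangeUm[1])))
  }

  margin <- spec@trunkRadiusUm + 2 * max(sp)
  trunkLen <- if (spec@branchLevels > 0L) 0.45 * (ext[3] - 2 * margin)
              else 0.8 * (ext[3] - 2 * margin)
  if (trunkLen <= 0)
    stop("grid too small to contain the trunk vessel")
  # snap the trunk to a voxel-centered (x, y) position: an axis-aligned tube
  # whose centerline falls between voxel centers has no central voxel column
  # and no stable medial axis under grid thinning
  root <- c(floor((spec@gridShape[1] - 1) / 2) * sp[1],
            floor((spec@gridShape[2] - 1) / 2) * sp[2], margin)

  nodes <- list()
  segs <- list()
  polys <- list()
  nid <- 0L
  sid <- 0L
  addNode <- function(pos, kind) {
    nid <<- nid + 1L
    nodes[[nid]] <<- data.frame(id = nid, x = pos[1], y = pos[2], z = pos[3],
                                kind = kind, stringsAsFactors = FALSE)
    nid
  }
  addSeg <- function(from, to, P, radius, level) {
    sid <<- sid + 1L
    L <- sum(sqrt(rowSums((P[-1, , drop = FALSE] -
                           P[-nrow(P), , drop = FALSE])^2)))
    u <- P[nrow(P), ] - P[1, ]
    segs[[sid]] <<- data.frame(id = sid, from = from, to = to,
                               radius_um = radius, length_um = L,
                               angle_deg = .signedAngleToTrunk(u),
                               level = level, stringsAsFactors = FALSE)
    polys[[sid]] <<- P
    sid
  }

  .withSeed(spec@seed, {
    rootId <- addNode(root, "endpoint")
    grow <- function(fromId, p0, dir, len, radius, level) {
      p1 <- p0 + len * dir
      toKind <- if (level < spec@branchLevels) "bifurcation" else "endpoint"
      toId <- addNode(p1, toKind)
      addSeg(fromId, toId, rbind(p0, p1), radius, level)
      if (level < spec@branchLevels) {
        # rotation plane alternates with depth so the tree spreads in 3D
        ref <- if (level %% 2 == 0) c(1, 0, 0) else c(0, 1, 0)
        ax <- c(dir[2] * ref[3] - dir[3] * ref[2],
                dir[3] * ref[1] - dir[1] * ref[3],
                dir[1] * ref[2] - dir[2] * ref[1])
        if (sqrt(sum(ax^2)) < 1e-8) ax <- c(0, 1, 0)
        for (s in c(1, -1)) {
          jit <- stats::runif(1, -spec@angleJitterDeg, spec@angleJitterDeg)
          R <- .rodrigues(ax, s * (spec@branchAngleDeg + jit))
          grow(toId, p1, as.numeric(R %*% dir), len * 0.65,
               radius * spec@taperRatio, level + 1L)
        }
      }
    }
    grow(rootId, root, c(0, 0, 1), trunkLen, spec@trunkRadiusUm, 0L)
  })

  g <- new("GroundTruthGraph", nodes = do.call(rbind, nodes),
           segments = do.call(rbind, segs),
           polylines = stats::setNames(polys,
                                       as.character(seq_along(polys))))
  .checkTreeInGrid(g, spec)
  g
}

.checkTreeInGrid <- function(graph, spec) {
  ext <- (spec@gridShape - 1) * spec@spacingUm
  for (i in seq_len(nrow(graph@segments))) {
    P <- graph@polylines[[i]]
    r <- graph@segments$radius_um[i]
    lo <- apply(P, 2, min) - r
    hi <- apply(P, 2, max) + r
    if (any(lo < 0) || any(hi > ext))
      stop(sprintf("segment %d (radius %.3g um) exits the grid",
                   graph@segments$id[i], r))
  }
  invisible(TRUE)
}

#' Rasterize a ground-truth tree to a binary mask
#'
#' A voxel is foreground iff its center lies strictly within the segment
#' radius of some centerline (exact point-to-segment distance; centers
#' exactly on the tube wall are excluded symmetrically, so a tube of radius
#' exactly one voxel rasterizes to a single-voxel column).
#'
#' @param graph A \linkS4class{GroundTruthGraph}.
#' @param spec The \linkS4class{PhantomSpec} providing grid and spacing.
#' @return A \linkS4class{BinaryMask}.
#' @export
rasterizeTreeMask <- function(graph, spec) {
  stopifnot(is(graph, "GroundTruthGraph"), is(spec, "PhantomSpec"))
  if (nrow(graph@segments) > 0) .checkTreeInGrid(graph, spec)
  m <- .rasterize_tubes_cpp(spec@gridShape, spec@spacingUm,
                            unname(graph@polylines),
                            graph@segments$radius_um)
  BinaryMask(array(m, dim = spec@gridShape), spec@spacingUm)
}

#' Rasterize a ground-truth tree to a grayscale volume
#'
#' Foreground voxels receive \code{foregroundIntensity}, background voxels
#' \code{backgroundIntensity} (degradation is a separate step, see
#' \code{\link{degradeVolume}}).
#'
#' @inheritParams rasterizeTreeMask
#' @return A \linkS4class{Volume3D}.
#' @export
rasterizeTree <- function(graph, spec) {
  m <- rasterizeTreeMask(graph, spec)
  v <- array(spec@backgroundIntensity, dim = spec@gridShape)
  v[voxelData(m)] <- spec@foregroundIntensity
  Volume3D(v, spec@spacingUm)
}

#' Degrade a phantom volume with blur and noise
#'
#' Applies Gaussian partial-volume blur (half-sample-symmetric boundary, so
#' the volume mean is conserved) followed by seeded additive Gaussian noise,
#' then clips to the valid gray range (8-bit [0, 255], or 16-bit when the
#' spec intensities exceed 255). Noise uses \code{spec@seed + 1} so it is
#' reproducible yet independent of the tree-geometry jitter stream.
#'
#' @param vol A \linkS4class{Volume3D}.
#' @param spec The \linkS4class{PhantomSpec} providing blur/noise parameters.
#' @return A degraded \linkS4class{Volume3D}.
#' @export
degradeVolume <- function(vol, spec) {
  stopifnot(is(vol, "Volume3D"), is(spec, "PhantomSpec"))
  v <- vol@values
  d <- dim(v)
  if (spec@blurSigmaUm > 0) {
    sig <- spec@blurSigmaUm / vol@spacing
    v <- array(.gaussian_blur3d_cpp(as.numeric(v), d, sig), dim = d)
  }
  if (spec@noiseSigma > 0) {
    v <- v + .withSeed(spec@seed + 1L,
                       array(stats::rnorm(length(v), 0, spec@noiseSigma),
                             dim = d))
  }
  hi <- if (max(spec@foregroundIntensity, spec@backgroundIntensity) <= 255)
    255 else 65535
  v[v < 0] <- 0
  v[v > hi] <- hi
  Volume3D(v, vol@spacing)
}

.insideCavity <- function(P, injury) {
  # rows of P inside the (open) unit ellipsoid around the epicenter
  ax <- injury@cavitySemiaxesUm
  if (all(ax == 0)) return(rep(FALSE, nrow(P)))
  q <- sweep(P, 2, injury@epicenterUm)
  rowSums(sweep(q, 2, ax, "/")^2) <= 1
}

#' Apply the injury model to a phantom
#'
#' Carves a prolate ellipsoidal avascular cavity into the ground truth and
#' tilts branches near the epicenter (rostral branches rostrally by
#' \code{+tiltDeg}, caudal branches caudally by \code{-tiltDeg}). The ground
#' truth is edited first -- segments fully inside the cavity are removed and
#' crossing segments truncated with new endpoint nodes -- and the returned
#' volume is re-rasterized from the edited tree with the cavity carved, which
#' keeps graph and volume exactly consistent. Apply injury before
#' \code{\link{degradeVolume}}.
#'
#' @param graph A \linkS4class{GroundTruthGraph}.
#' @param vol The matching clean \linkS4class{Volume3D} (returned unchanged
#'   if the injury is a no-op).
#' @param injury An \linkS4class{InjurySpec}.
#' @param spec The \linkS4class{PhantomSpec} used to build the phantom.
#' @return A list with elements \code{graph} and \code{volume}.
#' @export
applyInjury <- function(graph, vol, injury, spec) {
  stopifnot(is(graph, "GroundTruthGraph"), is(vol, "Volume3D"),
            is(injury, "InjurySpec"), is(spec, "PhantomSpec"))
  ext <- (spec@gridShape - 1) * spec@spacingUm
  if (any(injury@epicenterUm < 0) || any(injury@epicenterUm > ext))
    stop("injury epicenter lies outside the grid")
  if (all(injury@cavitySemiaxesUm == 0) && injury@tiltDeg == 0)
    return(list(graph = graph, volume = vol))
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  if (all(.insideCavity(corners, injury)))
    stop("cavity covers the whole grid; no vasculature would remain")

  segs <- graph@segments
  polys <- graph@polylines
  nodes <- graph@nodes
  nodePos <- as.matrix(nodes[, c("x", "y", "z")])

  # --- tilt: rotate qualifying branches (and their subtrees) about their
  # proximal node; rotations compose down the tree
  if (injury@tiltDeg != 0 && injury@tiltExtentUm > 0 && nrow(segs) > 0) {
    children <- split(seq_len(nrow(segs)), segs$from)
    newPos <- nodePos
    rotOf <- rep(list(diag(3)), nrow(nodes))
    roots <- setdiff(segs$from, segs$to)
    queue <- unlist(children[as.character(roots)], use.names = FALSE)
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      from <- segs$from[i]; to <- segs$to[i]
      R <- rotOf[[from]]
      p0old <- nodePos[from, ]
      p0new <- newPos[from, ]
      P <- polys[[i]]
      u <- P[nrow(P), ] - P[1, ]
      qual <- segs$level[i] >= 1L &&
        abs(p0old[3] - injury@epicenterUm[3]) <= injury@tiltExtentUm
      if (qual) {
        sgn <- if (p0old[3] >= injury@epicenterUm[3]) 1 else -1
        udir <- as.numeric(R %*% u)
        ax <- c(udir[2], -udir[1], 0)          # cross(u, z-hat)
        if (sqrt(sum(ax^2)) < 1e-8) ax <- c(0, 1, 0)
        ax <- ax / sqrt(sum(ax^2))
        # rotation about +(u x z-hat) tilts u toward +z (rostral); flip the
        # axis on the caudal side
        R <- .rodrigues(ax * sgn, injury@tiltDeg) %*% R
      }
      Pnew <- t(p0new + R %*% (t(P) - p0old))
      polys[[i]] <- Pnew
      segs$angle_deg[i] <- .signedAngleToTrunk(Pnew[nrow(Pnew), ] - Pnew[1, ])
      newPos[to, ] <- Pnew[nrow(Pnew), ]
      rotOf[[to]] <- R
      kids <- children[[as.character(to)]]
      if (!is.null(kids)) queue <- c(queue, kids)
    }
    nodes$x <- newPos[, 1]; nodes$y <- newPos[, 2]; nodes$z <- newPos[, 3]
    nodePos <- newPos
  }

  # --- cavity: remove enclosed segments, truncate crossing ones
  if (any(injury@cavitySemiaxesUm > 0) && nrow(segs) > 0) {
    step <- min(spec@spacingUm) / 2
    keepSegs <- list(); keepPolys <- list(); nextNode <- nrow(nodes)
    newNodes <- list()
    for (i in seq_len(nrow(segs))) {
      P <- polys[[i]]
      # densify so truncation lands on the cavity wall to sub-voxel accuracy
      Pd <- .densifyPolyline(P, step)
      ins <- .insideCavity(Pd, injury)
      if (all(ins)) next                      # segment fully enclosed
      if (!any(ins)) {
        keepSegs[[length(keepSegs) + 1L]] <- segs[i, ]
        keepPolys[[length(keepPolys) + 1L]] <- P
        next
      }
      runs <- rle(!ins)
      ends <- cumsum(runs$lengths)
      starts <- c(1L, ends[-length(ends)] + 1L)
      for (r in which(runs$values)) {
        idx <- starts[r]:ends[r]
        if (length(idx) < 2L) next
        Q <- Pd[idx, , drop = FALSE]
        L <- sum(sqrt(rowSums((Q[-1, , drop = FALSE] -
                               Q[-nrow(Q), , drop = FALSE])^2)))
        if (L < min(spec@spacingUm)) next
        fromId <- segs$from[i]; toId <- segs$to[i]
        if (idx[1] != 1L) {                   # proximal end cut: new endpoint
          nextNode <- nextNode + 1L
          newNodes[[length(newNodes) + 1L]] <-
            data.frame(id = nextNode, x = Q[1, 1], y = Q[1, 2], z = Q[1, 3],
                       kind = "endpoint", stringsAsFactors = FALSE)
          fromId <- nextNode
        }
        if (idx[length(idx)] != nrow(Pd)) {   # distal end cut: new endpoint
          nextNode <- nextNode + 1L
          newNodes[[length(newNodes) + 1L]] <-
            data.frame(id = nextNode, x = Q[nrow(Q), 1], y = Q[nrow(Q), 2],
                       z = Q[nrow(Q), 3], kind = "endpoint",
                       stringsAsFactors = FALSE)
          toId <- nextNode
        }
        s <- segs[i, ]
        s$from <- fromId; s$to <- toId; s$length_um <- L
        keepSegs[[length(keepSegs) + 1L]] <- s
        keepPolys[[length(keepPolys) + 1L]] <- Q
      }
    }
    segs <- if (length(keepSegs)) do.call(rbind, keepSegs) else segs[0, ]
    polys <- keepPolys
    if (length(newNodes)) nodes <- rbind(nodes, do.call(rbind, newNodes))
    # drop orphaned nodes, relabel kinds by surviving degree
    used <- unique(c(segs$from, segs$to))
    nodes <- nodes[nodes$id %in% used, , drop = FALSE]
    deg <- table(factor(c(segs$from, segs$to), levels = nodes$id))
    nodes$kind <- ifelse(deg >= 3, "bifurcation",
                         ifelse(deg == 2, "passthrough", "endpoint"))
    if (nrow(segs)) segs$id <- seq_len(nrow(segs))
    rownames(nodes) <- NULL; rownames(segs) <- NULL
  }

  g2 <- new("GroundTruthGraph", nodes = nodes, segments = segs,
            polylines = stats::setNames(polys,
                                        as.character(seq_len(length(polys)))))

  # volume: re-rasterize the edited tree, then carve the cavity
  v2 <- rasterizeTree(g2, spec)
  if (any(injury@cavitySemiaxesUm > 0)) {
    d <- dim(v2@values)
    ax <- injury@cavitySemiaxesUm
    cx <- ((seq_len(d[1]) - 1) * spec@spacingUm[1] - injury@epicenterUm[1]) / ax[1]
    cy <- ((seq_len(d[2]) - 1) * spec@spacingUm[2] - injury@epicenterUm[2]) / ax[2]
    cz <- ((seq_len(d[3]) - 1) * spec@spacingUm[3] - injury@epicenterUm[3]) / ax[3]
    inside <- outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= 1
    vv <- v2@values
    vv[inside] <- spec@backgroundIntensity
    v2 <- Volume3D(vv, v2@spacing)
  }
  list(graph = g2, volume = v2)
}

.densifyPolyline <- function(P, step) {
  if (nrow(P) < 2L) return(P)
  out <- list(P[1, , drop = FALSE])
  for (e in seq_len(nrow(P) - 1L)) {
    a <- P[e, ]; b <- P[e + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq_len(k) / k
    out[[e + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                           a[2] + t * (b[2] - a[2]),
                           a[3] + t * (b[3] - a[3]))
  }
  M <- do.call(rbind, out)
  dimnames(M) <- NULL
  M
}

#' Generate a complete phantom in one call
#'
#' Runs tree generation, rasterization, optional injury, and degradation.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param injury Optional \linkS4class{InjurySpec}; \code{NULL} for an
#'   uninjured phantom.
#' @param degrade apply blur and noise per the phantom parameters (default
#'   TRUE).
#' @return A list: \code{volume} (degraded \linkS4class{Volume3D}),
#'   \code{cleanVolume}, \code{mask} (ground-truth \linkS4class{BinaryMask},
#'   post-injury), and \code{graph} (\linkS4class{GroundTruthGraph}).
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = 64L, branchLevels = 1L,
#'                                   trunkRadiusUm = 11.1, noiseSigma = 0))
#' nrow(graphSegments(ph$graph))  # 3 segments: trunk + 2 children
#' @export
generatePhantom <- function(spec, injury = NULL, degrade = TRUE) {
  g <- generateTree(spec)
  v <- rasterizeTree(g, spec)
  if (!is.null(injury)) {
    inj <- applyInjury(g, v, injury, spec)
    g <- inj$graph
    v <- inj$volume
  }
  mask <- rasterizeTreeMask(g, spec)
  if (!is.null(injury) && any(injury@cavitySemiaxesUm > 0)) {
    mv <- voxelData(mask)
    mv[voxelData(v) == spec@backgroundIntensity] <- FALSE
    mask <- BinaryMask(mv, spec@spacingUm)
  }
  dv <- if (degrade) degradeVolume(v, spec) else v
  list(volume = dv, cleanVolume = v, mask = mask, graph = g)
}
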