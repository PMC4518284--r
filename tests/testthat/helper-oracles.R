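# Independent oracles and fixture builders used across the suite. These are
# deliberately written with different algorithms/data structures than the
# package internals (brute force, flood fill, closed forms).

# O(n^2) nearest-background search: the reference for the distance map.
bruteForceEDT <- function(v, sp = c(1, 1, 1)) {
  D <- array(0, dim(v))
  fg <- which(v, arr.ind = TRUE)
  bg <- which(!v, arr.ind = TRUE)
  if (nrow(fg) == 0) return(D)
  stopifnot(nrow(bg) > 0)
  d2 <- outer(fg[, 1], bg[, 1], "-")^2 * sp[1]^2 +
    outer(fg[, 2], bg[, 2], "-")^2 * sp[2]^2 +
    outer(fg[, 3], bg[, 3], "-")^2 * sp[3]^2
  D[which(v)] <- sqrt(apply(d2, 1, min))
  D
}

# Queue-based flood fill, independent of the package's stack-based BFS.
floodFillCount <- function(v, connectivity = 26) {
  d <- dim(v)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  seen <- array(FALSE, d)
  count <- 0L
  idx <- which(v, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (seen[p[1], p[2], p[3]]) next
    count <- count + 1L
    queue <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(off))) {
        n <- q + off[k, ]
        if (any(n < 1) || any(n > d)) next
        if (v[n[1], n[2], n[3]] && !seen[n[1], n[2], n[3]]) {
          seen[n[1], n[2], n[3]] <- TRUE
          queue[[length(queue) + 1L]] <- n
        }
      }
    }
  }
  count
}

# Brute-force tube rasterization (point-to-segment distance in R), with the
# same boundary-inclusion convention as the package rasterizer.
bruteRasterize <- function(dims, sp, polylines, radii) {
  grid <- as.matrix(expand.grid(x = (seq_len(dims[1]) - 1) * sp[1],
                                y = (seq_len(dims[2]) - 1) * sp[2],
                                z = (seq_len(dims[3]) - 1) * sp[3]))
  fg <- rep(FALSE, nrow(grid))
  for (s in seq_along(polylines)) {
    P <- polylines[[s]]
    r2 <- radii[s]^2 * (1 - 1e-12)
    for (e in seq_len(max(1, nrow(P) - 1))) {
      A <- P[min(e, nrow(P)), ]
      B <- P[min(e + 1, nrow(P)), ]
      AB <- B - A
      den <- sum(AB^2)
      rel <- sweep(grid, 2, A)
      t <- if (den > 0) pmin(1, pmax(0, rel %*% AB / den)) else rep(0, nrow(grid))
      d2 <- rowSums((rel - t %*% t(AB))^2)
      fg <- fg | (d2 < r2)
    }
  }
  array(fg, dims)
}

# Axis-aligned solid cylinder mask (voxel units, 1-based integer center).
cylinderMask <- function(dims, center, rVox, zRange) {
  v <- array(FALSE, dims)
  for (z in zRange[1]:zRange[2])
    for (y in seq_len(dims[2]))
      for (x in seq_len(dims[1]))
        if ((x - center[1])^2 + (y - center[2])^2 <= rVox^2)
          v[x, y, z] <- TRUE
  v
}

# Y-shaped tube: vertical trunk with two oblique arms.
yTubeMask <- function() {
  dims <- c(40L, 40L, 48L)
  p0 <- c(20, 20, 5) * 1.0
  pj <- c(20, 20, 24) * 1.0
  pa <- c(30, 20, 40) * 1.0
  pb <- c(10, 20, 40) * 1.0
  bruteRasterize(dims, c(1, 1, 1),
                 list(rbind(p0, pj), rbind(pj, pa), rbind(pj, pb)),
                 c(3, 2.5, 2.5))
}

# Hollow torus in the xy-plane.
torusMask <- function(R = 10, r = 3, dims = c(32L, 32L, 12L)) {
  v <- array(FALSE, dims)
  cx <- 16; cy <- 16; cz <- 6
  for (z in seq_len(dims[3]))
    for (y in seq_len(dims[2]))
      for (x in seq_len(dims[1])) {
        rho <- sqrt((x - cx)^2 + (y - cy)^2)
        if ((rho - R)^2 + (z - cz)^2 <= r^2) v[x, y, z] <- TRUE
      }
  v
}

# Random blob mask with a guaranteed background voxel.
randomMask <- function(dims, pFg = 0.35) {
  v <- array(stats::runif(prod(dims)) < pFg, dims)
  v[1, 1, 1] <- FALSE
  v
}

# Segment-graph forest check: acyclic iff #segments = #attached nodes - #comp
graphIsForest <- function(g) {
  segs <- graphSegments(g)
  if (any(segs$cyclic)) return(FALSE)
  if (nrow(segs) == 0) return(TRUE)
  ig <- igraph::graph_from_data_frame(segs[, c("from", "to")],
                                      directed = FALSE)
  !any(igraph::which_loop(ig)) && igraph::is_forest(ig)
}

# Pooled two-sample t closed form, independent of stats::t.test.
pooledTClosedForm <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

skeletonFromMask <- function(v, sp = c(1, 1, 1)) {
  skeletonize3D(BinaryMask(v, sp))
}
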