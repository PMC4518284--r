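test_that("tree generation produces the expected topology", {
  # degenerate tree: a single trunk
  g0 <- generateTree(phantomSpec(gridShape = 64L, branchLevels = 0L))
  expect_identical(nrow(graphSegments(g0)), 1L)
  expect_identical(nrow(graphNodes(g0)), 2L)
  expect_true(all(graphNodes(g0)$kind == "endpoint"))
  expect_identical(sum(graphNodes(g0)$kind == "bifurcation"), 0L)

  # two levels of bifurcation: 1 + 2 + 4 segments, 3 internal nodes
  g2 <- generateTree(phantomSpec())
  expect_identical(nrow(graphSegments(g2)), 7L)
  expect_identical(sum(graphNodes(g2)$kind == "bifurcation"), 3L)
  expect_identical(sum(graphNodes(g2)$kind == "endpoint"), 5L)

  # connected and acyclic
  ig <- igraph::graph_from_data_frame(graphSegments(g2)[, c("from", "to")],
                                      directed = FALSE)
  expect_true(igraph::is_connected(ig))
  expect_true(igraph::is_forest(ig))

  # node degrees: endpoints 1, bifurcations >= 3
  deg <- table(factor(c(graphSegments(g2)$from, graphSegments(g2)$to),
                      levels = graphNodes(g2)$id))
  expect_true(all(deg[graphNodes(g2)$kind == "endpoint"] == 1))
  expect_true(all(deg[graphNodes(g2)$kind == "bifurcation"] >= 3))

  # level-1 branch angles match the requested angle within the jitter half-width
  segs <- graphSegments(g2)
  lev1 <- segs$angle_deg[segs$level == 1L]
  expect_true(all(abs(lev1 - 45) <= 5 + 1e-9))

  # radii taper geometrically and stay in the admissible range
  expect_equal(sort(unique(segs$radius_um)),
               sort(18.5 * 0.8^(0:2)), tolerance = 1e-12)
})

test_that("tree generation is deterministic and validates its inputs", {
  expect_identical(generateTree(phantomSpec(seed = 11L)),
                   generateTree(phantomSpec(seed = 11L)))
  expect_false(identical(generateTree(phantomSpec(seed = 11L)),
                         generateTree(phantomSpec(seed = 12L))))
  # taper below one voxel is rejected, naming the offending level
  expect_error(generateTree(phantomSpec(trunkRadiusUm = 10, taperRatio = 0.55,
                                        branchLevels = 2L)),
               "level 2")
})

test_that("rasterization matches brute-force distance thresholding", {
  spec <- phantomSpec(gridShape = 48L, trunkRadiusUm = 11.1,
                      branchLevels = 1L, seed = 3L)
  g <- generateTree(spec)
  mask <- rasterizeTreeMask(g, spec)
  oracle <- bruteRasterize(spec@gridShape, spec@spacingUm,
                           unname(segmentPolylines(g)),
                           graphSegments(g)$radius_um)
  expect_identical(unname(voxelData(mask)), oracle)

  # empty graph rasterizes to pure background
  g0 <- new("GroundTruthGraph",
            nodes = graphNodes(g)[0, ], segments = graphSegments(g)[0, ],
            polylines = list())
  v0 <- rasterizeTree(g0, spec)
  expect_true(all(voxelData(v0) == spec@backgroundIntensity))
})

test_that("transverse slices of a straight trunk are discs of the right radius", {
  spec <- phantomSpec(gridShape = 48L, trunkRadiusUm = 18.5,
                      branchLevels = 0L)
  mask <- rasterizeTreeMask(generateTree(spec), spec)
  v <- voxelData(mask)
  zmid <- 24
  sl <- v[, , zmid]
  ctr <- which(sl, arr.ind = TRUE)
  cx <- floor((spec@gridShape[1] - 1) / 2) + 1
  rad <- sqrt((ctr[, 1] - cx)^2 + (ctr[, 2] - cx)^2)
  expect_lte(max(rad), 5 + 0.5)
  # every lattice point strictly inside the disc is foreground
  for (x in seq_len(48)) for (y in seq_len(48))
    if ((x - cx)^2 + (y - cx)^2 <= (5 - 0.5)^2)
      expect_true(sl[x, y])
})

test_that("a radius-1-voxel tube rasterizes to a 26-connected path", {
  spec <- phantomSpec(gridShape = 32L, trunkRadiusUm = 3.7,
                      branchLevels = 0L)
  mask <- rasterizeTreeMask(generateTree(spec), spec)
  expect_gt(sum(voxelData(mask)), 0)
  cc <- connectedComponents(mask, 26L)
  expect_identical(length(cc$sizes), 1L)
})

test_that("degradation preserves the mean under blur and is seeded", {
  spec <- phantomSpec(gridShape = 32L, branchLevels = 0L,
                      trunkRadiusUm = 11.1, blurSigmaUm = 5, noiseSigma = 0)
  v <- rasterizeTree(generateTree(spec), spec)
  b <- degradeVolume(v, spec)
  expect_equal(mean(voxelData(b)), mean(voxelData(v)), tolerance = 1e-6)

  # blur 0 / noise 0 is the identity
  spec0 <- phantomSpec(gridShape = 32L, branchLevels = 0L,
                       trunkRadiusUm = 11.1, blurSigmaUm = 0, noiseSigma = 0)
  expect_identical(voxelData(degradeVolume(v, spec0)), voxelData(v))

  # seeded noise is reproducible
  specN <- phantomSpec(gridShape = 32L, branchLevels = 0L,
                       trunkRadiusUm = 11.1, noiseSigma = 20, seed = 5L)
  expect_identical(voxelData(degradeVolume(v, specN)),
                   voxelData(degradeVolume(v, specN)))
  specM <- phantomSpec(gridShape = 32L, branchLevels = 0L,
                       trunkRadiusUm = 11.1, noiseSigma = 20, seed = 6L)
  expect_false(identical(voxelData(degradeVolume(v, specN)),
                         voxelData(degradeVolume(v, specM))))
})

test_that("identical spec and seed give bit-identical phantom and truth", {
  a <- generatePhantom(phantomSpec(gridShape = 48L, branchLevels = 1L,
                                   trunkRadiusUm = 11.1, seed = 9L))
  b <- generatePhantom(phantomSpec(gridShape = 48L, branchLevels = 1L,
                                   trunkRadiusUm = 11.1, seed = 9L))
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(a$graph, b$graph)
})

test_that("the injury model edits graph and volume consistently", {
  spec <- phantomSpec(seed = 2L, noiseSigma = 0, blurSigmaUm = 0)
  g <- generateTree(spec)
  v <- rasterizeTree(g, spec)

  # zero cavity and zero tilt: exact identity
  inj0 <- injurySpec(c(100, 100, 100), cavitySemiaxesUm = c(0, 0, 0),
                     tiltDeg = 0)
  out0 <- applyInjury(g, v, inj0, spec)
  expect_identical(out0$graph, g)
  expect_identical(out0$volume, v)

  # cavity enclosing one whole leaf branch: segment count drops by the
  # number of enclosed segments (point-in-ellipsoid oracle on the truth)
  segs <- graphSegments(g)
  leaf <- which(segs$level == 2L)[1]
  P <- segmentPolylines(g)[[leaf]]
  mid <- (P[1, ] + P[nrow(P), ]) / 2
  semi <- c(70, 70, 90)
  inj <- injurySpec(mid, cavitySemiaxesUm = semi, tiltDeg = 0)
  inside <- function(Q) all(colSums(((t(Q) - mid) / semi)^2) <= 1)
  nEnclosed <- sum(vapply(segmentPolylines(g), inside, TRUE))
  expect_gte(nEnclosed, 1)
  out <- applyInjury(g, v, inj, spec)
  expect_identical(nrow(graphSegments(out$graph)),
                   nrow(segs) - as.integer(nEnclosed))

  # epicenter outside the grid and an all-covering cavity are rejected
  expect_error(applyInjury(g, v, injurySpec(c(-10, 0, 0)), spec),
               "outside")
  expect_error(applyInjury(g, v, injurySpec(
    (spec@gridShape - 1) * spec@spacingUm / 2,
    cavitySemiaxesUm = c(5e4, 5e4, 5e4)), spec),
    "whole grid")
})

test_that("enlarging the cavity never increases the remaining foreground", {
  spec <- phantomSpec(gridShape = 64L, seed = 4L, trunkRadiusUm = 11.1,
                      branchLevels = 1L, noiseSigma = 0, blurSigmaUm = 0)
  epi <- (spec@gridShape - 1) * spec@spacingUm / 2
  prev <- Inf
  for (s in c(20, 50, 80, 110)) {
    ph <- generatePhantom(spec, injurySpec(epi, c(s, s, 1.5 * s),
                                           tiltDeg = 0), degrade = FALSE)
    fg <- sum(voxelData(ph$mask))
    expect_lte(fg, prev)
    prev <- fg
  }
})

test_that("tilting rotates branch angles by the signed tilt", {
  spec <- phantomSpec(seed = 7L, noiseSigma = 0, blurSigmaUm = 0,
                      angleJitterDeg = 0)
  g <- generateTree(spec)
  v <- rasterizeTree(g, spec)
  # trunk junction is rostral of the cavity epicenter placed caudally
  epiZ <- graphNodes(g)$z[graphNodes(g)$kind == "bifurcation"][1]
  inj <- injurySpec(c(117.5, 117.5, epiZ - 1), cavitySemiaxesUm = c(0, 0, 0),
                    tiltDeg = 10, tiltExtentUm = 50)
  out <- applyInjury(g, v, inj, spec)
  a0 <- graphSegments(g)$angle_deg
  a1 <- graphSegments(out$graph)$angle_deg
  lev <- graphSegments(g)$level
  # level-1 branches sit within the tilt extent, rostral side: rotated
  # toward the rostral axis by 10 degrees (signed angle decreases)
  expect_equal(a1[lev == 1L], a0[lev == 1L] - 10, tolerance = 1e-6)
  expect_equal(a1[lev == 0L], a0[lev == 0L], tolerance = 1e-9)
})

test_that("phantom spec validity enforces the documented invariants", {
  expect_error(phantomSpec(taperRatio = 0), "taperRatio")
  expect_error(phantomSpec(foregroundIntensity = 10,
                           backgroundIntensity = 50), "exceed")
  expect_error(phantomSpec(radiusRangeUm = c(1, 50)), "voxel spacing")
  expect_error(phantomSpec(trunkRadiusUm = 60), "radiusRangeUm")
  expect_error(injurySpec(c(0, 0, 0), cavitySemiaxesUm = c(50, 50, 20)),
               "spindle")
})
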