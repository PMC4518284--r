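# hand-drawn thin skeletons used by several blocks
drawSkeleton <- function(dims, voxels, sp = 1) {
  v <- array(FALSE, dims)
  v[voxels] <- TRUE
  new("Skeleton3D", values = v, spacing = rep(sp, 3))
}

lineVoxels <- function(dims, pts) {
  # linear indices of a voxel list given as an n x 3 matrix
  pts[, 1] + (pts[, 2] - 1) * dims[1] + (pts[, 3] - 1) * dims[1] * dims[2]
}

test_that("skeleton voxels classify by neighbor count", {
  dims <- c(15L, 15L, 15L)
  # straight path of 10
  sk <- drawSkeleton(dims, lineVoxels(dims, cbind(3, 3, 3:12)))
  cls <- classifySkeletonVoxels(sk)
  expect_identical(unname(cls$counts), c(2L, 8L, 0L))

  # Y: three arms meeting at one voxel
  arms <- rbind(cbind(8, 8, 3:7),            # vertical below junction
                cbind(8 + 1:4, 8, 8 + 1:4),  # up-right
                cbind(8 - 1:4, 8, 8 + 1:4),  # up-left
                c(8, 8, 8))                  # junction voxel
  sk <- drawSkeleton(dims, lineVoxels(dims, arms))
  cls <- classifySkeletonVoxels(sk)
  expect_identical(unname(cls$counts["junction"]), 1L)
  expect_identical(unname(cls$counts["endpoint"]), 3L)

  # isolated voxel is an endpoint by convention, with a message
  sk <- drawSkeleton(dims, lineVoxels(dims, cbind(5, 5, 5)))
  expect_message(cls <- classifySkeletonVoxels(sk), "isolated")
  expect_identical(unname(cls$counts["endpoint"]), 1L)
})

test_that("graph building recovers Y topology and cycles", {
  dims <- c(15L, 15L, 15L)
  arms <- rbind(cbind(8, 8, 3:7), cbind(8 + 1:4, 8, 8 + 1:4),
                cbind(8 - 1:4, 8, 8 + 1:4), c(8, 8, 8))
  g <- buildVesselGraph(drawSkeleton(dims, lineVoxels(dims, arms)))
  expect_identical(nrow(graphSegments(g)), 3L)  # VN
  expect_identical(sum(graphNodes(g)$kind == "junction"), 1L)  # VNN
  expect_true(all(graphNodes(g)$degree[graphNodes(g)$kind == "junction"] == 3))

  # closed diamond ring (each voxel has exactly two neighbors): one cyclic
  # segment, no nodes
  ring <- NULL
  for (dx in -5:5) {
    dy <- 5 - abs(dx)
    ring <- rbind(ring, c(8 + dx, 8 + dy, 5))
    if (dy > 0) ring <- rbind(ring, c(8 + dx, 8 - dy, 5))
  }
  g <- buildVesselGraph(drawSkeleton(dims, lineVoxels(dims, ring)))
  expect_identical(nrow(graphSegments(g)), 1L)
  expect_true(graphSegments(g)$cyclic)
  expect_identical(sum(graphNodes(g)$kind == "junction"), 0L)

  # empty skeleton: empty graph
  g <- buildVesselGraph(drawSkeleton(dims, integer(0)))
  expect_identical(nrow(graphSegments(g)), 0L)
  expect_identical(nrow(graphNodes(g)), 0L)
})

test_that("segment length is the spacing-aware arc length", {
  dims <- c(12L, 12L, 12L)
  sk <- drawSkeleton(dims, lineVoxels(dims, cbind(3, 3, 2:11)), sp = 3.7)
  g <- buildVesselGraph(sk)
  expect_equal(graphSegments(g)$length_um, 9 * 3.7, tolerance = 1e-9)
  # diagonal steps
  sk <- drawSkeleton(dims, lineVoxels(dims, cbind(2:9, 2:9, 5)), sp = 2)
  g <- buildVesselGraph(sk)
  expect_equal(graphSegments(g)$length_um, 7 * 2 * sqrt(2), tolerance = 1e-9)
})

test_that("vessel volume counts voxels and converts units", {
  v <- array(FALSE, c(10, 10, 10))
  v[1:10, 1, 1] <- TRUE  # 10 voxels
  m <- BinaryMask(v, 3.7)
  out <- vesselVolume(m)
  expect_equal(out$fraction, 10 / 1000)
  expect_equal(out$mm3, 10 * 3.7^3 * 1e-9)

  # 100 voxels at 3.7 um isotropic: 5.0653e-6 mm^3
  v[] <- FALSE; v[1:10, 1:10, 1] <- TRUE
  expect_equal(vesselVolume(BinaryMask(v, 3.7))$mm3, 100 * 3.7^3 * 1e-9)
  expect_equal(vesselVolume(BinaryMask(v, 3.7))$mm3, 5.0653e-6,
               tolerance = 1e-4)

  # all-foreground ROI; empty mask
  expect_equal(vesselVolume(BinaryMask(array(TRUE, c(4, 4, 4)), 1))$fraction,
               1.0)
  expect_equal(vesselVolume(BinaryMask(array(FALSE, c(4, 4, 4)), 1))$mm3, 0)

  # ROI restriction and bounds checking
  roi <- ROI3D(c(0, 0, 0), c(10, 10, 1))
  expect_equal(vesselVolume(m, roi)$fraction, 10 / 100)
  expect_error(vesselVolume(m, ROI3D(c(0, 0, 0), c(11, 10, 1))), "bounds")
})

test_that("ROI half-open tiling partitions a volume", {
  set.seed(2)
  v <- BinaryMask(array(runif(8^3) < 0.4, c(8, 8, 8)), 1)
  total <- 0
  for (xl in c(0, 4)) for (zl in c(0, 2, 4, 6)) {
    roi <- ROI3D(c(xl, 0, zl), c(xl + 4, 8, zl + 2))
    vv <- vesselVolume(v, roi)
    total <- total + vv$fraction * 4 * 8 * 2
  }
  expect_equal(total, sum(voxelData(v)))
})

test_that("diameter distribution uses half-open bins over segments", {
  dims <- c(12L, 12L, 30L)
  sk <- drawSkeleton(dims, lineVoxels(dims, cbind(6, 6, 2:28)), sp = 1)
  g <- buildVesselGraph(sk)
  g@segments$diameter_um <- 20
  h <- diameterDistribution(g, c(0, 10, 20, 30))
  expect_identical(h$counts, c(0L, 0L, 1L))  # 20 falls in [20, 30)
  # empty graph: zero histogram
  g0 <- buildVesselGraph(drawSkeleton(dims, integer(0)))
  expect_identical(sum(diameterDistribution(g0)$counts), 0L)
})

test_that("signed bifurcation angles follow the rostro-caudal convention", {
  dims <- c(40L, 40L, 60L)
  trunk <- cbind(20, 20, 5:45)
  perp <- cbind(20 + 1:12, 20, 25)              # perpendicular arm
  rost <- cbind(20 - 1:12, 20, 25 + 1:12)       # 45 deg rostral
  caud <- cbind(20, 20 + 1:12, 25 - 1:12)       # 45 deg caudal
  sk <- drawSkeleton(dims, lineVoxels(dims, rbind(trunk, perp, rost, caud)))
  g <- buildVesselGraph(sk)
  ang <- bifurcationAngles(g)
  th <- sort(round(ang$theta_deg, 6))
  expect_true(any(abs(ang$theta_deg - 90) < 1e-6))   # perpendicular: +90
  expect_true(any(abs(ang$theta_deg - 45) < 1e-6))   # rostral: +45
  expect_true(any(abs(ang$theta_deg + 45) < 1e-6))   # caudal: -45
  expect_true(all(abs(ang$theta_deg) <= 90 + 1e-9))

  # branches too short for the direction fit are omitted with a warning
  short <- rbind(cbind(20, 20, 5:25), cbind(20 + 1:3, 20, 25))
  gs <- buildVesselGraph(drawSkeleton(dims, lineVoxels(dims, short)))
  expect_warning(a <- bifurcationAngles(gs), "omitted")
})

test_that("angles on rasterized phantom branches recover the truth", {
  spec <- phantomSpec(gridShape = 96L, trunkRadiusUm = 14.8,
                      branchLevels = 1L, branchAngleDeg = 60,
                      angleJitterDeg = 0, noiseSigma = 0, blurSigmaUm = 0)
  ph <- generatePhantom(spec, degrade = FALSE)
  edm <- euclideanDistanceMap(ph$mask)
  sk <- skeletonize3D(ph$mask)
  g <- buildVesselGraph(sk, radiusFromEDM(sk, edm))
  ang <- suppressWarnings(bifurcationAngles(g))
  got <- sort(ang$theta_deg[abs(ang$theta_deg) > 10])
  truth <- sort(graphSegments(ph$graph)$angle_deg[
    graphSegments(ph$graph)$level == 1L])
  expect_identical(length(got), length(truth))
  expect_lt(max(abs(got - truth)), 5)  # within 5 degrees
})

test_that("summarizeROI assembles a consistent report", {
  spec <- phantomSpec(gridShape = 64L, trunkRadiusUm = 11.1,
                      branchLevels = 1L, noiseSigma = 0, blurSigmaUm = 0)
  ph <- generatePhantom(spec, degrade = FALSE)
  edm <- euclideanDistanceMap(ph$mask)
  sk <- skeletonize3D(ph$mask)
  g <- buildVesselGraph(sk, radiusFromEDM(sk, edm))
  rep <- suppressWarnings(summarizeROI(ph$mask, g))
  expect_s4_class(rep, "MorphometryReport")
  expect_identical(rep@vn, nrow(graphSegments(g)))
  expect_identical(rep@vnn, sum(graphNodes(g)$kind == "junction"))
  expect_identical(sum(rep@histCounts), rep@vn)     # conservation
  expect_equal(rep@vvFraction * prod(dim(ph$mask)) * prod(spacingUm(ph$mask)) *
               1e-9, rep@vvMm3, tolerance = 1e-12)

  # empty mask: all-zero report
  em <- BinaryMask(array(FALSE, c(8, 8, 8)), 3.7)
  esk <- new("Skeleton3D", values = array(FALSE, c(8, 8, 8)),
             spacing = rep(3.7, 3))
  rep0 <- summarizeROI(em, buildVesselGraph(esk))
  expect_identical(rep0@vn, 0L)
  expect_identical(rep0@vnn, 0L)
  expect_equal(rep0@vvFraction, 0)

  # segment lengths are bounded by the skeleton size
  expect_lte(sum(graphSegments(g)$length_um),
             sum(voxelData(sk)) * sqrt(3) * max(spacingUm(sk)))
})

test_that("spur pruning removes only short endpoint branches", {
  dims <- c(30L, 30L, 30L)
  main <- cbind(15, 15, 3:27)
  spur <- cbind(15 + 1:3, 15, 15)
  sk <- drawSkeleton(dims, lineVoxels(dims, rbind(main, spur)))
  g <- buildVesselGraph(sk)
  expect_identical(nrow(graphSegments(g)), 3L)  # spur splits the main line
  gp <- pruneSpurs(g, minLengthUm = 5)
  expect_identical(nrow(graphSegments(gp)), 2L)
  # pruning with a tiny threshold removes nothing
  expect_identical(nrow(graphSegments(pruneSpurs(g, 0.5))), 3L)
})
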