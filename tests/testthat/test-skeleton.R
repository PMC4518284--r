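test_that("distance map equals the brute-force oracle exactly", {
  # single foreground voxel, unit spacing
  v <- array(FALSE, c(5, 5, 5)); v[3, 3, 3] <- TRUE
  edm <- euclideanDistanceMap(BinaryMask(v, 1))
  expect_identical(voxelData(edm)[3, 3, 3], 1)
  expect_identical(sum(voxelData(edm) != 0), 1L)

  # arbitrary random masks, exact equality with the O(n^2) search
  set.seed(21)
  for (rep in 1:5) {
    v <- randomMask(c(12L, 12L, 12L))
    edm <- euclideanDistanceMap(BinaryMask(v, 1))
    expect_identical(unname(voxelData(edm)), bruteForceEDT(v))
  }
})

test_that("distance map honors anisotropic spacing", {
  v <- array(FALSE, c(7, 7, 7)); v[4, 4, 4] <- TRUE
  sp <- c(2, 3, 10)
  edm <- euclideanDistanceMap(BinaryMask(v, sp))
  expect_equal(voxelData(edm)[4, 4, 4], 2)  # nearest along cheapest axis
  set.seed(5)
  v <- randomMask(c(10L, 10L, 10L))
  edm <- euclideanDistanceMap(BinaryMask(v, sp))
  expect_equal(unname(voxelData(edm)), bruteForceEDT(v, sp),
               tolerance = 1e-12)
})

test_that("distance map is 1-Lipschitz along the grid", {
  set.seed(8)
  v <- randomMask(c(14L, 14L, 14L))
  d <- voxelData(euclideanDistanceMap(BinaryMask(v, 1)))
  dif <- abs(d[-1, , ] - d[-14, , ])
  expect_lte(max(dif), 1 + 1e-12)
})

test_that("distance map rejects an all-foreground mask", {
  expect_error(euclideanDistanceMap(BinaryMask(array(TRUE, c(3, 3, 3)), 1)),
               "all-foreground")
})

test_that("chamfer mode approximates the exact transform", {
  set.seed(13)
  v <- randomMask(c(12L, 12L, 12L))
  exact <- voxelData(euclideanDistanceMap(BinaryMask(v, 1)))
  cham <- voxelData(euclideanDistanceMap(BinaryMask(v, 1), chamfer = TRUE))
  # (3,4,5) chamfer error bound is ~10% of the true distance
  expect_lt(max(abs(cham - exact) / pmax(exact, 1)), 0.12)
  expect_error(euclideanDistanceMap(BinaryMask(v, c(1, 1, 2)), chamfer = TRUE),
               "isotropic")
})

test_that("centerline distance of a solid cylinder is its radius", {
  v <- cylinderMask(c(25L, 25L, 40L), c(13, 13), 5, c(5, 36))
  edm <- voxelData(euclideanDistanceMap(BinaryMask(v, 1)))
  core <- edm[13, 13, 12:30]  # away from the ends
  expect_true(all(abs(core - 5) <= 0.5))
})

test_that("thinning fixes single voxels and lines", {
  v <- array(FALSE, c(5, 5, 5)); v[3, 3, 3] <- TRUE
  expect_identical(voxelData(skeletonFromMask(v)), v)
  v <- array(FALSE, c(5, 5, 20)); v[3, 3, 3:18] <- TRUE
  expect_identical(voxelData(skeletonFromMask(v)), v)
})

test_that("a cylinder thins to a single endpoint-to-endpoint path", {
  v <- cylinderMask(c(25L, 25L, 60L), c(13, 13), 3, c(6, 55))
  sk <- skeletonFromMask(v)
  cls <- classifySkeletonVoxels(sk)
  expect_identical(unname(cls$counts["endpoint"]), 2L)
  expect_identical(unname(cls$counts["junction"]), 0L)
  expect_identical(length(connectedComponents(voxelData(sk), 26L)$sizes), 1L)
  # the skeleton lies on the true centerline away from the ends
  w <- which(voxelData(sk), arr.ind = TRUE)
  mid <- w[w[, 3] > 12 & w[, 3] < 49, , drop = FALSE]
  expect_true(all(mid[, 1] == 13 & mid[, 2] == 13))
})

test_that("thinning preserves component count and cycles on the fixtures", {
  fixtures <- list(
    cylinder = cylinderMask(c(20L, 20L, 30L), c(10, 10), 3, c(4, 27)),
    ytube = yTubeMask(),
    torus = torusMask(),
    twoTubes = {
      v <- cylinderMask(c(30L, 30L, 30L), c(8, 8), 2.5, c(4, 27))
      v | cylinderMask(c(30L, 30L, 30L), c(22, 22), 2.5, c(4, 27))
    })
  for (nm in names(fixtures)) {
    v <- fixtures[[nm]]
    sk <- skeletonFromMask(v)
    expect_identical(length(connectedComponents(voxelData(sk), 26L)$sizes),
                     length(connectedComponents(v, 26L)$sizes),
                     info = nm)
    g <- buildVesselGraph(sk)
    if (nm == "torus") {
      expect_true(any(graphSegments(g)$cyclic), info = nm)
      expect_identical(nrow(graphSegments(g)), 1L)
    } else {
      expect_true(graphIsForest(g), info = nm)
    }
  }
})

test_that("the skeleton is always a subset of its mask", {
  set.seed(17)
  for (rep in 1:3) {
    v <- sizeFilter(BinaryMask(randomMask(c(14L, 14L, 14L), 0.45), 1))
    sk <- skeletonize3D(v)
    expect_true(all(!voxelData(sk) | voxelData(v)))
    expect_identical(
      length(connectedComponents(voxelData(sk), 26L)$sizes),
      length(connectedComponents(voxelData(v), 26L)$sizes))
  }
})

test_that("radius map is the distance map restricted to the skeleton", {
  v <- cylinderMask(c(25L, 25L, 40L), c(13, 13), 5, c(5, 36))
  m <- BinaryMask(v, 3.7)
  edm <- euclideanDistanceMap(m)
  sk <- skeletonize3D(m)
  r <- radiusFromEDM(sk, edm)
  expect_true(all(voxelData(r)[!voxelData(sk)] == 0))
  expect_identical(voxelData(r)[voxelData(sk)],
                   voxelData(edm)[voxelData(sk)])
  # cylinder radius 5 voxels at 3.7 um spacing: ~18.5 um radius, ~37 um VD
  core <- voxelData(r)[13, 13, 12:30]
  expect_true(all(abs(core - 18.5) <= 3.7 / 2 + 1e-9))

  # empty skeleton gives an all-zero map
  e <- array(FALSE, c(4, 4, 4)); e[2, 2, 2] <- TRUE
  me <- BinaryMask(e, 3.7)
  ske <- new("Skeleton3D", values = array(FALSE, c(4, 4, 4)),
             spacing = c(3.7, 3.7, 3.7))
  expect_true(all(voxelData(radiusFromEDM(ske,
                                          euclideanDistanceMap(me))) == 0))
  expect_error(radiusFromEDM(skeletonize3D(me),
                             euclideanDistanceMap(BinaryMask(
                               array(c(TRUE, FALSE), c(2, 2, 2)), 3.7))),
               "shapes")
})

test_that("a radius-1-voxel tube reads out the 7.4 um detection floor", {
  spec <- phantomSpec(gridShape = 32L, trunkRadiusUm = 3.7,
                      branchLevels = 0L, noiseSigma = 0, blurSigmaUm = 0)
  ph <- generatePhantom(spec, degrade = FALSE)
  seg <- segmentVolume(ph$volume)
  expect_gt(sum(voxelData(seg$mask)), 0)
  edm <- euclideanDistanceMap(seg$mask)
  sk <- skeletonize3D(seg$mask)
  g <- buildVesselGraph(sk, radiusFromEDM(sk, edm))
  expect_identical(nrow(graphSegments(g)), 1L)
  expect_equal(graphSegments(g)$diameter_um, 7.4, tolerance = 1e-9)
})
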