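test_that("gradient is a physical-unit central difference", {
  v <- VoxelVolume(array(5, c(4, 4, 4)), c(1, 1, 3))
  g <- imageGradient(v)
  expect_true(all(vapply(g, function(x) all(x == 0), logical(1))))

  ramp <- array(0, c(6, 5, 4))
  for (i in 1:6) ramp[i, , ] <- 2.5 * (i - 1)
  gr <- imageGradient(VoxelVolume(ramp, c(0.5, 1, 3)))
  expect_true(all(gr[[1]][2:5, , ] == 2.5 / 0.5))
  expect_true(all(gr[[2]] == 0) && all(gr[[3]] == 0))

  set.seed(12)
  arr <- array(rnorm(125), c(5, 5, 5))
  vv <- VoxelVolume(arr, c(1, 1, 3))
  go <- gradientOracle(arr, c(1, 1, 3))
  gf <- imageGradient(vv)
  for (ax in 1:3) expect_identical(gf[[ax]], go[[ax]])

  expect_error(imageGradient(VoxelVolume(array(0, c(2, 5, 5)), c(1, 1, 1))),
               class = "cmbrst_small_grid")
})

test_that("saturation counts match direct shell enumeration", {
  for (sp in list(c(1, 1, 1), c(1, 1, 3), c(0.96, 0.96, 3), c(1, 1))) {
    for (r in c(1, 2, 3)) {
      expect_equal(cmbrst:::shellVoteCount(r, sp), shellCountOracle(r, sp),
                   info = sprintf("radius %g spacing %s", r,
                                  paste(sp, collapse = ",")))
    }
  }
})

test_that("constant input yields an all-zero symmetry map", {
  v <- VoxelVolume(array(42, c(10, 10, 6)), c(1, 1, 3))
  expect_true(all(mapValues(rstTransform(v, RSTParams())) == 0))
})

test_that("a dark sphere peaks at its center; bright spheres do not (dark polarity)", {
  ph <- generatePhantom(PhantomSpec(
    extents = c(32, 32, 32), spacingMM = c(1, 1, 1),
    spheres = data.frame(x = 15, y = 15, z = 15, diameter = 5, depth = 1),
    noiseSigma = 0, textureSigma = 0))
  dark <- phantomVolume(ph)
  m <- rstTransform(dark, RSTParams())
  am <- which(mapValues(m) == max(mapValues(m)), arr.ind = TRUE)[1, ] - 1L
  expect_true(all(abs(am - c(15, 15, 15)) <= 1))

  # invert the contrast: a bright sphere on dark background
  bright <- VoxelVolume(400 - voxelData(dark), voxelSpacing(dark))
  mb <- rstTransform(bright, RSTParams())
  expect_lte(mapValues(mb)[16, 16, 16],
             quantile(mapValues(mb), 0.95))
})

test_that("radii are interpreted in millimetres on anisotropic grids", {
  ph <- generatePhantom(PhantomSpec(
    extents = c(32, 32, 12), spacingMM = c(1, 1, 3),
    spheres = data.frame(x = 16, y = 16, z = 15, diameter = 5, depth = 1),
    noiseSigma = 0, textureSigma = 0))
  m <- rstTransform(phantomVolume(ph), RSTParams())
  am <- which(mapValues(m) == max(mapValues(m)), arr.ind = TRUE)[1, ] - 1L
  expect_true(all(abs(am - c(16, 16, 5)) <= 1))
})

test_that("map values can be read with a halo", {
  vals <- array(0, c(6, 6, 6))
  vals[3, 3, 3] <- 5; vals[4, 3, 3] <- 7; vals[6, 6, 6] <- 11
  map <- new("SymmetryMap", values = vals, spacing = c(1, 1, 1),
             params = RSTParams())
  expect_equal(rstValueAt(map, c(2, 2, 2), 0), 5)
  expect_equal(rstValueAt(map, c(2, 2, 2), 1), 7)
  expect_equal(rstValueAt(map, c(0, 0, 0), 99), max(vals))
  expect_error(rstValueAt(map, c(6, 0, 0), 0), class = "cmbrst_out_of_grid")
  expect_error(rstValueAt(map, c(1, 1, 1), -1), class = "cmbrst_bad_params")
})

test_that("whole-voxel translations shift the map values identically", {
  base <- PhantomSpec(extents = c(28, 28, 14), spacingMM = c(1, 1, 2),
                      spheres = data.frame(x = 12, y = 12, z = 12,
                                           diameter = 4, depth = 0.9),
                      noiseSigma = 0, textureSigma = 0)
  shifted <- PhantomSpec(extents = c(28, 28, 14), spacingMM = c(1, 1, 2),
                         spheres = data.frame(x = 15, y = 16, z = 16,
                                              diameter = 4, depth = 0.9),
                         noiseSigma = 0, textureSigma = 0)
  m1 <- mapValues(rstTransform(phantomVolume(generatePhantom(base)),
                               RSTParams(radiiMM = c(1, 2))))
  m2 <- mapValues(rstTransform(phantomVolume(generatePhantom(shifted)),
                               RSTParams(radiiMM = c(1, 2))))
  # compare away from the boundary: offset (3, 4, 2) voxels
  expect_equal(m2[10:24, 11:25, 5:11], m1[7:21, 7:21, 3:9],
               tolerance = 1e-9)
})

test_that("dark spheres outscore dark tubes of equal cross-section", {
  ph <- generatePhantom(PhantomSpec(
    extents = c(48, 48, 16), spacingMM = c(1, 1, 3),
    spheres = data.frame(x = 12, y = 12, z = 21, diameter = 5, depth = 0.8),
    tubes = list(list(points = cbind(c(34, 34), c(34, 34), c(0, 45)),
                      radius = 2.5, depth = 0.8)),
    noiseSigma = 0, textureSigma = 0))
  m <- mapValues(rstTransform(phantomVolume(ph), RSTParams()))
  sphereMax <- max(m[9:16, 9:16, ])
  tubeMax <- max(m[31:38, 31:38, ])
  expect_gt(sphereMax, tubeMax)
})
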