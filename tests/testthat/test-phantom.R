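test_that("a lesion-free phantom is pure textured background", {
  spec <- PhantomSpec(extents = c(24, 24, 10), seed = 4)
  ph <- generatePhantom(spec)
  expect_equal(nrow(phantomTruth(ph)), 0L)
  spread <- sqrt(spec@noiseSigma^2 + spec@textureSigma^2)
  expect_true(all(abs(voxelData(phantomVolume(ph)) - spec@backgroundMean) <
                    6 * spread))
  expect_true(any(voxelData(phantomMask(ph)) != 0))
})

test_that("spheres appear in the truth table with diameter-based labels", {
  spheres <- data.frame(x = c(10, 20, 30), y = c(10, 20, 10),
                        z = c(9, 15, 21), diameter = c(2.5, 3.0, 8),
                        depth = c(0.6, 0.7, 0.8))
  ph <- generatePhantom(PhantomSpec(extents = c(40, 40, 12),
                                    spheres = spheres, seed = 2))
  tr <- phantomTruth(ph)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$x_mm, spheres$x)
  expect_equal(tr$z_mm, spheres$z)
  expect_equal(tr$label, c("possible", "definite", "definite"))
})

test_that("lesions darken the volume as specified", {
  spheres <- data.frame(x = 15, y = 15, z = 15, diameter = 6, depth = 0.7)
  ph <- generatePhantom(PhantomSpec(extents = c(30, 30, 12),
                                    spacingMM = c(1, 1, 3),
                                    spheres = spheres, noiseSigma = 0,
                                    textureSigma = 0, seed = 1))
  center <- voxelData(phantomVolume(ph))[16, 16, 6]
  expect_lt(center, 200 * (1 - 0.7 / 2))
  # tube darkens along its axis but contributes nothing to truth
  ph2 <- generatePhantom(PhantomSpec(extents = c(30, 30, 12),
                                     spacingMM = c(1, 1, 3),
                                     tubes = list(list(
                                       points = cbind(c(15, 15), c(15, 15),
                                                      c(0, 33)),
                                       radius = 1.5, depth = 0.8)),
                                     planes = list(list(
                                       origin = c(5, 5, 5),
                                       normal = c(1, 0, 0), thickness = 1,
                                       depth = 0.5)),
                                     noiseSigma = 0, textureSigma = 0,
                                     seed = 1))
  expect_equal(nrow(phantomTruth(ph2)), 0L)
  expect_lt(voxelData(phantomVolume(ph2))[16, 16, 6], 60)
})

test_that("generation is deterministic in the spec and sensitive to the seed", {
  spec <- PhantomSpec(extents = c(20, 20, 8),
                      spheres = data.frame(x = 10, y = 10, z = 9,
                                           diameter = 4, depth = 0.8),
                      seed = 77)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxelData(phantomVolume(a)), voxelData(phantomVolume(b)))
  spec2 <- spec; spec2@seed <- 78L
  expect_false(identical(voxelData(phantomVolume(a)),
                         voxelData(phantomVolume(generatePhantom(spec2)))))
})

test_that("out-of-grid lesions are rejected", {
  expect_error(generatePhantom(PhantomSpec(
    extents = c(20, 20, 8),
    spheres = data.frame(x = 50, y = 10, z = 9, diameter = 4, depth = 0.8))),
    class = "cmbrst_out_of_grid")
  expect_error(generatePhantom(PhantomSpec(
    extents = c(20, 20, 8),
    tubes = list(list(points = cbind(c(5, 25), c(5, 5), c(5, 5)),
                      radius = 1, depth = 0.5)))),
    class = "cmbrst_out_of_grid")
})

test_that("the standard cohort reproduces its seeded structure", {
  co <- getStandardCohort()
  expect_length(co, 20L)
  nWith <- sum(vapply(co, function(p) nrow(phantomTruth(p)) > 0, logical(1)))
  # regression value for the fixed standard seed; close to the 53% carrier rate
  expect_equal(nWith, 11L)
  expect_true(all(vapply(co, function(p) length(p@spec@tubes) >= 3,
                         logical(1))))
  expect_true(all(vapply(co, function(p) length(p@spec@planes) >= 1,
                         logical(1))))
  diams <- unlist(lapply(co, function(p) p@spec@spheres$diameter))
  expect_true(all(diams >= 2 & diams <= 10))

  two <- standardCohort(2, seed = 1, extents = c(32, 32, 10))
  expect_length(two, 2L)
  other <- standardCohort(2, seed = 2, extents = c(32, 32, 10))
  expect_false(identical(voxelData(phantomVolume(two[[1]])),
                         voxelData(phantomVolume(other[[1]]))))
  expect_error(standardCohort(1), class = "cmbrst_bad_params")
})
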