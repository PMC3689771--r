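test_that("minIP patches equal the loop-based slab minimum", {
  set.seed(8)
  arr <- array(rnorm(9 * 9 * 3, 100, 15), c(9, 9, 3))
  v <- VoxelVolume(arr, c(1, 1, 3))
  cand <- list(i = 4L, j = 4L, k = 1L)
  patch <- extractMinipPatch(v, cand, MinIPSpec(slabThicknessMM = 12,
                                                roiHalfwidthMM = 3))
  # oracle: explicit per-voxel minimum over the slices within +/- 6 mm
  expectd <- matrix(0, 7, 7)
  for (a in 1:7) for (b in 1:7)
    expectd[a, b] <- min(arr[a + 1, b + 1, 1:3])
  expect_equal(voxelData(patch), expectd)
  expect_equal(voxelSpacing(patch), c(1, 1))
})

test_that("slab selection follows the +/- half-thickness rule on 3 mm slices", {
  arr <- array(0, c(5, 5, 10))
  for (k in 1:10) arr[, , k] <- k   # slice index encoded in intensity
  v <- VoxelVolume(arr, c(1, 1, 3))
  # interior candidate at 0-based k=4 (z = 12 mm): slices with |z - 12| <= 6
  # have 0-based k 2..6, i.e. 5 slices; their minimum intensity is 3
  p <- extractMinipPatch(v, list(i = 2L, j = 2L, k = 4L), MinIPSpec())
  expect_true(all(voxelData(p) == 3))
  # boundary candidate at k=0: slices 0..2 only
  p0 <- extractMinipPatch(v, list(i = 2L, j = 2L, k = 0L), MinIPSpec())
  expect_true(all(voxelData(p0) == 1))
  expect_error(extractMinipPatch(v, list(i = 2L, j = 2L, k = 10L),
                                 MinIPSpec()),
               class = "cmbrst_out_of_grid")
})

test_that("a single-slice volume projects to the windowed slice itself", {
  arr <- array(rnorm(11 * 11 * 1), c(11, 11, 1))
  v <- VoxelVolume(arr, c(1, 1, 3))
  p <- extractMinipPatch(v, list(i = 5L, j = 5L, k = 0L),
                         MinIPSpec(roiHalfwidthMM = 4))
  expect_equal(voxelData(p), arr[2:10, 2:10, 1])
})

test_that("t2d = 0 disables stage 2 entirely", {
  ph <- smallPhantom()
  nm <- rangeNormalize(phantomVolume(ph), phantomMask(ph))
  cand <- thresholdAndCluster(rstTransform(nm, RSTParams()),
                              phantomMask(ph), DetectionParams(1.5))
  out <- filterCandidates(nm, cand, RSTParams(), MinIPSpec(), t2d = 0)
  expect_true(all(out$status == "passed_2d"))
  expect_true(all(is.na(out$s2d)))
  expect_equal(out[, setdiff(names(out), c("status", "s2d"))],
               cand[, setdiff(names(cand), c("status", "s2d"))])
  expect_equal(nrow(filterCandidates(nm, cand[0, ], RSTParams(),
                                     MinIPSpec(), 1)), 0L)
})

test_that("a 2D threshold separates a sphere from a through-plane tube", {
  # flat background at detection scale: both lesions survive stage 1
  ph <- generatePhantom(PhantomSpec(
    extents = c(40, 40, 12), spacingMM = c(1, 1, 3),
    backgroundMean = 200, noiseSigma = 3, textureSigma = 0,
    spheres = data.frame(x = 13, y = 13, z = 15, diameter = 5, depth = 0.8),
    tubes = list(list(points = cbind(c(33, 28, 23), c(33, 28, 23),
                                     c(0, 16.5, 33)),
                      radius = 1.2, depth = 0.8)),
    seed = 6))
  vol <- phantomVolume(ph)
  map <- rstTransform(vol, RSTParams())
  cand <- thresholdAndCluster(map, phantomMask(ph), DetectionParams(0.3))
  mres <- matchCandidates(cand, phantomTruth(ph), 5)
  expect_equal(mres$tp, 1L)
  sphereRow <- which(cand$id == mres$pairs$candidate_id)
  tube <- ph@spec@tubes[[1]]
  dT <- pmin(
    cmbrst:::segmentDistance(cand$x_mm, cand$y_mm, cand$z_mm,
                             tube$points[1, ], tube$points[2, ]),
    cmbrst:::segmentDistance(cand$x_mm, cand$y_mm, cand$z_mm,
                             tube$points[2, ], tube$points[3, ]))
  tubeRow <- which(dT <= tube$radius + 2)[1]
  expect_false(is.na(tubeRow))
  scored <- filterCandidates(vol, cand[c(sphereRow, tubeRow), ], RSTParams(),
                             MinIPSpec(), t2d = 1e-9)
  expect_gt(scored$s2d[1], scored$s2d[2])
  mid <- mean(scored$s2d)
  out <- filterCandidates(vol, cand[c(sphereRow, tubeRow), ], RSTParams(),
                          MinIPSpec(), t2d = mid)
  expect_equal(out$status, c("passed_2d", "rejected_2d"))
})

test_that("raising t2d never enlarges the passed set", {
  ph <- smallPhantom()
  nm <- rangeNormalize(phantomVolume(ph), phantomMask(ph))
  cand <- thresholdAndCluster(rstTransform(nm, RSTParams()),
                              phantomMask(ph), DetectionParams(1.0))
  base <- filterCandidates(nm, cand, RSTParams(), MinIPSpec(), 0)
  prev <- base$id[base$status == "passed_2d"]
  for (t2 in c(0.25, 0.5, 1, 2)) {
    out <- filterCandidates(nm, cand, RSTParams(), MinIPSpec(), t2)
    passed <- out$id[out$status == "passed_2d"]
    expect_true(all(passed %in% prev),
                info = sprintf("t2d %.2f not nested", t2))
    prev <- passed
  }
})

test_that("invalid stage-2 configurations raise named errors", {
  ph <- smallPhantom()
  nm <- rangeNormalize(phantomVolume(ph), phantomMask(ph))
  cand <- data.frame(id = "c0001", i = 5L, j = 5L, k = 5L, x_mm = 5,
                     y_mm = 5, z_mm = 15, s3d = 2, s2d = NA_real_,
                     status = "pending", stringsAsFactors = FALSE)
  expect_error(filterCandidates(nm, cand, RSTParams(),
                                MinIPSpec(roiHalfwidthMM = 2), 1),
               class = "cmbrst_bad_params")
  expect_error(filterCandidates(nm, cand, RSTParams(), MinIPSpec(), -1),
               class = "cmbrst_bad_params")
})
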