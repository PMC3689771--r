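candAt <- function(xyz, ids = NULL) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  data.frame(id = ids %||% sprintf("c%04d", seq_len(n)),
             i = rep(0L, n), j = rep(0L, n), k = rep(0L, n),
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             s3d = rep(1, n), s2d = rep(NA_real_, n),
             status = rep("passed_2d", n), stringsAsFactors = FALSE)
}
truthAt <- function(xyz, labels = "definite") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(id = sprintf("mb%03d", seq_len(nrow(xyz))),
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             label = rep_len(labels, nrow(xyz)), stringsAsFactors = FALSE)
}

test_that("matching counts TP/FP/FN with one-to-one greedy pairing", {
  tr <- truthAt(c(0, 0, 0, 20, 0, 0, 0, 20, 0))
  m0 <- matchCandidates(candAt(numeric(0))[0, ], tr, 5)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0, 0, 3))
  expect_equal(m0$sensitivity, 0)

  mp <- matchCandidates(candAt(c(0, 0, 0, 20, 0, 0, 0, 20, 0)), tr, 5)
  expect_equal(c(mp$tp, mp$fp, mp$fn), c(3, 0, 0))
  expect_equal(mp$sensitivity, 1)

  # one candidate equidistant from two lesions within tolerance: the only
  # maximal one-to-one matchings have size 1 (enumerated by hand), so
  # exactly one pair forms and one lesion stays unmatched
  me <- matchCandidates(candAt(c(0, 0, 0)),
                        truthAt(c(3, 0, 0, -3, 0, 0)), 5)
  expect_equal(nrow(me$pairs), 1L)
  expect_equal(c(me$tp, me$fp, me$fn), c(1, 0, 1))
})

test_that("matching is invariant to row order and respects scope", {
  set.seed(77)
  tr <- truthAt(cbind(runif(6, 0, 50), runif(6, 0, 50), runif(6, 0, 30)),
                labels = c("definite", "possible"))
  cand <- candAt(cbind(runif(9, 0, 50), runif(9, 0, 50), runif(9, 0, 30)))
  a <- matchCandidates(cand, tr, 8)
  b <- matchCandidates(cand[sample(nrow(cand)), ], tr[sample(nrow(tr)), ], 8)
  expect_equal(a$tp, b$tp)
  expect_equal(a$fn, b$fn)
  expect_equal(a$pairs[order(a$pairs$truth_id), ],
               b$pairs[order(b$pairs$truth_id), ], ignore_attr = TRUE)

  d <- matchCandidates(cand, tr, 8, scope = "definite_only")
  expect_equal(d$tp + d$fn, sum(tr$label == "definite"))
})

test_that("a one-point grid equals a direct pipeline run", {
  ph <- smallPhantom()
  froc <- frocGrid(list(ph), RSTParams(), t3dValues = 1.0, t2dValues = 0.5)
  expect_equal(nrow(froc), 1L)
  direct <- detectMicrobleeds(phantomVolume(ph), phantomMask(ph),
                              DetectionParams(1.0, 0.5))
  passed <- direct$candidates[direct$candidates$status == "passed_2d", ]
  dm <- matchCandidates(passed, phantomTruth(ph), 5)
  expect_equal(froc$tp, dm$tp)
  expect_equal(froc$fp, dm$fp)
  expect_equal(froc$fn, dm$fn)
  expect_equal(froc$mean_candidates, nrow(passed))
})

test_that("cached lattice evaluation equals from-scratch runs at random points", {
  ph1 <- smallPhantom(seed = 2)
  ph2 <- smallPhantom(seed = 3, withSphere = FALSE)
  cohort <- list(ph1, ph2)
  froc <- frocGrid(cohort, RSTParams(), t3dValues = c(0.5, 1.5, 2.5),
                   t2dValues = c(0, 0.5, 1.5))
  set.seed(9)
  for (pick in sample(nrow(froc), 3)) {
    t3 <- froc$t3d[pick]; t2 <- froc$t2d[pick]
    tp <- fp <- fn <- nc <- 0
    for (ph in cohort) {
      res <- detectMicrobleeds(phantomVolume(ph), phantomMask(ph),
                               DetectionParams(t3, t2))
      passed <- res$candidates[res$candidates$status == "passed_2d", ]
      m <- matchCandidates(passed, phantomTruth(ph), 5)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      nc <- nc + nrow(passed)
    }
    expect_equal(froc$tp[pick], tp)
    expect_equal(froc$fp[pick], fp)
    expect_equal(froc$fn[pick], fn)
    expect_equal(froc$mean_candidates[pick], nc / 2)
  }
})

test_that("the Pareto frontier equals all-pairs dominance filtering", {
  one <- data.frame(t3d = 1, t2d = 1, sensitivity = 0.5,
                    mean_candidates = 10, tp = 1, fp = 9, fn = 1)
  expect_equal(paretoFrontier(one), one, ignore_attr = TRUE)

  two <- rbind(one, within(one, { sensitivity <- 0.7; mean_candidates <- 8
                                  t3d <- 2 }))
  expect_equal(nrow(paretoFrontier(two)), 1L)
  expect_equal(paretoFrontier(two)$sensitivity, 0.7)

  set.seed(13)
  for (rep in 1:5) {
    pts <- data.frame(t3d = rep(seq(0.5, 3, 0.5), each = 7),
                      t2d = rep(seq(0, 3, 0.5), 6),
                      sensitivity = round(runif(42), 2),
                      mean_candidates = round(runif(42, 0, 100)),
                      tp = 0, fp = 0, fn = 0)
    expect_equal(paretoFrontier(pts)[, c("t3d", "t2d", "sensitivity",
                                         "mean_candidates")],
                 dominanceOracle(pts)[, c("t3d", "t2d", "sensitivity",
                                          "mean_candidates")],
                 ignore_attr = TRUE)
  }
})

test_that("tiered screening degenerates correctly and screens out empty runs", {
  cohort <- list(smallPhantom(seed = 2), smallPhantom(seed = 3))
  prep <- cohortScores(cohort, RSTParams(), c(0.5, 1.5))
  flat <- cmbrst:::frocFromScores(prep, 1.5, 0.5, 5, "all")
  same <- tieredScreen(cohort, RSTParams(), settingA = c(1.5, 0.5),
                       settingC = c(1.5, 0.5), prep = prep)
  expect_equal(same$sensitivity, flat$sensitivity)
  expect_equal(unname(same$totals["tp"]), flat$tp)

  # a screening threshold above the map maximum: nobody is re-run, every
  # lesion becomes a false negative
  prep2 <- cohortScores(cohort, RSTParams(), c(0.5, 99))
  none <- tieredScreen(cohort, RSTParams(), settingA = c(99, 3),
                       settingC = c(0.5, 0), prep = prep2)
  expect_true(all(none$perParticipant$setting_used == "A"))
  expect_equal(unname(none$totals["tp"]), 0L)
  expect_equal(unname(none$totals["fn"]),
               sum(vapply(cohort, function(p) nrow(phantomTruth(p)),
                          integer(1))))

  expect_error(tieredScreen(cohort, RSTParams(), settingA = c(0.5, 0),
                            settingC = c(1.5, 0.5)),
               class = "cmbrst_tiering")
})
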