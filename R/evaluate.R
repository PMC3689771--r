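# Ground-truth matching, FROC over the (T3D, T2D) lattice, Pareto frontier,
# and the tiered A -> C screening workflow.

t3dKey <- function(x) sprintf("%.6g", x)

truthInScope <- function(truth, scope) {
  scope <- match.arg(scope, c("all", "definite_only"))
  if (scope == "definite_only") truth[truth$label == "definite", , drop = FALSE]
  else truth
}

#' Match candidates to ground-truth lesions
#'
#' One-to-one greedy matching in ascending Euclidean world-mm distance: a
#' candidate/lesion pair is admissible iff their distance is at most
#' `tolMM`; each candidate and each lesion is used at most once. Unmatched
#' candidates are false positives, unmatched lesions false negatives. The
#' result is invariant to the input row order.
#'
#' @param candidates candidate data.frame (normally the passed set) with
#'   x_mm, y_mm, z_mm and id columns.
#' @param truth ground-truth data.frame (id, x_mm, y_mm, z_mm, label).
#' @param tolMM matching tolerance in mm (> 0); default 5.
#' @param scope "all" counts definite + possible lesions, "definite_only"
#'   restricts to definite.
#' @return List with tp, fp, fn counts, `pairs` data.frame (candidate_id,
#'   truth_id, dist_mm) and `sensitivity` = tp / (tp + fn) (NaN when there
#'   are no in-scope lesions).
#' @export
matchCandidates <- function(candidates, truth, tolMM = 5, scope = "all") {
  if (tolMM <= 0)
    cmbStop("cmbrst_bad_params", "tolMM must be > 0")
  truth <- truthInScope(truth, scope)
  nc <- nrow(candidates); nt <- nrow(truth)
  pairs <- data.frame(candidate_id = character(0), truth_id = character(0),
                      dist_mm = numeric(0), stringsAsFactors = FALSE)
  if (nc > 0 && nt > 0) {
    cm <- as.matrix(candidates[, c("x_mm", "y_mm", "z_mm")])
    tm <- as.matrix(truth[, c("x_mm", "y_mm", "z_mm")])
    dmat <- sqrt(pmax(outer(rowSums(cm^2), rowSums(tm^2), `+`) -
                        2 * cm %*% t(tm), 0))
    adm <- which(dmat <= tolMM, arr.ind = TRUE)
    if (nrow(adm) > 0) {
      dd <- dmat[adm]
      o <- order(dd, truth$id[adm[, 2L]], candidates$id[adm[, 1L]])
      usedC <- logical(nc); usedT <- logical(nt)
      keep <- integer(0)
      for (r in o) {
        ic <- adm[r, 1L]; it <- adm[r, 2L]
        if (!usedC[ic] && !usedT[it]) {
          usedC[ic] <- TRUE; usedT[it] <- TRUE
          keep <- c(keep, r)
        }
      }
      pairs <- data.frame(candidate_id = candidates$id[adm[keep, 1L]],
                          truth_id = truth$id[adm[keep, 2L]],
                          dist_mm = dd[keep], stringsAsFactors = FALSE)
    }
  }
  tp <- nrow(pairs)
  list(tp = tp, fp = nc - tp, fn = nt - tp, pairs = pairs,
       sensitivity = if (nt > 0) tp / nt else NaN)
}

# Per-participant score cache: the 3D map is computed once; candidates are
# re-clustered exactly per t3d (components can split as t3d rises, so peak
# sets are not nested); 2D scores are memoized per peak voxel so each
# location is scored once across the whole threshold lattice.
scoreParticipant <- function(volume, mask, rstParams, t3dValues,
                             normSpec = NormalizationSpec(),
                             minipSpec = MinIPSpec(), connectivity = 26) {
  norm <- rangeNormalize(volume, mask, normSpec)
  map <- rstTransform(norm, rstParams)
  s2dCache <- new.env(parent = emptyenv())
  perT3d <- lapply(sort(unique(t3dValues)), function(t3) {
    cand <- thresholdAndCluster(map, mask,
                                DetectionParams(t3, 0, connectivity),
                                volume = volume)
    if (nrow(cand) > 0) {
      cand$s2d <- vapply(seq_len(nrow(cand)), function(r) {
        key <- paste(cand$i[r], cand$j[r], cand$k[r])
        hit <- s2dCache[[key]]
        if (!is.null(hit)) return(hit)
        v <- tryCatch({
          patch <- extractMinipPatch(norm, cand[r, ], minipSpec)
          m2 <- rstTransform(patch, rstParams)
          rstValueAt(m2, patchCenterIndex(norm, patch, cand[r, ]),
                     minipSpec@haloVoxels)
        }, error = function(e) NA_real_)
        s2dCache[[key]] <- v
        v
      }, numeric(1))
    }
    cand
  })
  names(perT3d) <- t3dKey(sort(unique(t3dValues)))
  perT3d
}

passedAt <- function(candT3d, t2d) {
  if (nrow(candT3d) == 0L) return(candT3d)
  if (t2d == 0) {
    candT3d$status <- "passed_2d"
    return(candT3d)
  }
  keep <- !is.na(candT3d$s2d) & candT3d$s2d > t2d
  out <- candT3d[keep, , drop = FALSE]
  if (nrow(out)) out$status <- "passed_2d"
  out
}

#' Passed candidates of one participant at an operating point
#'
#' Reads a participant's stage-1 candidates at `t3d` from a [cohortScores()]
#' cache and applies the stage-2 threshold `t2d` (0 passes everything).
#'
#' @param prep result of [cohortScores()].
#' @param participant participant index into the cohort.
#' @param t3d a stage-1 threshold present in the cache.
#' @param t2d stage-2 threshold.
#' @return Candidate data.frame of the passed set.
#' @export
candidatesAtSetting <- function(prep, participant, t3d, t2d) {
  tab <- prep$scores[[participant]][[t3dKey(t3d)]]
  if (is.null(tab))
    cmbStop("cmbrst_bad_params", "t3d %.3g was not scored in this cache", t3d)
  passedAt(tab, t2d)
}

asCohortList <- function(cohort) {
  lapply(cohort, function(p) {
    if (is(p, "PhantomOutput"))
      list(volume = p@volume, mask = p@mask, truth = p@truth)
    else p
  })
}

#' Score a cohort once for lattice evaluation
#'
#' Runs the expensive stages (normalization, 3D transform, per-threshold
#' clustering, memoized 2D scoring) once per participant so that any
#' (t3d, t2d) operating point can then be evaluated by pure thresholding,
#' identically to a from-scratch run.
#'
#' @param cohort list of [PhantomOutput-class] objects or of
#'   `list(volume, mask, truth)` triples.
#' @param rstParams an [RSTParams-class].
#' @param t3dValues stage-1 thresholds to pre-cluster at.
#' @param normSpec,minipSpec,connectivity pipeline settings.
#' @return List with `scores` (per participant, per t3d candidate tables
#'   with 2D scores) and `truths`.
#' @export
cohortScores <- function(cohort, rstParams = RSTParams(),
                         t3dValues = seq(0.5, 3, by = 0.5),
                         normSpec = NormalizationSpec(),
                         minipSpec = MinIPSpec(), connectivity = 26) {
  cohort <- asCohortList(cohort)
  if (length(cohort) < 1L)
    cmbStop("cmbrst_bad_params", "cohort must be nonempty")
  scores <- vector("list", length(cohort))
  for (p in seq_along(cohort)) {
    scores[[p]] <- tryCatch(
      scoreParticipant(cohort[[p]]$volume, cohort[[p]]$mask, rstParams,
                       t3dValues, normSpec, minipSpec, connectivity),
      error = function(e)
        cmbStop("cmbrst_pipeline", "participant %d: %s", p,
                conditionMessage(e)))
  }
  list(scores = scores, truths = lapply(cohort, `[[`, "truth"))
}

#' Evaluate FROC points from precomputed cohort scores
#'
#' Turns a [cohortScores()] cache into FROC operating points for arbitrary
#' sub-lattices of the scored thresholds, without re-running the transform.
#'
#' @param prep result of [cohortScores()].
#' @param t3dValues,t2dValues thresholds to evaluate; every `t3dValues` entry
#'   must have been scored in `prep`.
#' @param tolMM matching tolerance in mm.
#' @param scope "all" or "definite_only".
#' @return data.frame as in [frocGrid()].
#' @export
frocFromScores <- function(prep, t3dValues, t2dValues, tolMM = 5,
                           scope = "all") {
  rows <- vector("list", length(t3dValues) * length(t2dValues))
  n <- length(prep$scores)
  r <- 0L
  for (t3 in t3dValues) {
    key <- t3dKey(t3)
    for (t2 in t2dValues) {
      tp <- fp <- fn <- ncand <- 0L
      for (p in seq_len(n)) {
        passed <- passedAt(prep$scores[[p]][[key]], t2)
        m <- matchCandidates(passed, prep$truths[[p]], tolMM, scope)
        tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
        ncand <- ncand + nrow(passed)
      }
      r <- r + 1L
      rows[[r]] <- data.frame(
        t3d = t3, t2d = t2,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
        mean_candidates = ncand / n, tp = tp, fp = fp, fn = fn)
    }
  }
  do.call(rbind, rows)
}

#' Exhaustive FROC grid over the two-threshold lattice
#'
#' Evaluates every (t3d, t2d) combination on a cohort and returns one
#' operating point per combination: cohort sensitivity, mean candidates per
#' participant, and TP/FP/FN totals. The default lattice (t3d 0.5-3.0,
#' t2d 0.0-3.0, step 0.5) has 42 points. Cached per-volume scores make the
#' lattice sweep identical to, but much cheaper than, per-point
#' recomputation.
#'
#' @inheritParams cohortScores
#' @param t3dValues,t2dValues threshold grids.
#' @param tolMM matching tolerance in mm.
#' @param scope "all" or "definite_only" lesion scope.
#' @return data.frame(t3d, t2d, sensitivity, mean_candidates, tp, fp, fn),
#'   ordered t3d-major.
#' @export
frocGrid <- function(cohort, rstParams = RSTParams(),
                     t3dValues = seq(0.5, 3, by = 0.5),
                     t2dValues = seq(0, 3, by = 0.5), tolMM = 5,
                     scope = "all", normSpec = NormalizationSpec(),
                     minipSpec = MinIPSpec(), connectivity = 26) {
  if (length(t3dValues) < 1L || length(t2dValues) < 1L)
    cmbStop("cmbrst_bad_params", "threshold lists must be nonempty")
  prep <- cohortScores(cohort, rstParams, t3dValues, normSpec, minipSpec,
                       connectivity)
  frocFromScores(prep, t3dValues, t2dValues, tolMM, scope)
}

#' Pareto frontier of FROC operating points
#'
#' Returns the points not dominated by any other point, where a dominator
#' has sensitivity at least as high and mean candidate burden at most as
#' high, with at least one strict inequality. Exact ties on both axes keep
#' the point with the lexicographically larger (t3d, t2d). Output is sorted
#' by ascending mean candidates.
#'
#' @param points FROC data.frame from [frocGrid()].
#' @return The non-dominated subset, sorted by ascending mean candidates.
#' @export
paretoFrontier <- function(points) {
  if (nrow(points) < 1L)
    cmbStop("cmbrst_bad_params", "points must be nonempty")
  keyed <- points[order(points$sensitivity, points$mean_candidates,
                        -points$t3d, -points$t2d), , drop = FALSE]
  dup <- duplicated(keyed[, c("sensitivity", "mean_candidates")])
  pts <- keyed[!dup, , drop = FALSE]
  n <- nrow(pts)
  dominated <- vapply(seq_len(n), function(a) {
    any(pts$sensitivity >= pts$sensitivity[a] &
          pts$mean_candidates <= pts$mean_candidates[a] &
          (pts$sensitivity > pts$sensitivity[a] |
             pts$mean_candidates < pts$mean_candidates[a]))
  }, logical(1))
  out <- pts[!dominated, , drop = FALSE]
  out[order(out$mean_candidates, out$sensitivity), , drop = FALSE]
}

#' Tiered two-setting screening of a cohort
#'
#' Runs the strict setting A on every participant; participants with at
#' least one passed candidate are re-evaluated at the permissive setting C
#' and contribute C's candidates, the rest contribute none (their lesions
#' count as false negatives). This discards lesion-free participants
#' quickly while retaining most of C's sensitivity.
#'
#' @inheritParams cohortScores
#' @param settingA,settingC numeric c(t3d, t2d); A must be at least as
#'   strict (componentwise >=) as C.
#' @param tolMM matching tolerance in mm.
#' @param scope lesion scope for sensitivity.
#' @param prep optional precomputed [cohortScores()] result (its t3dValues
#'   must include both settings' t3d).
#' @return List with `perParticipant` data.frame (participant, setting_used,
#'   n_candidates, tp, fp, fn), `sensitivity`, and totals, plus the flat
#'   sensitivities at A and C for reference.
#' @export
tieredScreen <- function(cohort, rstParams = RSTParams(), settingA, settingC,
                         tolMM = 5, scope = "all",
                         normSpec = NormalizationSpec(),
                         minipSpec = MinIPSpec(), connectivity = 26,
                         prep = NULL) {
  if (!(settingA[1] >= settingC[1] && settingA[2] >= settingC[2]))
    cmbStop("cmbrst_tiering",
            "setting A must be at least as strict as setting C on both thresholds")
  if (is.null(prep))
    prep <- cohortScores(cohort, rstParams,
                         unique(c(settingA[1], settingC[1])),
                         normSpec, minipSpec, connectivity)
  n <- length(prep$scores)
  kA <- t3dKey(settingA[1]); kC <- t3dKey(settingC[1])
  rows <- vector("list", n)
  tpT <- fpT <- fnT <- 0L
  for (p in seq_len(n)) {
    pa <- passedAt(prep$scores[[p]][[kA]], settingA[2])
    if (nrow(pa) >= 1L) {
      used <- "C"
      cand <- passedAt(prep$scores[[p]][[kC]], settingC[2])
    } else {
      used <- "A"
      cand <- pa
    }
    m <- matchCandidates(cand, prep$truths[[p]], tolMM, scope)
    tpT <- tpT + m$tp; fpT <- fpT + m$fp; fnT <- fnT + m$fn
    rows[[p]] <- data.frame(participant = p, setting_used = used,
                            n_candidates = nrow(cand), tp = m$tp,
                            fp = m$fp, fn = m$fn,
                            stringsAsFactors = FALSE)
  }
  flat <- function(setting) {
    tp <- fn <- 0L
    for (p in seq_len(n)) {
      m <- matchCandidates(passedAt(prep$scores[[p]][[t3dKey(setting[1])]],
                                    setting[2]),
                           prep$truths[[p]], tolMM, scope)
      tp <- tp + m$tp; fn <- fn + m$fn
    }
    if (tp + fn > 0) tp / (tp + fn) else NaN
  }
  list(perParticipant = do.call(rbind, rows),
       sensitivity = if (tpT + fnT > 0) tpT / (tpT + fnT) else NaN,
       totals = c(tp = tpT, fp = fpT, fn = fnT),
       flatA = flat(settingA), flatC = flat(settingC))
}
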