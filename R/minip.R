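# Stage 2: per-candidate transversal minimum-intensity-projection patch,
# re-scored with the 2D radial symmetry transform. On a minIP, a microbleed
# stays a dark round spot while a through-plane vessel elongates, so the 2D
# score separates them.

#' Extract a transversal minIP patch around a candidate
#'
#' Selects the axial slices whose centers lie within half the slab thickness
#' of the candidate's z (clipped at the volume boundary; always at least the
#' candidate's own slice) and takes the voxel-wise minimum over them inside
#' the square in-plane window of half-width `roiHalfwidthMM` centered on the
#' candidate (also clipped). The returned 2D [VoxelVolume-class] inherits
#' the in-plane spacing and a world-consistent 2D affine.
#'
#' @param volume source 3D [VoxelVolume-class] (normalized intensities).
#' @param candidate one-row candidate data.frame (or list) with 0-based
#'   voxel index fields i, j, k.
#' @param spec a [MinIPSpec-class].
#' @return A 2D [VoxelVolume-class] minIP patch.
#' @export
extractMinipPatch <- function(volume, candidate, spec = MinIPSpec()) {
  a <- voxelData(volume)
  d <- dim(a)
  idx <- as.integer(round(c(candidate$i, candidate$j, candidate$k)))
  if (length(idx) != 3L || any(idx < 0L) || any(idx > d - 1L))
    cmbStop("cmbrst_out_of_grid", "candidate outside the volume grid")
  aff <- voxelAffine(volume)
  zs <- aff[3L, 3L] * (seq_len(d[3L]) - 1L) + aff[3L, 4L]
  zc <- zs[idx[3L] + 1L]
  ks <- which(abs(zs - zc) <= spec@slabThicknessMM / 2 + 1e-9)
  if (!length(ks)) ks <- idx[3L] + 1L
  sp <- voxelSpacing(volume)
  di <- as.integer(floor(spec@roiHalfwidthMM / sp[1L] + 1e-9))
  dj <- as.integer(floor(spec@roiHalfwidthMM / sp[2L] + 1e-9))
  ir <- max(1L, idx[1L] + 1L - di):min(d[1L], idx[1L] + 1L + di)
  jr <- max(1L, idx[2L] + 1L - dj):min(d[2L], idx[2L] + 1L + dj)
  patch <- a[ir, jr, ks[1L]]
  for (k in ks[-1L]) patch <- pmin(patch, a[ir, jr, k])
  patch <- matrix(patch, length(ir), length(jr))
  origin0 <- c(ir[1L], jr[1L], idx[3L] + 1L) - 1L
  ow <- drop(aff %*% c(origin0, 1))[1:2]
  aff2 <- rbind(cbind(aff[1:2, 1:2], ow), c(0, 0, 1))
  VoxelVolume(patch, sp[1:2], aff2)
}

patchCenterIndex <- function(volume, patch, candidate) {
  w <- drop(voxelAffine(volume) %*%
              c(candidate$i, candidate$j, candidate$k, 1))[1:2]
  as.integer(round(worldToVoxel(patch, w)))
}

#' Score candidates on minIP patches and apply the 2D threshold
#'
#' When `t2d` is 0 the 2D stage is skipped entirely: every candidate passes
#' with its 2D score unset. Otherwise each candidate's minIP patch is scored
#' by the 2D radial symmetry transform with the same radii, strictness,
#' smoothing and polarity as the 3D stage; the candidate's 2D score is the
#' map maximum within `haloVoxels` of the patch center, and the candidate is
#' marked `passed_2d` if the score strictly exceeds `t2d`, else
#' `rejected_2d`. A per-candidate scoring failure (e.g. a degenerate patch)
#' rejects that candidate with a warning, never aborts the batch.
#'
#' @param volume normalized 3D [VoxelVolume-class].
#' @param candidates candidate data.frame from [thresholdAndCluster()].
#' @param rstParams the [RSTParams-class] shared by both stages.
#' @param spec a [MinIPSpec-class]; `roiHalfwidthMM` must be at least the
#'   largest radius.
#' @param t2d stage-2 threshold (>= 0; 0 disables the stage).
#' @return The candidate table with s2d and status filled in; callers filter
#'   on `status == "passed_2d"`.
#' @export
filterCandidates <- function(volume, candidates, rstParams = RSTParams(),
                             spec = MinIPSpec(), t2d = 0) {
  if (t2d < 0)
    cmbStop("cmbrst_bad_params", "t2d must be >= 0")
  if (spec@roiHalfwidthMM < max(rstParams@radiiMM))
    cmbStop("cmbrst_bad_params",
            "roiHalfwidthMM must be at least the largest RST radius")
  if (nrow(candidates) == 0L) return(candidates)
  if (t2d == 0) {
    candidates$status <- "passed_2d"
    candidates$s2d <- NA_real_
    return(candidates)
  }
  for (r in seq_len(nrow(candidates))) {
    res <- tryCatch({
      patch <- extractMinipPatch(volume, candidates[r, ], spec)
      map2 <- rstTransform(patch, rstParams)
      ctr <- patchCenterIndex(volume, patch, candidates[r, ])
      rstValueAt(map2, ctr, spec@haloVoxels)
    }, error = function(e) {
      warning(sprintf("candidate %s rejected: 2D scoring failed (%s)",
                      candidates$id[r], conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    candidates$s2d[r] <- res
    candidates$status[r] <-
      if (!is.na(res) && res > t2d) "passed_2d" else "rejected_2d"
  }
  candidates
}

#' One-volume detection pipeline
#'
#' Runs normalization, the 3D radial symmetry transform, stage-1
#' threshold-and-cluster and the stage-2 minIP filter on a single volume.
#'
#' @param volume raw intensity [VoxelVolume-class].
#' @param mask brain mask on the same grid (nonzero = inside).
#' @param detection a [DetectionParams-class] carrying t3d/t2d/connectivity.
#' @param rstParams an [RSTParams-class].
#' @param normSpec a [NormalizationSpec-class].
#' @param minipSpec a [MinIPSpec-class].
#' @return List with elements `candidates` (all candidates with statuses),
#'   `map` (the 3D [SymmetryMap-class]) and `normalized` (the normalized
#'   volume).
#' @export
detectMicrobleeds <- function(volume, mask, detection,
                              rstParams = RSTParams(),
                              normSpec = NormalizationSpec(),
                              minipSpec = MinIPSpec()) {
  validObject(detection)
  norm <- rangeNormalize(volume, mask, normSpec)
  map <- rstTransform(norm, rstParams)
  cand <- thresholdAndCluster(map, mask, detection, volume = volume)
  cand <- filterCandidates(norm, cand, rstParams, minipSpec, detection@t2d)
  list(candidates = cand, map = map, normalized = norm)
}
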