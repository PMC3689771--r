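# Stage 1: threshold the 3D symmetry map inside the mask and reduce each
# suprathreshold connected component to one candidate at its peak voxel.

connOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  g <- g[keep, , drop = FALSE]
  # half set: first nonzero component positive (each undirected pair once)
  first <- ifelse(g[, 1] != 0, g[, 1], ifelse(g[, 2] != 0, g[, 2], g[, 3]))
  g[first > 0, , drop = FALSE]
}

#' Threshold a symmetry map and cluster into candidates
#'
#' Binarizes `map > t3d` within the mask, partitions the suprathreshold
#' voxels into connected components (6/18/26 connectivity), and emits one
#' candidate per component at its maximum-value voxel (ties broken by the
#' lexicographically smallest 0-based (i, j, k)). Candidates are sorted by
#' descending 3D symmetry value.
#'
#' @param map a 3D [SymmetryMap-class].
#' @param mask mask [VoxelVolume-class] on the same grid (nonzero = inside).
#' @param params a [DetectionParams-class] (uses `t3d` and `connectivity`).
#' @param volume optional source volume supplying the affine for world
#'   coordinates; defaults to the mask.
#' @return Candidate data.frame with columns id, i, j, k, x_mm, y_mm, z_mm,
#'   s3d, s2d (NA), status ("pending").
#' @export
thresholdAndCluster <- function(map, mask, params, volume = mask) {
  d <- dim(map@values)
  if (!identical(d, dim(voxelData(mask))))
    cmbStop("cmbrst_grid_mismatch", "map and mask grids differ")
  validObject(params)
  sel <- which(map@values > params@t3d & voxelData(mask) != 0)
  if (length(sel) == 0L) return(emptyCandidates())
  ci <- arrayInd(sel, d)
  memb <- labelComponents(ci, sel, d, params@connectivity)
  vals <- map@values[sel]
  peaks <- vapply(split(seq_along(sel), memb), function(ix) {
    m <- max(vals[ix])
    tied <- ix[vals[ix] == m]
    if (length(tied) > 1L) {
      o <- order(ci[tied, 1L], ci[tied, 2L], ci[tied, 3L])
      tied <- tied[o[1L]]
    }
    tied[1L]
  }, integer(1))
  idx0 <- ci[peaks, , drop = FALSE] - 1L
  s3d <- vals[peaks]
  ord <- order(-s3d, idx0[, 1L], idx0[, 2L], idx0[, 3L])
  idx0 <- idx0[ord, , drop = FALSE]
  s3d <- s3d[ord]
  w <- voxelToWorld(volume, idx0)
  data.frame(id = sprintf("c%04d", seq_along(s3d)),
             i = idx0[, 1L], j = idx0[, 2L], k = idx0[, 3L],
             x_mm = w[, 1L], y_mm = w[, 2L], z_mm = w[, 3L],
             s3d = s3d, s2d = NA_real_, status = "pending",
             stringsAsFactors = FALSE)
}

# Connected components of a sparse voxel set via igraph.
labelComponents <- function(ci, lin, d, connectivity) {
  offs <- connOffsets(connectivity)
  n1 <- d[1L]; n12 <- d[1L] * d[2L]
  key <- lin
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ni <- ci[, 1L] + offs[r, 1L]
    nj <- ci[, 2L] + offs[r, 2L]
    nk <- ci[, 3L] + offs[r, 3L]
    ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] &
      nk >= 1L & nk <= d[3L]
    nlin <- ni[ok] + (nj[ok] - 1L) * n1 + (nk[ok] - 1L) * n12
    hit <- match(nlin, key)
    found <- !is.na(hit)
    if (any(found))
      edges[[r]] <- cbind(which(ok)[found], hit[found])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0)
    g <- igraph::add_edges(g, t(em))
  igraph::components(g)$membership
}
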