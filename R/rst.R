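# The radial symmetry transform: gradient voting in physical units on
# anisotropic 2D/3D grids, per-radius orientation/magnitude projection,
# radial-strictness response, per-radius Gaussian smoothing, mean over radii.

#' Physical-unit image gradient
#'
#' Central differences at interior voxels and one-sided differences at the
#' boundary, each divided by the per-axis spacing so components are in
#' intensity per mm.
#'
#' @param volume a [VoxelVolume-class] with every extent >= 3.
#' @return List with one gradient-component array per axis.
#' @export
imageGradient <- function(volume) {
  a <- voxelData(volume)
  d <- dim(a)
  if (any(d < 3L))
    cmbStop("cmbrst_small_grid",
            "gradient requires every grid extent >= 3 (got %s)",
            paste(d, collapse = " x "))
  sp <- voxelSpacing(volume)
  lapply(seq_along(d), function(ax) diffAxis(a, ax, sp[ax]))
}

diffAxis <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, seq_along(d)[-axis])
  m <- matrix(aperm(a, perm), nrow = n)
  g <- matrix(0, n, ncol(m))
  g[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] -
                        m[1:(n - 2L), , drop = FALSE]) / (2 * h)
  g[1L, ] <- (m[2L, ] - m[1L, ]) / h
  g[n, ] <- (m[n, ] - m[n - 1L, ]) / h
  aperm(array(g, d[perm]), order(perm))
}

# Saturation count for radius n on a given grid: the number of voxel offsets
# a perfect digital sphere (circle in 2D) shell of radius n mm would vote
# into the center, i.e. offsets v with round(n * unitdir(v) / spacing) == v.
# Cached per (radius, spacing).
.shellCache <- new.env(parent = emptyenv())

shellVoteCount <- function(radiusMM, spacing) {
  key <- paste(c(format(radiusMM, digits = 12),
                 format(spacing, digits = 12)), collapse = "|")
  hit <- .shellCache[[key]]
  if (!is.null(hit)) return(hit)
  nd <- length(spacing)
  rng <- lapply(seq_len(nd), function(ax) {
    r <- as.integer(ceiling(radiusMM / spacing[ax])) + 1L
    (-r):r
  })
  v <- as.matrix(do.call(expand.grid, rng))
  v <- v[rowSums(v != 0) > 0, , drop = FALSE]
  u <- sweep(v, 2L, spacing, `*`)
  nu <- sqrt(rowSums(u^2))
  w <- round(sweep(u / nu, 2L, spacing, `/`) * radiusMM)
  k <- sum(rowSums(w == v) == nd)
  k <- max(k, 1L)
  .shellCache[[key]] <- k
  k
}

#' Radial symmetry transform (2D or 3D)
#'
#' For each radius n (mm), every voxel whose gradient magnitude exceeds
#' `gradThresholdFrac` times the image maximum casts a vote at the voxel
#' displaced by `round(n * ghat / spacing)` per axis along (bright polarity)
#' or against (dark polarity) its unit gradient ghat; on the rim of a dark
#' blob gradients point outward, so the negative offset lands at the blob
#' center. Votes accumulate an orientation-count image O_n and a
#' gradient-magnitude image M_n (out-of-grid votes are discarded); O_n is
#' clamped at the saturation count k_n that a perfect digital sphere shell
#' of radius n would produce on this grid. The per-radius response
#' `F_n = (M_n / k_n) * (min(|O_n|, k_n) / k_n)^alpha` is smoothed by a
#' Gaussian of scale `smoothSigmaFactor * n` mm (converted per axis to
#' voxels, zero-padded), and the map is the mean of the smoothed responses.
#'
#' Dimensionality (2D vs 3D) follows the input grid.
#'
#' @param volume input [VoxelVolume-class] (normalized input recommended;
#'   detection thresholds are calibrated on [0, 255] intensities).
#' @param params an [RSTParams-class].
#' @return A [SymmetryMap-class] on the same grid.
#' @examples
#' ph <- generatePhantom(PhantomSpec(extents = c(32, 32, 12),
#'   spheres = data.frame(x = 16, y = 16, z = 18, diameter = 5, depth = 0.8),
#'   noiseSigma = 0))
#' m <- rstTransform(phantomVolume(ph), RSTParams(radiiMM = c(1, 2)))
#' which(mapValues(m) == max(mapValues(m)), arr.ind = TRUE) - 1  # near (16,16,6)
#' @export
rstTransform <- function(volume, params = RSTParams()) {
  validObject(params)
  a <- voxelData(volume)
  d <- dim(a)
  nd <- length(d)
  if (any(d < 3L))
    cmbStop("cmbrst_small_grid",
            "radial symmetry transform requires every extent >= 3")
  sp <- voxelSpacing(volume)
  grads <- imageGradient(volume)
  gm2 <- grads[[1]]^2
  for (ax in seq_len(nd)[-1]) gm2 <- gm2 + grads[[ax]]^2
  gm <- sqrt(gm2)
  mx <- max(gm)
  nvox <- prod(d)
  S <- array(0, d)
  for (n in params@radiiMM) {
    k <- shellVoteCount(n, sp)
    O <- numeric(nvox)
    M <- numeric(nvox)
    if (mx > 0) {
      voters <- which(gm > params@gradThresholdFrac * mx)
      if (length(voters)) {
        ci <- arrayInd(voters, d)
        mag <- gm[voters]
        off <- matrix(0L, length(voters), nd)
        for (ax in seq_len(nd))
          off[, ax] <- as.integer(round(n * (grads[[ax]][voters] / mag) / sp[ax]))
        voteInto <- function(tgt, sign) {
          ok <- rep(TRUE, nrow(tgt))
          for (ax in seq_len(nd))
            ok <- ok & tgt[, ax] >= 1L & tgt[, ax] <= d[ax]
          if (!any(ok)) return(invisible())
          t1 <- tgt[ok, , drop = FALSE]
          lin <- t1[, 1L]
          mult <- 1L
          for (ax in seq_len(nd)[-1]) {
            mult <- mult * d[ax - 1L]
            lin <- lin + (t1[, ax] - 1L) * mult
          }
          cnt <- tabulate(lin, nbins = nvox)
          O <<- O + sign * cnt
          acc <- rowsum(mag[ok], lin)
          at <- as.integer(rownames(acc))
          M[at] <<- M[at] + acc[, 1L]
          invisible()
        }
        if (params@polarity %in% c("dark", "both"))
          voteInto(ci - off, if (params@polarity == "both") -1 else 1)
        if (params@polarity %in% c("bright", "both"))
          voteInto(ci + off, 1)
      }
    }
    absO <- pmin(abs(O), k)
    Fn <- array((M / k) * (absO / k)^params@alpha, d)
    S <- S + gaussianSmooth(Fn, params@smoothSigmaFactor * n, sp)
  }
  S <- S / length(params@radiiMM)
  new("SymmetryMap", values = S, spacing = sp, params = params)
}

#' Read a symmetry value at (or near) a voxel
#'
#' Maximum map value over the axis-aligned neighborhood of half-width
#' `haloVoxels` around a 0-based index, clipped to the grid. A halo of 0
#' reads the voxel itself; a halo larger than the grid reads the global
#' maximum.
#'
#' @param map a [SymmetryMap-class].
#' @param index 0-based voxel index (length 2 or 3 to match the map).
#' @param haloVoxels neighborhood half-width in voxels (>= 0).
#' @return Scalar symmetry value.
#' @export
rstValueAt <- function(map, index, haloVoxels = 0L) {
  d <- dim(map@values)
  nd <- length(d)
  index <- as.integer(round(index))
  if (length(index) != nd || any(index < 0L) || any(index > d - 1L))
    cmbStop("cmbrst_out_of_grid", "index outside the map grid")
  if (haloVoxels < 0L)
    cmbStop("cmbrst_bad_params", "haloVoxels must be >= 0")
  rngs <- lapply(seq_len(nd), function(ax) {
    lo <- max(0L, index[ax] - as.integer(haloVoxels))
    hi <- min(d[ax] - 1L, index[ax] + as.integer(haloVoxels))
    (lo:hi) + 1L
  })
  max(do.call(`[`, c(list(map@values), rngs)))
}
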