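# Internal helpers: structured errors, axis-wise array ops, seeded RNG.

cmbStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "cmbrst_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Separable 1D convolution along `axis` with zero padding outside the grid.
# Kernel must have odd length; its center aligns with the output voxel.
convolveAxis <- function(a, kernel, axis) {
  L <- length(kernel)
  if (L == 1L) return(a * kernel)
  r <- (L - 1L) %/% 2L
  d <- dim(a)
  nd <- length(d)
  perm <- c(axis, seq_len(nd)[-axis])
  m <- matrix(aperm(a, perm), nrow = d[axis])
  n <- d[axis]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_len(L)) {
    off <- t - r - 1L
    lo <- max(1L, 1L - off)
    hi <- min(n, n - off)
    if (lo > hi) next
    idx <- lo:hi
    out[idx, ] <- out[idx, ] + kernel[t] * m[idx + off, , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

gaussKernel1D <- function(sigmaVox) {
  if (sigmaVox < 1e-8) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigmaVox)))
  t <- (-r):r
  w <- exp(-t^2 / (2 * sigmaVox^2))
  w / sum(w)
}

# N-D Gaussian smoothing with a physical (mm) sigma, converted per axis to
# voxel units; zero padding at the boundary.
gaussianSmooth <- function(a, sigmaMM, spacing) {
  for (ax in seq_along(spacing)) {
    k <- gaussKernel1D(sigmaMM / spacing[ax])
    a <- convolveAxis(a, k, ax)
  }
  a
}

# Restore the caller's RNG state after seeded work.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Weak rolling checksum for config provenance in logs/outputs.
configChecksum <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  b <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% 2147483647
  sprintf("%010d", as.integer(h))
}

sameGrid <- function(a, b) {
  identical(dim(voxelData(a)), dim(voxelData(b))) &&
    all(abs(voxelSpacing(a) - voxelSpacing(b)) <= 1e-9 * voxelSpacing(a))
}
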