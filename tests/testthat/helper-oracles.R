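# Independent, literal loop-based oracles. These deliberately re-derive the
# pipeline's definitions with per-voxel loops and direct enumeration, never
# calling the package's vectorized code paths.

# --- gradient: per-voxel central/one-sided differences -----------------------
gradientOracle <- function(a, sp) {
  d <- dim(a)
  g <- list(array(0, d), array(0, d), array(0, d))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- c(i, j, k)
    for (ax in 1:3) {
      n <- d[ax]
      p <- ii; m <- ii
      if (ii[ax] == 1) { p[ax] <- 2; m[ax] <- 1; h <- sp[ax] }
      else if (ii[ax] == n) { p[ax] <- n; m[ax] <- n - 1; h <- sp[ax] }
      else { p[ax] <- ii[ax] + 1; m[ax] <- ii[ax] - 1; h <- 2 * sp[ax] }
      g[[ax]][i, j, k] <- (a[p[1], p[2], p[3]] - a[m[1], m[2], m[3]]) / h
    }
  }
  g
}

# --- saturation count: direct offset enumeration -----------------------------
shellCountOracle <- function(radiusMM, sp) {
  nd <- length(sp)
  r <- ceiling(radiusMM / sp) + 1
  count <- 0
  rec <- function(prefix) {
    ax <- length(prefix) + 1L
    if (ax > nd) {
      v <- prefix
      if (all(v == 0)) return()
      u <- v * sp
      w <- round(radiusMM * (u / sqrt(sum(u^2))) / sp)
      if (all(w == v)) count <<- count + 1
      return()
    }
    for (t in (-r[ax]):r[ax]) rec(c(prefix, t))
  }
  rec(integer(0))
  max(count, 1)
}

# --- per-voxel Gaussian smoothing with zero padding --------------------------
smoothOracle3D <- function(a, sigmaMM, sp) {
  d <- dim(a)
  for (ax in 1:3) {
    sv <- sigmaMM / sp[ax]
    if (sv < 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * sv)))
    w <- exp(-((-r):r)^2 / (2 * sv^2))
    w <- w / sum(w)
    out <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      s <- 0
      for (t in (-r):r) {
        ii <- c(i, j, k)
        ii[ax] <- ii[ax] + t
        if (ii[ax] >= 1 && ii[ax] <= d[ax])
          s <- s + w[t + r + 1] * a[ii[1], ii[2], ii[3]]
      }
      out[i, j, k] <- s
    }
    a <- out
  }
  a
}

# --- the full transform, voxel by voxel --------------------------------------
rstOracle3D <- function(vol, params) {
  a <- cmbrst::voxelData(vol)
  sp <- cmbrst::voxelSpacing(vol)
  d <- dim(a)
  g <- gradientOracle(a, sp)
  gm <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    gm[i, j, k] <- sqrt(g[[1]][i, j, k]^2 + g[[2]][i, j, k]^2 +
                          g[[3]][i, j, k]^2)
  mx <- max(gm)
  S <- array(0, d)
  for (n in params@radiiMM) {
    kSat <- shellCountOracle(n, sp)
    O <- array(0, d); M <- array(0, d)
    if (mx > 0) {
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        mag <- gm[i, j, k]
        if (mag <= params@gradThresholdFrac * mx) next
        ghat <- c(g[[1]][i, j, k], g[[2]][i, j, k], g[[3]][i, j, k]) / mag
        off <- round(n * ghat / sp)
        vote <- function(tgt, sgn) {
          if (all(tgt >= 1) && all(tgt <= d)) {
            O[tgt[1], tgt[2], tgt[3]] <<- O[tgt[1], tgt[2], tgt[3]] + sgn
            M[tgt[1], tgt[2], tgt[3]] <<- M[tgt[1], tgt[2], tgt[3]] + mag
          }
        }
        if (params@polarity %in% c("dark", "both"))
          vote(c(i, j, k) - off, if (params@polarity == "both") -1 else 1)
        if (params@polarity %in% c("bright", "both"))
          vote(c(i, j, k) + off, 1)
      }
    }
    Fn <- (M / kSat) * (pmin(abs(O), kSat) / kSat)^params@alpha
    S <- S + smoothOracle3D(Fn, params@smoothSigmaFactor * n, sp)
  }
  S / length(params@radiiMM)
}

# --- flood-fill component labeling over a boolean 3D array -------------------
floodFillOracle <- function(sel3d, connectivity = 26) {
  d <- dim(sel3d)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(offs)) == 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keep, , drop = FALSE]
  nextLab <- 0L
  for (start in which(sel3d)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- list(arrayInd(start, d)[1, ])
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        if (sel3d[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nextLab
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# --- all-pairs dominance for the Pareto frontier -----------------------------
dominanceOracle <- function(points) {
  n <- nrow(points)
  dup <- logical(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b || dup[a]) next
    if (points$sensitivity[b] == points$sensitivity[a] &&
        points$mean_candidates[b] == points$mean_candidates[a] &&
        (points$t3d[b] > points$t3d[a] ||
           (points$t3d[b] == points$t3d[a] && points$t2d[b] > points$t2d[a])))
      dup[a] <- TRUE
  }
  keep <- !dup
  dominated <- logical(n)
  for (a in seq_len(n)) {
    if (!keep[a]) next
    for (b in seq_len(n)) {
      if (a == b || !keep[b]) next
      if (points$sensitivity[b] >= points$sensitivity[a] &&
          points$mean_candidates[b] <= points$mean_candidates[a] &&
          (points$sensitivity[b] > points$sensitivity[a] ||
             points$mean_candidates[b] < points$mean_candidates[a]))
        dominated[a] <- TRUE
    }
  }
  out <- points[keep & !dominated, , drop = FALSE]
  out[order(out$mean_candidates, out$sensitivity), , drop = FALSE]
}

# --- sorted linear-interpolation percentile ----------------------------------
percentileOracle <- function(vals, p) {
  x <- sort(vals)
  h <- (length(x) - 1) * p / 100
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (if (lo + 2 <= length(x)) x[lo + 2] - x[lo + 1] else 0)
}
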