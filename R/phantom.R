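# Synthetic phantoms: textured noisy background with dark spheres
# (microbleed analogues), dark curvilinear tubes (vessel analogues) and
# dark planes (fissure analogues) on an anisotropic grid, with exact
# ground truth. Lesions darken multiplicatively with a smooth
# (error-function) edge of about one in-plane voxel, and compose by
# minimum where they overlap.

erfEdgeProfile <- function(dist, edgeWidth) {
  stats::pnorm(-(dist) / edgeWidth)
}

worldGrid <- function(extents, spacing) {
  list(x = (seq_len(extents[1L]) - 1L) * spacing[1L],
       y = (seq_len(extents[2L]) - 1L) * spacing[2L],
       z = (seq_len(extents[3L]) - 1L) * spacing[3L])
}

boxRange <- function(centerMM, radiusMM, axisCoords) {
  which(axisCoords >= centerMM - radiusMM & axisCoords <= centerMM + radiusMM)
}

applyProfile <- function(mult, ir, jr, kr, dist, radius, depth, edge) {
  prof <- erfEdgeProfile(dist - radius, edge)
  m <- 1 - depth * prof
  cur <- mult[ir, jr, kr]
  mult[ir, jr, kr] <- pmin(cur, array(m, dim(cur)))
  mult
}

addSphere <- function(mult, g, spacing, center, diameter, depth, edge) {
  R <- diameter / 2
  pad <- R + 4 * edge
  ir <- boxRange(center[1], pad, g$x); jr <- boxRange(center[2], pad, g$y)
  kr <- boxRange(center[3], pad, g$z)
  if (!length(ir) || !length(jr) || !length(kr)) return(mult)
  dx <- g$x[ir] - center[1]; dy <- g$y[jr] - center[2]; dz <- g$z[kr] - center[3]
  dist <- sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
  applyProfile(mult, ir, jr, kr, dist, R, depth, edge)
}

segmentDistance <- function(px, py, pz, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  dx <- px - a[1]; dy <- py - a[2]; dz <- pz - a[3]
  if (L2 < 1e-12) return(sqrt(dx^2 + dy^2 + dz^2))
  t <- pmin(pmax((dx * ab[1] + dy * ab[2] + dz * ab[3]) / L2, 0), 1)
  sqrt((dx - t * ab[1])^2 + (dy - t * ab[2])^2 + (dz - t * ab[3])^2)
}

addTube <- function(mult, g, spacing, points, radius, depth, edge) {
  pad <- radius + 4 * edge
  for (s in seq_len(nrow(points) - 1L)) {
    a <- points[s, ]; b <- points[s + 1L, ]
    lo <- pmin(a, b) - pad; hi <- pmax(a, b) + pad
    ir <- which(g$x >= lo[1] & g$x <= hi[1])
    jr <- which(g$y >= lo[2] & g$y <= hi[2])
    kr <- which(g$z >= lo[3] & g$z <= hi[3])
    if (!length(ir) || !length(jr) || !length(kr)) next
    co <- expand.grid(x = g$x[ir], y = g$y[jr], z = g$z[kr])
    dist <- segmentDistance(co$x, co$y, co$z, a, b)
    mult <- applyProfile(mult, ir, jr, kr,
                         array(dist, c(length(ir), length(jr), length(kr))),
                         radius, depth, edge)
  }
  mult
}

addPlane <- function(mult, g, spacing, origin, normal, thickness, depth, edge) {
  nh <- normal / sqrt(sum(normal^2))
  co <- expand.grid(x = g$x, y = g$y, z = g$z)
  dist <- abs((co$x - origin[1]) * nh[1] + (co$y - origin[2]) * nh[2] +
                (co$z - origin[3]) * nh[3])
  d3 <- array(dist, c(length(g$x), length(g$y), length(g$z)))
  applyProfile(mult, seq_along(g$x), seq_along(g$y), seq_along(g$z),
               d3, thickness / 2, depth, edge)
}

#' Generate a synthetic phantom
#'
#' Background = `backgroundMean` + seeded Gaussian noise; each lesion
#' multiplies local intensity by `1 - depth * profile(distance)` with a
#' smooth error-function edge about one in-plane voxel wide; overlapping
#' lesions compose by taking the darkest multiplier. The mask is the full
#' grid eroded by `maskMarginMM` from every face. Deterministic given the
#' spec (including its seed).
#'
#' @param spec a [PhantomSpec-class].
#' @return A [PhantomOutput-class] with volume, mask and ground truth (one
#'   entry per sphere; "definite" for diameter >= 3 mm, else "possible").
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@extents
  sp <- spec@spacingMM
  g <- worldGrid(d, sp)
  hiW <- (d - 1L) * sp
  edge <- sp[1L]
  s <- spec@spheres
  if (nrow(s) > 0) {
    bad <- s$x < 0 | s$x > hiW[1] | s$y < 0 | s$y > hiW[2] |
      s$z < 0 | s$z > hiW[3]
    if (any(bad))
      cmbStop("cmbrst_out_of_grid", "sphere center(s) outside the grid")
  }
  for (tb in spec@tubes)
    if (any(tb$points < 0) ||
        any(sweep(tb$points, 2L, hiW, `>`)))
      cmbStop("cmbrst_out_of_grid", "tube polyline outside the grid")
  mult <- array(1, d)
  for (r in seq_len(nrow(s)))
    mult <- addSphere(mult, g, sp, c(s$x[r], s$y[r], s$z[r]),
                      s$diameter[r], s$depth[r], edge)
  for (tb in spec@tubes)
    mult <- addTube(mult, g, sp, tb$points, tb$radius, tb$depth, edge)
  for (pl in spec@planes)
    mult <- addPlane(mult, g, sp, pl$origin, pl$normal, pl$thickness,
                     pl$depth, edge)
  vol <- withSeed(spec@seed, {
    bg <- spec@backgroundMean +
      array(stats::rnorm(prod(d), 0, spec@noiseSigma), d)
    if (spec@textureSigma > 0) {
      tex <- gaussianSmooth(array(stats::rnorm(prod(d)), d),
                            spec@textureScaleMM / 2, sp)
      inner <- tex[2:(d[1] - 1L), 2:(d[2] - 1L), 2:(d[3] - 1L)]
      tex <- tex / stats::sd(inner) * spec@textureSigma
      bg <- bg + tex
    }
    bg * mult
  })
  maskArr <- array(0, d)
  ii <- which(g$x >= spec@maskMarginMM & g$x <= hiW[1] - spec@maskMarginMM)
  jj <- which(g$y >= spec@maskMarginMM & g$y <= hiW[2] - spec@maskMarginMM)
  kk <- which(g$z >= spec@maskMarginMM & g$z <= hiW[3] - spec@maskMarginMM)
  maskArr[ii, jj, kk] <- 1
  truth <- if (nrow(s) > 0)
    data.frame(id = sprintf("mb%03d", seq_len(nrow(s))),
               x_mm = s$x, y_mm = s$y, z_mm = s$z,
               label = ifelse(s$diameter >= 3, "definite", "possible"),
               stringsAsFactors = FALSE)
  else data.frame(id = character(0), x_mm = numeric(0), y_mm = numeric(0),
                  z_mm = numeric(0), label = character(0),
                  stringsAsFactors = FALSE)
  new("PhantomOutput",
      volume = VoxelVolume(vol, sp),
      mask = VoxelVolume(maskArr, sp),
      truth = truth, spec = spec)
}

randomTubePolyline <- function(loW, hiW, orientation) {
  nseg <- 4L
  if (orientation == "through") {
    x0 <- stats::runif(1, loW[1], hiW[1]); y0 <- stats::runif(1, loW[2], hiW[2])
    zs <- seq(loW[3], hiW[3], length.out = nseg + 1L)
    jit <- function(n) stats::runif(n, -3, 3)
    pts <- cbind(pmin(pmax(x0 + cumsum(c(0, jit(nseg))), loW[1]), hiW[1]),
                 pmin(pmax(y0 + cumsum(c(0, jit(nseg))), loW[2]), hiW[2]),
                 zs)
  } else {
    z0 <- stats::runif(1, loW[3], hiW[3])
    theta <- stats::runif(1, 0, 2 * pi)
    dir2 <- c(cos(theta), sin(theta))
    mid <- c(stats::runif(1, loW[1] + 10, hiW[1] - 10),
             stats::runif(1, loW[2] + 10, hiW[2] - 10))
    span <- min(hiW[1:2] - loW[1:2]) * 0.45
    t <- seq(-span, span, length.out = nseg + 1L)
    jit <- stats::runif(nseg + 1L, -2, 2)
    perp <- c(-dir2[2], dir2[1])
    xy <- cbind(mid[1] + t * dir2[1] + jit * perp[1],
                mid[2] + t * dir2[2] + jit * perp[2])
    pts <- cbind(pmin(pmax(xy[, 1], loW[1]), hiW[1]),
                 pmin(pmax(xy[, 2], loW[2]), hiW[2]),
                 pmin(pmax(z0 + stats::runif(nseg + 1L, -2, 2), loW[3]), hiW[3]))
  }
  pts
}

polylineMinDistTo <- function(points, centers) {
  if (nrow(centers) == 0L) return(Inf)
  mn <- Inf
  for (s in seq_len(nrow(points) - 1L)) {
    dst <- segmentDistance(centers[, 1], centers[, 2], centers[, 3],
                           points[s, ], points[s + 1L, ])
    mn <- min(mn, dst)
  }
  mn
}

#' Generate the standard reproducible phantom cohort
#'
#' Emulates the cohort structure of a memory-clinic microbleed study: about
#' 53% of participants carry at least one microbleed, with a right-skewed
#' per-participant count (1 + a small geometric tail), diameters uniform on
#' [2, 10] mm and depths uniform on [0.5, 0.9]. Every phantom receives 3-8
#' decoy tubes and 1-2 decoy planes, placed at least 8 mm from every sphere
#' center so decoys never contaminate truth matching. Fully deterministic
#' given the seed.
#'
#' @param nParticipants cohort size (>= 2).
#' @param seed integer RNG seed.
#' @param extents,spacingMM grid geometry passed to each phantom.
#' @return List of [PhantomOutput-class] objects.
#' @export
standardCohort <- function(nParticipants, seed = 20130621,
                           extents = c(96, 96, 40), spacingMM = c(1, 1, 3)) {
  if (nParticipants < 2L)
    cmbStop("cmbrst_bad_params", "nParticipants must be >= 2")
  hiW <- (extents - 1L) * spacingMM
  withSeed(seed, {
    lapply(seq_len(nParticipants), function(p) {
      hasMB <- stats::runif(1) < 0.53
      nmb <- if (hasMB) min(1L + stats::rgeom(1L, 0.55), 8L) else 0L
      centers <- matrix(numeric(0), 0, 3)
      spheres <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                            diameter = numeric(0), depth = numeric(0))
      if (nmb > 0) {
        diam <- stats::runif(nmb, 2, 10)
        depth <- stats::runif(nmb, 0.5, 0.9)
        for (m in seq_len(nmb)) {
          margin <- diam[m] / 2 + 5
          for (try in 1:200) {
            c0 <- c(stats::runif(1, margin, hiW[1] - margin),
                    stats::runif(1, margin, hiW[2] - margin),
                    stats::runif(1, margin, hiW[3] - margin))
            if (nrow(centers) == 0L ||
                min(sqrt(colSums((t(centers) - c0)^2))) >= 12) break
          }
          centers <- rbind(centers, c0)
          spheres <- rbind(spheres,
                           data.frame(x = c0[1], y = c0[2], z = c0[3],
                                      diameter = diam[m], depth = depth[m]))
        }
      }
      ntube <- sample(3:8, 1L)
      tubes <- lapply(seq_len(ntube), function(t) {
        orientation <- sample(c("through", "inplane"), 1L)
        radius <- stats::runif(1, 0.6, 1.5)
        depth <- stats::runif(1, 0.5, 0.9)
        best <- NULL; bestD <- -Inf
        for (try in 1:40) {
          pts <- randomTubePolyline(c(0, 0, 0), hiW, orientation)
          dmin <- polylineMinDistTo(pts, centers)
          if (dmin >= 8) { best <- pts; break }
          if (dmin > bestD) { bestD <- dmin; best <- pts }
        }
        list(points = best, radius = radius, depth = depth)
      })
      nplane <- sample(1:2, 1L)
      planes <- lapply(seq_len(nplane), function(q) {
        thickness <- stats::runif(1, 0.6, 1.2)
        depth <- stats::runif(1, 0.4, 0.8)
        best <- NULL; bestD <- -Inf
        for (try in 1:40) {
          theta <- stats::runif(1, 0, 2 * pi)
          nh <- c(cos(theta), sin(theta), stats::runif(1, -0.2, 0.2))
          nh <- nh / sqrt(sum(nh^2))
          origin <- c(stats::runif(1, 0.25, 0.75) * hiW[1],
                      stats::runif(1, 0.25, 0.75) * hiW[2],
                      stats::runif(1, 0.25, 0.75) * hiW[3])
          dmin <- if (nrow(centers) == 0L) Inf else
            min(abs((centers[, 1] - origin[1]) * nh[1] +
                      (centers[, 2] - origin[2]) * nh[2] +
                      (centers[, 3] - origin[3]) * nh[3]))
          if (dmin >= 8) { best <- list(origin = origin, normal = nh); break }
          if (dmin > bestD) { bestD <- dmin; best <- list(origin = origin,
                                                          normal = nh) }
        }
        list(origin = best$origin, normal = best$normal,
             thickness = thickness, depth = depth)
      })
      spec <- PhantomSpec(extents = extents, spacingMM = spacingMM,
                          spheres = spheres, tubes = tubes, planes = planes,
                          seed = sample.int(2147483646L, 1L))
      generatePhantom(spec)
    })
  })
}

#' Write a phantom cohort to disk as NIfTI + CSV
#'
#' Writes `vol_NNN.nii.gz`, `mask_NNN.nii.gz` and `truth_NNN.csv` per
#' participant plus a `manifest.csv` (volume, mask, truth paths) consumable
#' by [runFroc()] and [runTiered()].
#'
#' @param outDir output directory (created if needed).
#' @param nParticipants cohort size.
#' @param seed cohort seed.
#' @param extents,spacingMM grid geometry.
#' @return Path to the manifest, invisibly.
#' @export
writePhantomCohort <- function(outDir, nParticipants, seed = 20130621,
                               extents = c(96, 96, 40),
                               spacingMM = c(1, 1, 3)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- standardCohort(nParticipants, seed, extents, spacingMM)
  rows <- lapply(seq_along(cohort), function(p) {
    vf <- file.path(outDir, sprintf("vol_%03d.nii.gz", p))
    mf <- file.path(outDir, sprintf("mask_%03d.nii.gz", p))
    tf <- file.path(outDir, sprintf("truth_%03d.csv", p))
    writeVolume(cohort[[p]]@volume, vf)
    writeVolume(cohort[[p]]@mask, mf)
    writeGroundTruth(cohort[[p]]@truth, tf)
    data.frame(volume = vf, mask = mf, truth = tf, stringsAsFactors = FALSE)
  })
  manifest <- file.path(outDir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
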