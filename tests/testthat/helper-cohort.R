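# Shared fixtures, generated in code and memoized for the whole test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixtures <- new.env(parent = emptyenv())

standardSeed <- 20130621
defaultGridT3d <- seq(0.5, 3, by = 0.5)
defaultGridT2d <- seq(0, 3, by = 0.5)

# The standard 20-participant phantom cohort at the package's default study
# conditions (96 x 96 x 40 grid, (1,1,3) mm voxels).
getStandardCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- cmbrst::standardCohort(20, seed = standardSeed)
  .fixtures$cohort
}

# Cached per-participant scores over the full threshold lattice.
getStandardPrep <- function() {
  if (is.null(.fixtures$prep))
    .fixtures$prep <- cmbrst::cohortScores(getStandardCohort(),
                                           cmbrst::RSTParams(),
                                           defaultGridT3d)
  .fixtures$prep
}

getStandardFroc <- function() {
  if (is.null(.fixtures$froc))
    .fixtures$froc <- cmbrst:::frocFromScores(getStandardPrep(),
                                              defaultGridT3d, defaultGridT2d,
                                              5, "all")
  .fixtures$froc
}

# A small, fast phantom for unit tests: one clear microbleed analogue, one
# through-plane vessel analogue, quiet-ish background.
smallPhantom <- function(seed = 42, withSphere = TRUE, withTube = TRUE,
                         noiseSigma = 4, textureSigma = 20) {
  spheres <- if (withSphere)
    data.frame(x = 14, y = 14, z = 15, diameter = 5, depth = 0.8) else NULL
  tubes <- if (withTube)
    list(list(points = cbind(c(28, 29, 28), c(28, 27, 28), c(0, 16, 33)),
              radius = 1.2, depth = 0.8)) else list()
  cmbrst::generatePhantom(cmbrst::PhantomSpec(
    extents = c(40, 40, 12), spacingMM = c(1, 1, 3),
    spheres = spheres, tubes = tubes,
    noiseSigma = noiseSigma, textureSigma = textureSigma, seed = seed))
}

# Write one phantom's volume/mask/truth trio to disk for pipeline runs.
writeSmallPair <- function(dir, ph) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vf <- file.path(dir, "vol.nii.gz")
  mf <- file.path(dir, "mask.nii.gz")
  tf <- file.path(dir, "truth.csv")
  cmbrst::writeVolume(cmbrst::phantomVolume(ph), vf)
  cmbrst::writeVolume(cmbrst::phantomMask(ph), mf)
  cmbrst::writeGroundTruth(cmbrst::phantomTruth(ph), tf)
  c(volume = vf, mask = mf, truth = tf)
}

# Attribute candidates to decoys (tubes/planes) from the generating spec.
attributeCandidates <- function(candidates, phantom, truthTolMM = 5,
                                decoyTolMM = 3) {
  spec <- phantom@spec
  tr <- cmbrst::phantomTruth(phantom)
  cls <- rep("noise", nrow(candidates))
  if (nrow(candidates) == 0L) return(cls)
  if (nrow(tr) > 0) {
    m <- cmbrst::matchCandidates(candidates, tr, truthTolMM)
    cls[candidates$id %in% m$pairs$candidate_id] <- "truth"
  }
  dT <- rep(Inf, nrow(candidates))
  for (tb in spec@tubes)
    for (s in seq_len(nrow(tb$points) - 1L))
      dT <- pmin(dT, cmbrst:::segmentDistance(
        candidates$x_mm, candidates$y_mm, candidates$z_mm,
        tb$points[s, ], tb$points[s + 1L, ]) - tb$radius)
  dP <- rep(Inf, nrow(candidates))
  for (pl in spec@planes)
    dP <- pmin(dP, abs((candidates$x_mm - pl$origin[1]) * pl$normal[1] +
                         (candidates$y_mm - pl$origin[2]) * pl$normal[2] +
                         (candidates$z_mm - pl$origin[3]) * pl$normal[3]) -
                 pl$thickness / 2)
  cls[cls != "truth" & (dT <= decoyTolMM | dP <= decoyTolMM)] <- "decoy"
  cls
}
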