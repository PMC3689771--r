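---
title: "Detecting cerebral microbleeds with a two-stage radial symmetry transform"
author: "cmbrst authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cerebral microbleeds with a two-stage radial symmetry transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmbrst)
```

## The problem

Cerebral microbleeds are small (roughly 2-10 mm) hemosiderin deposits that
appear as hypointense, approximately spherical lesions on T2*-weighted MRI.
Visual rating is slow and rater-dependent; a semi-automated detector that
proposes candidate locations for a human to censor can cut rating time from
5-10 minutes to 1-2 minutes per participant while matching the sensitivity
of experienced raters. The difficulty at clinical field strengths is the
anisotropic voxel grid (slices much thicker than the in-plane resolution)
and the abundance of dark mimics: vessels, calcifications, fissures, and
bone/air artifacts.

`cmbrst` implements a two-stage pipeline:

1. **Stage 1 (3D).** The brain-masked volume is intensity-normalized and a
   3D radial symmetry transform (RST) scores every voxel for how strongly
   surrounding gradients converge on it. Thresholding the map at `t3d`
   inside the mask and clustering suprathreshold voxels yields candidate
   locations.
2. **Stage 2 (2D minIP).** Around each candidate a 12-mm transversal
   minimum-intensity-projection patch is built and re-scored with a 2D RST
   using the same settings. On a minIP, spherical lesions stay compact and
   round while vessels and fissures elongate, so candidates whose 2D score
   does not exceed `t2d` are discarded. Setting `t2d = 0` switches the
   stage off.

## The transform

For each physical radius $n$ (mm), every voxel $p$ whose gradient magnitude
exceeds a fraction (default 0.05) of the image maximum casts a vote at

$$p_{\pm} = p \pm \mathrm{round}\!\left(\frac{n\,\hat g(p)}{s}\right),$$

where $\hat g$ is the unit gradient and $s$ the per-axis voxel spacing.
Dark polarity (the pipeline default: microbleeds are hypointense) uses only
the negatively-affected voxel $p_-$: on the rim of a dark blob the gradient
points outward, so $p_-$ lands at the blob center. Votes accumulate an
orientation count $O_n$ and a gradient-magnitude sum $M_n$; out-of-grid
votes are discarded. The per-radius response is

$$F_n = \frac{M_n}{k_n}\left(\frac{\min(|O_n|, k_n)}{k_n}\right)^{\alpha},$$

smoothed with a Gaussian of scale $0.5\,n$ mm (converted per axis to voxel
units, zero-padded at the boundary), and the final map averages the
smoothed responses over the radius set. Gradients are central differences
divided by the per-axis spacing, so the whole construction is in physical
units: a 5-mm sphere is detected at its center whether the grid is 1 mm
isotropic or (1, 1, 3) mm anisotropic. Anisotropy is handled in the vote
geometry (per-axis rounding), not by resampling, which avoids interpolation
artifacts at 3-mm slice thickness.

The saturation count $k_n$ is the number of voxel offsets a perfect digital
sphere shell of radius $n$ would vote into its center on the given grid,
enumerated once per radius/spacing pair. It scales the orientation term so
that full shell convergence, and only full convergence, reaches the maximal
radial-strictness factor of 1. The strictness exponent $\alpha$ (default 2)
penalizes partial convergence, which is what distinguishes a sphere (votes
from all around) from a tube (votes only from the cross-sectional rim).

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `radiiMM` | 1, 2, 3, 4 mm | voting radii; should span the expected lesion radii |
| `alpha` | 2 | radial strictness; higher suppresses elongated structures harder |
| `smoothSigmaFactor` | 0.5 | per-radius Gaussian scale, as a fraction of the radius |
| `gradThresholdFrac` | 0.05 | relative gradient-magnitude floor for voting |
| `polarity` | dark | vote direction; dark for hypointense lesions |

Radii are deliberately a configuration knob: lesions larger than the
largest radius respond weakly (their rim votes fall short of the center),
and lesions thinner than a slice can vanish between slice centers. Both
failure modes are visible in the phantom experiments below.

## Normalization

Stage-1 thresholds are only transferable if the input scale is fixed. The
in-mask histogram is mapped linearly so that its 6th percentile goes to 0
and its 95th percentile to 255, clipping outside that window (percentiles
use the standard linear-interpolation definition). Microbleed intensities
sit below the 6th percentile on T2*-weighted scans, so lesions saturate at
the dark end while the bulk tissue contrast fills the range. Clipping
rather than extrapolating keeps the output bounded; the mapping is
invariant to positive affine rescalings of the raw intensities. Voxels
outside the mask are filled with 255 (bright): the transform reads
gradients from neighbors across the mask border, and a bright fill ensures
the border cannot imitate a dark blob (it instead imitates the real-world
bright/dark interfaces at the skull base, a known false-positive source).

## Candidates, matching and the threshold lattice

Each connected component (26-connectivity by default, conservative on
anisotropic grids) of the suprathreshold mask becomes exactly one
candidate at its maximum-value voxel, ties broken toward the
lexicographically smallest index so results are deterministic. Candidates
carry both the 0-based voxel index and world-mm coordinates; evaluation
matches candidates to ground-truth lesions greedily in ascending Euclidean
distance, one-to-one, within a 5-mm default tolerance (about half the
largest typical lesion diameter and more than one slice thickness).

The operating point is the pair (`t3d`, `t2d`). The FROC evaluation sweeps
the lattice t3d in {0.5, ..., 3.0} by 0.5 and t2d in {0.0, ..., 3.0} by
0.5 - 42 combinations - and reports per point the cohort sensitivity and
the mean number of passed candidates per participant (candidates, not
false positives: true detections are part of the censoring workload). The
Pareto frontier of these points (highest sensitivity at lowest candidate
burden) is where operating settings should be chosen; the shipped presets
A/B/C are frontier points of the standard phantom cohort (moderate, good,
high sensitivity) and are explicitly site-calibrated values that should be
re-derived for any new scanner protocol or cohort.

One caching subtlety: the expensive stages (the 3D map, the per-candidate
2D scores) are computed once per volume and reused across the lattice, but
candidates are re-clustered at every `t3d` rather than filtered from the
most permissive threshold. Raising `t3d` can split one component into
several, relocating peak voxels, so filtering cached candidates would not
equal recomputation; re-clustering on the cached map is exact. The same
mechanism means the *two-stage* pipeline is not guaranteed monotone along
`t3d`: a split can expose a child peak whose 2D score passes where the
parent peak failed. Along `t2d` the passed sets are nested by construction.
The phantom experiments show the practical size of this effect (a few
candidates at a few lattice cells).

## The phantom generator

Real patient volumes cannot ship with the package, so every experiment
runs on synthetic phantoms with exact ground truth. A phantom is a
96 x 96 x 40 grid of (1, 1, 3) mm voxels containing:

* a background of mean 200 with a smooth low-frequency texture
  (sd 30, correlation length 20 mm) plus white Gaussian noise (sd 8).
  The texture matters: percentile normalization on a texture-free
  background would stretch pure noise across [0, 255], which resembles no
  real scan. With it, the histogram is contrast-dominated, as on
  T2*-weighted images;
* dark **spheres** (the microbleed analogues) with diameters uniform on
  [2, 10] mm and fractional intensity drops uniform on [0.5, 0.9];
* dark curvilinear **tubes** (vessel analogues, 3-8 per phantom) and 1-2
  dark **planes** (fissure analogues), placed at least 8 mm from every
  sphere so decoys never contaminate truth matching;
* a mask equal to the grid eroded 3 mm from each face. Mask-boundary
  behavior is what matters computationally; anatomical realism is a
  non-goal.

Lesions darken multiplicatively, `intensity * (1 - depth * profile)`, with
an error-function edge about one in-plane voxel wide (hard edges would
make the transform artificially easy; T2* hypointensities bloom), and
overlapping lesions compose by taking the darkest multiplier. Everything
is a pure function of the spec and its seed; truth labels follow diameter
(>= 3 mm definite, smaller possible).

The standard cohort (`standardCohort(20)`) gives ~53% of participants at
least one sphere with a right-skewed count (1 plus a small geometric
tail), mirroring the prevalence structure of memory-clinic cohorts.

**What passing on phantoms does and does not show.** The phantoms exercise
the geometry (anisotropy, physical radii, slab projection), the threshold
semantics, and the sphere-versus-elongated-structure discrimination. They
do not reproduce patient-scale false-positive counts or sensitivities:
real scans add susceptibility artifacts, motion, anatomy-correlated
mimics, and rater uncertainty. Numbers measured here characterize the
implementation under controlled conditions, not clinical performance.

## Design choices and numerical details

* **Coordinates.** Voxel indices are 0-based; world coordinates are mm in
  the NIfTI affine frame. World mm is authoritative for evaluation
  matching (the tolerance is physical). Slab selection assumes
  axial-aligned volumes (the transversal minIP is taken along the third
  axis).
* **Percentile definition.** Linear interpolation between order
  statistics; the tests pin this against an explicit sort-and-interpolate
  oracle.
* **Vote rounding.** Per-axis `round()` (round-half-even); symmetric, and
  identical in the vectorized path and the loop oracle.
* **Smoothing boundary.** Zero padding. Responses within a kernel radius
  of the volume edge are attenuated; candidates that close to the edge
  are dominated by mask-border effects anyway.
* **Stage-2 reads.** The candidate's 2D score is the patch-map maximum
  within a 1-voxel halo of the projected candidate position, absorbing
  the one-voxel peak drift that the minIP can introduce. Failures inside
  a single candidate's scoring (degenerate patch, etc.) reject that
  candidate with a warning rather than aborting the batch.
* **Strict inequalities.** A candidate needs `s3d > t3d` to exist and
  `s2d > t2d` to survive stage 2, so `t2d = 0` with all-nonnegative maps
  passes everything only because the stage is explicitly bypassed there.
* **Degenerate inputs.** Constant volumes produce an all-zero map (no
  gradients, no votes). Constant in-mask histograms are a named error, as
  are empty masks, grid mismatches, out-of-grid indices and non-3D files.

## Known limitations

* Lesions with radius beyond the largest voting radius respond weakly;
  on the standard cohort the permissive-setting misses are a ~10 mm
  sphere and a shallow mid-size sphere, not only sub-slice lesions.
* The 2D minIP score is substantially more noise-sensitive than the 3D
  score (a 2D rim musters an order of magnitude fewer voters than a 3D
  shell), so nonzero `t2d` trades real sensitivity for its false-positive
  reduction; the stage removes well over half of the tube/plane-induced
  candidates at mid-lattice thresholds but also removes weakly-scored
  true spheres. Choose `t2d` on the frontier, not by intuition.
* Nearly vertical straight vessels project to compact dots on a
  transversal minIP and are not separable by the 2D stage - only tilted
  or in-plane elongated structures are. This matches the clinical
  experience that perforating vessels are the classic microbleed mimic.
* The tiered A-then-C workflow only saves work if setting A screens some
  participants to zero candidates; on phantoms whose noise floor always
  produces a few stage-1 candidates, tiering reduces to the flat
  high-sensitivity run.

## A worked run

```{r, eval = FALSE}
library(cmbrst)

cohort <- standardCohort(6, seed = 20130621, extents = c(64, 64, 24))
prep <- cohortScores(cohort, RSTParams(), seq(0.5, 3, by = 0.5))
froc <- frocFromScores(prep, seq(0.5, 3, by = 0.5), seq(0, 3, by = 0.5))
paretoFrontier(froc)

## single-volume use on files:
# runDetect("t2star.nii.gz", "mask.nii.gz",
#           defaultPipelineConfig(), "out/", preset = "B")
```

The experiment sizes used throughout the package (20 phantoms of
96 x 96 x 40 voxels for cohort-level checks, 16-24 voxel cubes for the
transform-equality checks) were chosen so that the full suite re-runs
comfortably on a single CPU while still exercising every code path at
realistic anisotropy.
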