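Package: cmbrst
Title: Semi-Automated Cerebral Microbleed Detection via the Radial
    Symmetry Transform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects cerebral microbleeds on T2*-weighted MR volumes with a
    two-stage radial symmetry transform (RST) pipeline. A percentile-based
    intensity normalization maps the brain-masked volume to [0, 255]; a 3D
    RST with physical (mm) radii on anisotropic voxel grids highlights dark
    spherical lesions and is thresholded into candidate locations; each
    candidate is re-scored by a 2D RST on a 12-mm transversal
    minimum-intensity-projection patch, which suppresses elongated mimics
    such as vessels and fissures. Includes FROC evaluation over a
    two-threshold lattice, Pareto-frontier extraction, a tiered screening
    workflow, and a reproducible synthetic-phantom generator with exact
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
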