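Package: occlumap
Title: Depth-Map Projection and Generative Partial Reconstruction of Molar
    Occlusal Surfaces
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for digital restoration of prepared molar teeth from
    triangle meshes. Implements pose normalization of single-crown meshes
    (minimum-volume oriented bounding box derotation followed by PCA-plane
    leveling of the occlusal surface), calibrated 8-bit depth-map projection
    with in-plane canonicalization and repeatability analysis, automatic
    extraction of the preparation-area binary mask from surface-normal and
    height heuristics, latent-space inversion of a tooth-image generator
    under a Bayesian reconstruction objective augmented with a boundary loss
    that enforces a seamless restoration edge, masked merging, back-projection
    of depth maps to heightfield meshes, and a millimetre-scale evaluation
    protocol (error-distance distributions, rising-mask studies, interior
    versus contour-cutting mask comparisons). A parametric synthetic-molar
    generator with known ground-truth preparations makes the full pipeline
    testable without clinical scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    grDevices,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
biocViews: Software, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'mask.R'
    'generator.R'
    'losses.R'
    'reconstruct.R'
    'evaluate.R'
    'mesh.R'
    'normalize.R'
    'pipeline.R'
    'projection.R'
    'synthetic.R'
    'utils-geometry.R'
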