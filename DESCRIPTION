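Package: leafpol
Title: Leaf Surface Phenotyping from Focus Stacks and Polarized Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes leaf surface phenotypes from two complementary
    measurements: shape-from-focus reconstruction of microscope focus stacks
    (in-focus composite, metric depth map, cell-scale roughness metrics such
    as margin undulation and cell cap aspect ratio), and polarized
    reflectance scans taken at Brewster's-angle geometry, from which the
    polarized bidirectional reflectance factor R_Qav and the red-edge
    diffuse ratio DIFF_R are extracted.  A quadratic discriminant classifier
    with equal priors assigns the four phenotypes (glossy wax, glaucous wax,
    hairy, glabrous) from these two features, and a Monte-Carlo random-split
    harness summarizes classification-rate distributions.  Synthetic
    generators for surfaces, focus stacks, polarized scan sets and labeled
    feature clouds make the whole pipeline testable without real leaves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
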