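Package: colonymap
Title: Multi-Scale Image Analysis of Pluripotent Stem Cell Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative, colony-aware image cytometry of
    pluripotent stem cell cultures. Builds seamless virtual slides from
    grids of overlapping microscope fields by consensus relabeling of
    per-field segmentations (no raw-pixel stitching), segments colonies
    and nuclei, extracts per-cell morphology and intensity features, and
    places every cell in its spatial population context: distance from
    the colony edge, cell layers, colony size classes and local-density
    windows. Includes cell-cycle and marker gating with percentile
    bootstrap confidence intervals, single-molecule RNA FISH spot
    detection in 3-D stacks with adaptive equalization of detection
    thresholds across fields, and a synthetic ground-truth scene
    generator so the whole pipeline can be validated without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    mclust,
    mgcv,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
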