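Package: micropattern
Title: Quantification of Micropatterned Colony Immunofluorescence Assays
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image quantification for micropatterned human pluripotent stem
    cell assays. Detects 500 um circular colonies in DAPI images, segments
    nuclei by watershed on the distance transform, and computes the standard
    spatial readouts of micropattern signalling assays: radial profiles of
    nuclear SMAD2/3 intensity, center/edge band summaries, positive-nucleus
    fractions, and marker area fractions (PAX6, N-CAD, SOX10 over DAPI) for
    neuruloids. Includes a synthetic micropattern image generator with known
    per-nucleus ground truth for validation, a one-way ANOVA layer with
    Dunnett many-to-one and Tukey all-pairs adjustments, and a deterministic
    end-to-end pipeline with CSV and JSON provenance outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    mvtnorm,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Visualization, Classification
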