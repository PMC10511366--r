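Package: AirwayMeasure
Title: Airway Wall Segmentation and Bronchial Parameter Measurement on Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated extraction of bronchial parameters from low-dose chest
    CT volumes given an airway-lumen segmentation. Refines the lumen and finds
    the outer airway-wall surface with a globally optimal coupled two-surface
    graph cut, extracts individual branches by front propagation with Weibel
    generation labelling, measures lumen and wall radii at 0.5 mm intervals
    along branch centrelines, and derives luminal area, wall area percentage,
    square root of wall area, Pi10 and total airway count. Includes a synthetic
    CT scanner module (tube phantoms and bifurcating airway trees with exact
    ground truth), Tree-structured Parzen Estimator tuning of the graph-cut
    parameters against phantoms, and Bland-Altman / R-squared repeat-scan
    reproducibility analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'metaimage.R'
    'io.R'
    'scanner.R'
    'mesh.R'
    'graphcut.R'
    'tree.R'
    'measure.R'
    'tuning.R'
    'repro.R'
    'export.R'
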