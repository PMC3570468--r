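Package: DCGtree
Title: Multi-Scale Ultrametric Clustering Trees via Regulated Random Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives a multi-scale ultrametric topology on a data cloud from
    an empirical similarity or distance matrix. A temperature parameter turns
    the similarity graph into a family of potential landscapes; visit-capped
    node-removing random walks map the potential wells at each temperature;
    ensembles of walks are aggregated into a cluster-sharing probability
    matrix whose eigen-spectrum counts the wells.  Scanning the temperature
    axis locates the phase transitions of the cluster count, and the critical
    levels are assembled into a self-correcting ultrametric, rendered as a
    hierarchical clustering tree (Newick export) and as a block-constant
    Parisi matrix.  Includes generators for the synthetic benchmark clouds
    (collinear Gaussian dots, two interlocking moons, planted-block
    similarity matrices) used to validate the procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'landscape.R'
    'walk.R'
    'sharing.R'
    'phase.R'
    'ultrametric.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'zzz.R'
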