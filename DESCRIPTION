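Package: stnparc
Title: Connectivity-Based Parcellation of the Subthalamic Nucleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for connectivity-based sub-segmentation of the
    subthalamic nucleus (STN) from probabilistic tractography. Binarizes
    voxel-wise probability-of-connection profiles, clusters them with Ward
    linkage on their cross-correlation matrix, selects the cluster number
    by a fractional-variance-explained elbow criterion, consolidates
    parcellations across subjects, derives per-sub-region connectivity
    distributions with seven-class overlap labelling, estimates population
    tissue priors via a Jacobian-weighted groupwise Gaussian mixture, and
    normalizes literature connection-report counts for chord-diagram
    export. Ships a synthetic phantom generator with known ground truth
    for validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
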