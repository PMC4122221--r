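Package: durasim
Title: Dura-Layer Effects in Voxel-Based EEG Forward Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds voxelized multi-layer head phantoms (nested corrugated
    shells with white matter, cortex, CSF, dura, skull and scalp), realizes
    tissue conductivity volumes from a literature resistivity table, and
    solves the quasi-static volume-conduction (EEG forward) problem with a
    cell-centered finite-volume scheme driven by distributed cortical
    dipoles oriented normal to the gray/white boundary.  An analytic
    multi-shell concentric-sphere series solution serves as an independent
    reference for the numerical solver.  Includes tissue-interface potential
    extraction with common-average referencing, topography comparison
    statistics (RDM*, MAG, Kolmogorov-Smirnov tests, histogram and CDF
    summaries), and orchestrated experiments quantifying how the poorly
    conducting dura mater attenuates and spatially smooths scalp potentials,
    including dura-vs-CSF substitution, multi-trial statistics, a
    surface-by-surface smoothing cascade, and skull-conductivity
    sensitivity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
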