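Package: erpfield
Title: Electrical Neuroimaging of Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end electrical-neuroimaging toolchain for two-session
    event-related potential (ERP) studies: epoch preprocessing (band-pass
    filtering, average reference, amplitude-based artifact rejection,
    trial-count floor, spherical-spline interpolation of bad channels),
    mass-univariate point-wise paired t-tests with temporal-persistence and
    spatial-cluster criteria, reference-free global field statistics (Global
    Field Power and global map dissimilarity) with paired randomization tests
    (including topographic analysis of variance, TANOVA), and distributed
    source estimation on an analytic three-shell spherical head model using a
    locally autoregressive weighted-minimum-norm inverse with voxel-wise
    parametric mapping and a cluster-extent threshold.  A dipole-based
    synthetic ERP generator with known ground truth makes every stage of the
    chain verifiable by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
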