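Package: fluctdyn
Title: Comparative Fluctuation Dynamics of Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trajectory-level comparison of protein conformational ensembles:
    distance-fluctuation coordination matrices, essential dynamics (covariance
    PCA) with sampling diagnostics, generalized correlation from k-nearest-
    neighbour mutual information, inter-domain principal-axis torsion angles,
    aromatic ring stacking geometry, hydrogen-bond and salt-bridge occupancy,
    GROMOS conformational clustering, and Gaussian network model slow-mode
    collectivity. Includes synthetic-trajectory generators with known
    statistical and geometric ground truth so every analysis stage can be
    validated end-to-end, plus a pipeline driver for multi-replica,
    multi-system comparative studies such as liganded versus apo integrin
    ectodomains.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
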