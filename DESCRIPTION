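Package: gridmol
Title: Grid-Based Generation of 3D Molecules Conditioned on Receptor
    Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolchain for structure-based molecular generation with atomic
    density grids. Molecules are mapped to multi-channel voxel grids through
    property-based atom typing and a truncated-Gaussian density kernel; a
    receptor-conditional variational autoencoder is trained on such grids;
    and generated densities are inverted back into valid 3D molecules by
    iterative atom fitting with gradient descent followed by rule-based bond
    and hydrogen inference. Includes the sampling controls (variability and
    bias factors, spherical latent interpolation) and molecule-level
    evaluation metrics (validity, novelty, uniqueness, Tanimoto diversity,
    force-field relaxation displacement) used to assess generated molecules.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB,
    bio3d,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
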