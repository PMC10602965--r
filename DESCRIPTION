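Package: npgclust
Title: Integrin Clustering Simulations on Nanoporous Gold Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Lattice kinetic Monte Carlo simulations of integrin activation,
    ligand binding, and association into focal-adhesion clusters on nanoporous
    gold (NPG) substrates. Provides a Cahn-Hilliard generator for bicontinuous
    two-phase substrate morphologies with calibrated pore size, a three-reaction
    energy model in which binding and association energies depend on pore size
    and local gold concentration, a fixed-time-step Monte Carlo engine on a
    periodic membrane lattice, cluster statistics (number of clustered integrins
    and mean focal-adhesion area over the largest decile of clusters), and
    binary-image morphometry (granulometric pore and ligament sizing, cell
    circularity, and pore-ligament regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
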