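Package: volscape
Title: Conformational Energy Landscapes from Cryo-EM Class Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify conformational heterogeneity in single-particle
    cryo-EM class ensembles of two-body complexes such as the 26S proteasome.
    Aligns 3D class volumes on a fixed subcomplex, performs eigenvolume
    principal component analysis via the Gram-matrix trick, converts per-class
    particle counts into Boltzmann free-energy landscapes with minima and
    minimax-path barrier detection, runs iterative competitive two-state
    projection-matching classification of particle images, estimates rigid
    rotation angles of the mobile subcomplex, and provides atomic-model
    B-factor segment truncation and AAA+ ring hexagon-angle analyses. A
    synthetic two-rigid-body phantom generator with Boltzmann-distributed
    class populations makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
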