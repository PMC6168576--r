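Package: shellcrack
Title: Lattice-Spring Shell Model of Crack Formation in Growing Stratum
    Corneum on Papillated Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a brittle, thin keratinous sheet (stratum corneum)
    growing on, or drying over, a papillated skin substrate, using a
    lattice-spring discrete-shell model with a curved stress-free rest
    configuration, damped Newtonian quasi-static relaxation, and
    strain-threshold bond breaking.  Includes a synthetic generator for
    quasi-regular papillary substrates, triangle-mesh utilities with
    OFF/OBJ/PLY input and output and an isotropic regularisation pass,
    virtual cross-sections through cracked sheets, and tri-junction
    angular statistics for crack and trough networks: (theta1, theta2)
    scatter, angular spreading, archetype classification and angle
    probability densities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
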