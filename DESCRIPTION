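Package: sigmacomp
Title: Sigma Factor Competition for RNA Polymerase Core Enzyme
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-steady-state modeling of competition between bacterial
    sigma factors for a shared pool of RNA polymerase core enzyme.
    Solves the coupled binding equilibria that partition core RNAP among
    an arbitrary number of sigma species, optionally with anti-sigma
    sequestration, non-specific DNA binding of cores and holoenzymes,
    Michaelis-Menten promoter occupancy with holoenzyme repression, and a
    self-consistent transcription cycle in which elongation sequesters
    subunits and inflates the effective sigma-core dissociation constant.
    Provides parameter scans, competition-onset detection, logarithmic
    response-factor (hypersensitivity) analysis, a stringent-response
    preset, dissociation-constant estimation from titration assays, and a
    synthetic titration-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
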