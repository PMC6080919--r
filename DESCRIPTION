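Package: congressim
Title: Two-Step Chromosome Congression: Simulation and Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Stochastic simulation and analysis of chromosome congression in
    large oocytes. Implements microtubule search-and-capture from static
    centrosomal asters extended by an F-actin-network velocity field that
    advects chromosomes toward the animal pole, and by a time-gated
    kinetochore binding rate standing in for Arp2/3-nucleated F-actin patches.
    Includes trajectory segmentation to detect capture events as the switch
    from slow advective/diffusive to fast directed poleward motion,
    spherical-ROI patch-intensity quantification with assembly/peak/disassembly
    timing, and seeded synthetic-data generators (trajectories, intensity
    traces, small 4D image stacks) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
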