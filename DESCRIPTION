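Package: dpcrmelt
Title: Droplet Digital PCR Quantification with Stepwise Melting Multiplexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An image-to-answer toolkit for droplet digital PCR (dPCR) on
    planar monolayer droplet arrays (PMDAs). Simulates droplet occupancies and
    multichannel, multi-temperature fluorescence images with ground truth;
    detects droplets and filters artifacts; aligns droplets across filter and
    temperature pages; classifies positives; and computes absolute
    concentrations by Poisson statistics, copy-number-variation ratios,
    variant allele frequencies, and multi-target digital stepwise melting
    analysis (dSMA) deconvolutions with uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
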