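Package: dnachannel
Title: Simulation of the DNA Data Storage Error Channel and Redundancy Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end stochastic simulator for the DNA data storage
    channel. Oligo pools are represented as variant tables (error types with
    copy numbers) and pushed through synthesis, decay, PCR, sampling and
    sequencing stages built from two primitives: an error-generation step and
    a copy-number distribution-change step. Reads are combined by positional
    majority voting, and the resulting loss and within-sequence error profiles
    drive a redundancy-design procedure for fountain plus Reed-Solomon coding:
    information density across Reed-Solomon lengths, Poisson fits of the total
    lost count, Gumbel fits of the droplets needed for fountain decoding, and
    the failure probability across fountain overheads. A self-contained
    Luby-transform fountain encoder and peeling decoder generates all test
    inputs, so no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
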