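Package: oxyderep
Title: Accurate-Mass Dereplication and 16S Mutation Scanning for
    Oxidative-Stress Cultivation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing secondary-metabolite induction in
    actinobacteria cultivated under elevated oxygen and ozone. Implements
    accurate-mass dereplication of LC-MS features against a natural-product
    library under a conjunctive Dalton + ppm tolerance with a
    biological-source filter, cross-sample feature alignment,
    presence/absence differential detection across cultivation conditions,
    encoding of DPPH radical-scavenging and disk-diffusion bioassays,
    substitution scanning of weekly 16S rRNA consensus sequences with
    mapping onto E. coli-numbered variable regions, Tamura-Nei (TN93)
    distances and neighbor-joining trees, plus seeded synthetic-data
    generators with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
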