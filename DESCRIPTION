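Package: ervatlas
Title: Cataloging, Classification and Molecular-Clock Dating of HML-2 Endogenous Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and characterizing catalogs of HERV-K (HML-2)
    endogenous retroviruses. Calls proviruses and solo LTRs from repeat
    annotations, classifies proviruses as type 1/2 by the 292-bp pol-env
    deletion and LTRs into the LTR5Hs/LTR5A/LTR5B subgroups by diagnostic
    indels, dates insertions with a paired-LTR molecular clock and with a
    calibrated solo-LTR consensus-distance method (Jukes-Cantor and Kimura
    2-parameter corrections), detects post-integration recombination via
    non-paired cognate LTRs and sliding-window breakpoint scans, and models
    the chromosomal distribution of elements with negative-binomial count
    regression. Includes a seeded synthetic ERV-evolution generator with
    full ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    MASS,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
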