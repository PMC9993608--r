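Package: diapausekit
Title: Time-Course Kinetics of Avian Embryonic Diapause and Reactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tidy tools for locating the termination of cold-induced
    embryonic diapause in multi-omic time courses. Implements a
    self-contained negative-binomial differential-expression caller with
    interval-normalised DEG rates, DEG retention and transition-window
    localisation; fold-change reversal regression between the diapause
    and reactivation contrasts with gene-set fold-change summaries; a
    three-condition temperature-responsive marker-gene screen plus a
    2^-ddCt qPCR utility; phosphopeptide normalisation, regulation calls
    and kinase-substrate enrichment analysis (KSEA) with
    permutation-normalised enrichment scores; and an OPLS-DA/VIP
    metabolite screen. Ships synthetic-data generators with planted,
    parameterised structure so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
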