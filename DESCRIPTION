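Package: metshift
Title: Rule-Based Metabolite Identification from High-Resolution LC-MS(n) Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mass-shift driven identification of drug metabolites
    from high-resolution LC-ESI-MS(n) peak lists, built around the in vivo
    metabolism of the flavanonol taxifolin (dihydroquercetin). Provides
    elemental-composition arithmetic and brute-force molecular formula
    prediction from accurate mass, enumeration of phase I/II biotransformation
    networks (including flavonoid dimerization and ring-cleavage phenolic
    acids), MS2/MS3 annotation by characteristic neutral losses and aglycone
    fragment matching, regioisomer assignment by the ClogP elution-order rule,
    dimer coupling-bond classification, identification-level bookkeeping, and
    metabolite-by-compartment distribution summaries. A ground-truthed
    synthetic peak-list generator supports end-to-end recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
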