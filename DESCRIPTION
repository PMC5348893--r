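Package: misilk
Title: Spidroin Gene Architecture and Minor Ampullate Silk Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the architecture of spider silk protein
    (spidroin) genes and linking it to fiber mechanics. Annotates the
    repetitive-region motif grammar of minor ampullate spidroins (GGX,
    poly-alanine, (GA)n, GPG), detects serine/threonine/valine-rich spacer
    regions and tandem/ensemble repeats, quantifies paralog divergence and
    concerted-evolution signatures, estimates paralog expression ratios from
    3'-biased read sets, derives true-stress/true-strain tensile properties
    from force-extension traces, and fits structure-property regressions with
    and without phylogenetic independent contrasts. Includes seeded simulators
    for spidroin families (duplication, gene conversion, slipped-strand
    mispairing), biased read sets, Brownian-motion traits, and noisy tensile
    traces, each shipping ground-truth logs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
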