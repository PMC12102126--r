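Package: ibdlocus
Title: Fast Exact Simulation of Identity-by-Descent Segments Around a Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the lengths of identity-by-descent (IBD) haplotype
    segments overlapping a single focal locus for large diploid samples. A
    hybrid discrete Wright-Fisher / Kingman coalescent engine generates pair
    coalescence events under piecewise-exponential demographies and hard
    selective sweeps (structured coalescent with allele-specific population
    sizes); per-branch exponential crossover distances define segment
    endpoints; pruning of undetectable haplotype records and merging of
    records with identical endpoints make runtime scale approximately
    linearly in sample size without changing the simulated segment set.
    Closed-form coalescent and recombination quantities are provided for
    validation and study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
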