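Package: surfload
Title: Expansion Load, Selection Efficacy and Allele Surfing from Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the genetic load carried by populations along a
    range expansion. Polarizes variants against outgroup panels, computes
    piN/piS over concatenated gene-space windows and GC3 bins, counts additive
    and recessive deleterious alleles per individual, estimates the
    distribution of fitness effects (gamma deleterious plus exponential
    beneficial) from unfolded site-frequency spectra by Poisson random field
    maximum likelihood, and derives alpha, omegaA and omegaNA from observed
    divergence. Includes classical population statistics (Ho, betaST,
    Tajima's D, Weir-Cockerham FST, LD decay, FST-based population trees),
    contrasts between diploid chromosomes and regions of residual tetraploidy,
    and a forward Wright-Fisher stepping-stone simulator of serial founder
    expansions with partially recessive deleterious mutations for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stringr,
    vcfR,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    generics,
    withr,
    pracma,
    methods,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
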