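Package: mitobottleneck
Title: Somatic Mitochondrial DNA Bottleneck Inference from Single-Cell Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the somatic mitochondrial DNA (mtDNA) genetic bottleneck in
    lymphocyte development from per-cell, strand-resolved allele-count tables.
    Provides a synthetic single-cell cohort generator with planted ground truth, a
    five-step somatic-variant filter cascade (germline removal, homopolymer and
    damage-substitution blacklists, depth/alt-read/strand-balance confidence
    filters, per-cell VAF recounting, cell-depth filtering), variant-allele-frequency
    spectrum statistics, a Wright-Fisher forward simulator of heteroplasmy dynamics
    under a dilution bottleneck, rejection-sampling approximate Bayesian computation
    (ABC) for bottleneck-size inference with mutation-rate model selection, and
    dN/dS selection statistics under the vertebrate mitochondrial genetic code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
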