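Package: periclinal
Title: Layer-Resolved Somatic Mutation Analysis for Clonal Polyploid Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify somatic mutations of clonally propagated
    polyploid plants to their shoot-apical-meristem layer of origin
    (epidermal L1 versus the homogenized L2,3 compartment) from
    multi-tissue and regenerant-panel read counts, to estimate
    callable-site-normalized mutation rates by genomic space, to compute
    and contrast single-base-substitution spectra, and to assign the
    layer of origin of regenerants from haplotype-marker read dosage.
    Includes a fully labeled synthetic tetraploid clone simulator so the
    whole pipeline is testable end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    tidyr,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
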