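Package: poolmap
Title: Mapping-by-Sequencing of Recessive Mutations from Pooled Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bulk segregant analysis of pooled whole-exome sequencing data
    for recessive mutation mapping in model-organism intercrosses. Joins
    variant calls from a pool of affected offspring and their carrier
    parents, applies coverage and shared-homozygosity filters, computes the
    absolute allele-frequency-difference statistic per locus, builds
    position-by-difference density maps, calls candidate linkage regions
    with a sliding-window scan, and classifies region variants by
    protein-level consequence with control-panel exclusion. Includes a
    forward simulator of an F2 intercross of two heterozygous carriers
    (Haldane meiosis, phenotype-selected pooling, binomial read sampling)
    that provides ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
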