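Package: stressmir
Title: Small RNA Discovery and Stress-Response miRNA Analysis for Non-Model Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a classic three-library (control,
    drought, salt) plant small-RNA workflow for species without a finished
    genome: adapter trimming and quality cleaning of small-RNA libraries, read
    collapsing and categorization against contaminant and known-miRNA catalogs,
    top-N Jaccard library similarity, hairpin-based discovery of conserved and
    novel miRNA loci (base-pair-maximization folding with miRNA/miRNA* duplex
    geometry checks), reads-per-million normalization with Pearson chi-squared
    two-tier differential-expression calls, plant-style miRNA target
    prediction with degradome (PARE) cleavage-site validation, and a
    PageRank-style CitationRank over a gene-document corpus. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
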