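Package: denovotrio
Title: De Novo Mutation Discovery and Rate Estimation from Parent-Offspring
    Trio Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies Mendelian inheritance errors (MIEs) in
    deep whole-genome sequencing of a parent-offspring trio, separating
    germline de novo single-nucleotide variants from copy-number-neutral
    inherited variants (allelic gene conversion), hemizygous-deletion
    inherited variants, and de novo copy-number variants by strand-resolved
    read evidence and pairwise read-depth comparison. Builds high-confidence
    target regions with depth, strand-balance, indel-proximity, allele/strand
    bias and read-end filters; clusters conversion variants against a
    uniform-placement bootstrap null; assigns parental origin through
    read-pair linkage to informative heterozygous sites; and converts
    validated counts into false-positive-corrected per-generation and
    per-year mutation rates, including a phylogenetic-rate calculator with
    ancestral-polymorphism correction. A synthetic trio simulator with full
    ground truth makes every stage testable without sequencing data.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
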