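Package: mitomut
Title: Mitochondrial DNA Heteroplasmy Analysis for Mutator-Mouse Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mitochondrial DNA (mtDNA) point-mutation and indel
    frequencies from per-site allele-count tables, annotates heteroplasmic
    substitutions as synonymous or non-synonymous under the vertebrate
    mitochondrial genetic code, maps confirmed human pathogenic mtDNA
    mutations onto a second species' mitochondrial genome by per-gene
    pairwise alignment, and compares genotype groups with the Tukey-Kramer
    test. A forward simulator of maternal germline mutagenesis with
    bottleneck drift, organ-private somatic mutation, and sequencing error
    provides ground-truth cohorts for validating every pipeline stage, in
    the style of proofreading-deficient Polg ("mutator") mouse studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
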