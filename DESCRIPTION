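Package: simval
Title: Simulated Diploid Genomes with Encoded Ground Truth for Benchmarking
    Alignment and Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes phased diploid genomes carrying germline and somatic
    variants (SNVs, indels, deletions, insertions, inversions and tandem
    duplications), simulates paired-end reads whose true reference alignments
    are encoded in the read names via a block map between the perturbed genome
    and the reference, and validates the alignments (SAM/BAM) and variant
    calls (VCF) of any secondary-analysis pipeline, reporting sensitivity,
    precision and F1 stratified by variant type and size bin. Includes a
    tumor/normal workflow with read mixing to model normal contamination, and
    a synthetic fixture generator so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    methods,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
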