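Package: napcomp
Title: Comparison Toolkit for Closely Related Brassica napus Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for improving and comparing genome assemblies of closely
    related, homozygous crop cultivars. Places unplaced contigs into
    pseudomolecules by co-segregation of their SNP genotypes with anchored
    markers across a doubled-haploid population; sorts contigs by homology
    hits with an ambiguity rule for equally good cross-chromosome matches;
    detects collapsed and repetitive assembly regions from unique- versus
    all-placement read depth; calls gene presence/absence from exon coverage
    and expression presence from fragment counts; estimates genome and
    assembly size from k-mer multiplicity histograms; classifies genes by
    collinear-block membership; and generates synthetic benchmark data with
    known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
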