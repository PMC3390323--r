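Package: tagdge
Title: Digital Gene Expression Tag Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for NlaIII/MmeI digital gene expression
    (DGE) tag profiling. Extracts CATG-anchored 21-bp tags from reads,
    cleans them with the standard six filtering rules, maps them against a
    virtual CATG+17 tag library built from reference transcripts (allowing
    one mismatch, sense and antisense), normalizes unambiguous per-gene
    counts to transcripts per million clean tags (TPM), calls differential
    expression between tag libraries with the Audic-Claverie exact test
    under Benjamini-Hochberg false discovery rate control, performs
    hypergeometric GO/pathway enrichment, ranks candidate qPCR reference
    genes by geNorm expression stability, and computes potassium-efficiency
    phenotype screening indices. Includes a synthetic-data generator that
    emulates a two-genotype, two-tissue, two-period eight-library tag-seq
    experiment with planted differential expression, sequencing error,
    adaptor contamination, antisense transcription and organellar/genomic
    decoy tags, so the whole pipeline is testable without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
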