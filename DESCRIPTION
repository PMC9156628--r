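Package: haplosel
Title: Haploid Selection and Molecular Evolution in Haplodiploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how haploid-biased (male), diploid-biased
    (female), and constitutively expressed genes of haplodiploid species
    differ in polymorphism, divergence, selection, base composition, and
    recombination rate. Implements sex- and tissue-biased expression
    classification with FDR control, Nei-Gojobori (1986) synonymous and
    nonsynonymous site counting, per-gene nucleotide diversity and
    McDonald-Kreitman statistics including the Direction of Selection,
    Marey-map recombination-rate estimation, and a relaxed-selection null
    model for haplodiploid species that maps scaled selection coefficients
    to expected dN/dS. A synthetic-data generator produces calibrated
    count matrices, coding sequences, variant tables and linkage maps with
    known ground truth so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
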