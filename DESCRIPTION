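Package: recscreen
Title: Candidate-Gene Variant Screening Under a Recessive Model from mRNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the single-case candidate-gene
    mutation hunt used to find recessive disease mutations from mRNA-seq of an
    affected individual. Provides a seeded synthetic-data generator (toy genome
    with exon/CDS gene models, spliced paired-end reads with planted variants,
    fragment-analysis genotyping panels, qPCR plates), a toy spliced read mapper
    and pileup builder, pileup-based SNV/indel detection with indel
    left-normalization, coding-consequence annotation, a recessive-model
    exclusion cascade over candidate genes, frameshift protein consequence
    prediction with HGVS output, in-silico PCR, pedigree segregation and
    population carrier analysis, and efficiency-corrected relative-expression
    (Pfaffl-style) qPCR quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
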