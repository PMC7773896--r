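Package: bsasweep
Title: Bulked Segregant Analysis and Selective Sweep Scanning for Trait Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping qualitative traits from pooled resequencing of
    extreme-phenotype bulks (QTL-seq style bulked segregant analysis) and for
    screening domestication-type selective sweeps in population panels.
    Implements per-marker SNP/InDel indexes, sliding-window index and
    delta-index profiles, permutation-derived confidence bands, candidate
    region calling and intersection, windowed Hudson/Weir-Cockerham Fst and
    nucleotide diversity, per-site allele-frequency tracks, codon-level
    variant effect classification against GFF3 gene models, and
    expression-table utilities (row Z-scores, depth-normalised Student's
    t-tests). Includes seeded simulators for BC1 backcross bulk-sequencing
    designs and two-population genotype panels with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
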