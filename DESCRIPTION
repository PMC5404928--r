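Package: retromzt
Title: Transposable-Element Activation Analysis Across the Maternal-to-Zygotic
    Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying retrotransposon (transposable element, TE)
    activation during the mouse maternal-to-zygotic transition from single-cell
    and single-embryo RNA-seq alignments. Quantifies TE expression at the
    element, family and class levels of the RepeatMasker hierarchy under
    unique-only and one-random-alignment multi-mapping policies; measures
    multi-mapping assignment ambiguity across the hierarchy; detects chimeric
    TE-gene transcripts from split and translocated reads; assigns nine-class
    time-series expression dynamics across oocyte, 1-cell and 2-cell stages;
    builds thresholded co-expression networks; relates TE and gene expression
    through nearest-gene correlation, neighbourhood-overlap and TSS permutation
    enrichment tests; and scans siRNA sequences genome-wide with mismatch
    stratification. Ships a synthetic genome, annotation, count and alignment
    generator with full ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    withr
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
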