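Package: hsfchip
Title: Tiling-Array ChIP Peak, Motif and Expression Analysis for the Heat
    Shock Regulon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis toolkit for genome-wide HSF (heat shock
    factor) ChIP-chip and heat-shock expression studies. Calls bound
    chromatin segments from probe-level tiling-array enrichment statistics,
    assigns segment peaks, and filters against mock immunoprecipitations;
    scores heat shock elements (HSEs) and other motifs with position weight
    matrices using exact score-distribution p-values; tests positional
    motif enrichment around peaks with windowed histograms and
    center-versus-flank chi-square statistics, including nGAAn-unit
    orientation comparisons and scrambled-matrix controls; classifies
    binding sites against multi-isoform gene annotation
    (promoter/exon/intron/intergenic) and tests overlap with polytene
    cytology; and integrates differential-expression calls with binding via
    set intersections, distance summaries, contingency tests, hierarchical
    clustering and term enrichment. A seeded synthetic-study generator
    (genome, annotation, probes, ChIP signal, expression, cytology, with
    planted ground truth) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
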