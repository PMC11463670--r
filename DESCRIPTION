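Package: multiomePGC
Title: Single-Nucleus Multiome Analysis of Primordial Germ Cell Sex Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a single-nucleus RNA+ATAC multiome
    analysis workflow for primordial germ cell (PGC) sex determination in the
    fetal mouse gonad: per-cell quality control and marker-count cell triage,
    chromosomal-sex assignment from Y-linked module scores and chrY fragment
    counts, multimodal dimensionality reduction and clustering with MST
    pseudotime, Wilcoxon differential expression and accessibility, peak-to-gene
    linkage against GC- and accessibility-matched background peaks, motif
    scanning, enrichment and per-cell motif deviations, transcription-factor
    candidate triage into gene regulatory networks, and a permutation
    ligand-receptor test between supporting cells and PGCs. A synthetic multiome
    generator with planted ground truth (sexes, DEGs, peak-gene links, TF
    targets, ligand-receptor pairs) exercises the pipeline end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
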