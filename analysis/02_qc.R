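#!/usr/bin/env Rscript
# Stage 2: per-cell QC (RNA counts, mito %, ATAC counts, nucleosome signal,
# TSS enrichment), strict-threshold cell filtering, peak filtering, the
# marker-count cell-type triage, and mitochondrial feature removal.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("qc")
qc <- res$qc
cat(sprintf("Retained %d/%d cells after QC; triage: %d PGC, %d supporting, %d other, %d excluded.\n",
            length(qc$retained), nrow(qc$metrics),
            sum(qc$types$label == "PGC"), sum(qc$types$label == "supporting"),
            sum(qc$types$label == "other"), sum(qc$types$label == "excluded")))
cat("Tables: cell_metrics.tsv, cell_types.tsv, peaks_retained.bed\n")
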