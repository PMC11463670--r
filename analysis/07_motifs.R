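#!/usr/bin/env Rscript
# Stage 7: PWM scanning of all retained peaks (both strands, threshold 0.8 of
# the maximal log-odds), motif enrichment in DA peaks linked to DEGs against
# a matched background, and chromVAR-style per-cell motif deviations.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("motif")
enr <- res$motif$enrichment
cat(sprintf("Scanned %d motifs; %d enriched at p < 0.05 in %d foreground peaks.\n",
            nrow(enr), sum(enr$p < 0.05), length(res$motif$foreground)))
print(head(enr[, c("motif_id", "fg_hits", "bg_hits", "p", "fdr")], 8))
cat("Tables: motif_hits.tsv, motif_enrichment.tsv, motif_deviation_z.tsv\n")
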