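#!/usr/bin/env Rscript
# Stage 6: peak-to-gene linkage for the DE genes - Pearson correlation across
# cells against GC- and accessibility-matched background peaks, one-sided
# upper-tail p; links retained at p < 0.05 with z > 0.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("link")
lk <- res$link$links
cat(sprintf("Tested %d candidate pairs within 500 kb; retained %d links for %d DE genes.\n",
            nrow(lk), sum(lk$retained), length(unique(lk$gene_id[lk$retained]))))
cat("Table: links.tsv\n")
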