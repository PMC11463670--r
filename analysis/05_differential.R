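#!/usr/bin/env Rscript
# Stage 5: Wilcoxon differential testing between XX and XY PGCs per stage
# (genes: min.pct 0.25, log2FC 0.25; peaks: min.pct 0.001, log2FC 0.1; BH),
# the germline-vs-soma contrast, and peak feature annotation (TSS +/- 3 kb).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("de")
for (st in names(res$de$degs))
  cat(sprintf("%s: %d DEGs, %d DAPs (FDR < 0.05).\n", st,
              sum(res$de$degs[[st]]$significant),
              sum(res$de$daps[[st]]$significant)))
ann <- table(res$de$annotation$category)
cat("Peak features:", paste(names(ann), ann, sep = "=", collapse = ", "), "\n")
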