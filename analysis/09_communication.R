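#!/usr/bin/env Rscript
# Stage 9: permutation-based ligand-receptor analysis between supporting
# cells (sender) and PGCs (receiver) per sex and stage, with the
# minimum-subunit complex rule and 10% expression gate; counts and the
# XX-only / XY-only / shared partition per stage.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("comm")
cnt <- res$comm$counts
print(cnt$counts)
for (st in names(cnt$venn))
  cat(sprintf("%s: XX-only %d, XY-only %d, shared %d\n", st,
              cnt$venn[[st]]["XX_only"], cnt$venn[[st]]["XY_only"],
              cnt$venn[[st]]["shared"]))
cat("Tables: interactions.tsv, interaction_counts.tsv\n")
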