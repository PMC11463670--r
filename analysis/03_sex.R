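#!/usr/bin/env Rscript
# Stage 3: chromosomal-sex assignment from the Y-linked gene module score
# (Kdm5d/Eif2s3y/Uty/Ddx3y analogues) and fragment counts in chrY peaks
# (region 1-90 Mb), thresholded against the E13.5 reference libraries.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("sex")
calls <- res$sex$calls
cat(sprintf("Sex calls: %d XY, %d XX, %d ambiguous (removed). Cuts: male %.3f / female %.3f.\n",
            sum(calls$call == "XY"), sum(calls$call == "XX"),
            sum(calls$call == "ambiguous"),
            calls$male_cut[1], calls$female_cut[1]))
cat("Table: sex_calls.tsv\n")
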