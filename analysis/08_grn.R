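#!/usr/bin/env Rscript
# Stage 8: TF-candidate triage (sex-DE + germline-enriched + motif-enriched +
# positive motif activity) and assembly of the TF->target regulatory network
# from motif hits inside significant linked peaks; cross-regulation and
# coverage statistics.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("grn")
cand <- res$grn$candidates
net <- res$grn$network
cat(sprintf("%d of %d TFs pass all four criteria; %d network edges over %d target genes.\n",
            sum(cand$passes_all), nrow(cand), nrow(net$edges),
            length(unique(net$edges$target))))
print(res$grn$summary$per_tf)
cat("Tables: tf_candidates.tsv, network_edges.tsv, cross_regulation.tsv, network_summary.tsv\n")
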