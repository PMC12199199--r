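#!/usr/bin/env Rscript
# Stage 3 — RT-qPCR stability ranking of the candidate references.
#
# Simulates the RT-qPCR readout (Cq values affine in log2 abundance with
# per-assay noise) for the planted candidate references and ranks their
# stability with all four algorithms — comparative delta-Ct, BestKeeper,
# NormFinder, geNorm — aggregated into the comprehensive geometric-mean
# rank.

library(evref)

seed <- 1
cfg <- synthetic_config(seed = seed)
sim <- generate_expression(cfg)
cq <- generate_cq(sim$truth, cfg)[sim$truth$reference_genes, ]

st <- stability_suite(cq)
write_result_tsv(st$summary, "results/stability.tsv")

message("comprehensive stability ranking (most stable first):")
for (i in seq_len(nrow(st$summary)))
  message(sprintf("  %d. %-10s  deltaCt %.3f  BK-SD %.3f  NF %.3f  geNorm-M %.3f",
                  st$summary$comprehensive_rank[i], st$summary$gene_id[i],
                  st$summary$delta_ct_value[i], st$summary$bestkeeper_sd[i],
                  st$summary$normfinder_value[i], st$summary$genorm_m[i]))
message(sprintf("geNorm final surviving pair: %s",
                paste(st$genorm$final_pair, collapse = " + ")))

v <- genorm_pairwise_variation(cq)
write_result_tsv(v, "results/genorm_pairwise_variation.tsv")
message(sprintf("geNorm V(2/3) = %.3f (how much a third reference would change the normalization factor)",
                v$v[1]))
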