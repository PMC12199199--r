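#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic 12-source EV expression cohort (3
# replicates per source, 5000 genes, five planted high-abundance
# low-variance reference transcripts and one erratically expressed
# RAB13-like target) and writes it in the same TSV dialect a deposited
# replicate-level RPKM matrix would arrive in, so that every later stage
# reads files exactly as it would read external data.

library(evref)

seed <- 1
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
sim <- generate_expression(cfg)

utils::write.table(
  data.frame(gene_id = rownames(sim$matrix), unclass(sim$matrix),
             check.names = FALSE),
  file.path(out, "expression_rpkm.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$replicate_map, file.path(out, "replicate_map.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$annotation, file.path(out, "annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       reference_genes = sim$truth$reference_genes,
       variable_gene = sim$truth$variable_gene,
       fold_enrichment = sim$truth$fold_enrichment),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

message(sprintf(
  "simulated %d genes x %d samples (%d sources); planted references: %s; target: %s",
  nrow(sim$matrix), ncol(sim$matrix), length(unique(sim$replicate_map$source_id)),
  paste(sim$truth$reference_genes, collapse = ", "), sim$truth$variable_gene))
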