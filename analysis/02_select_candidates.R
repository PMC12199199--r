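#!/usr/bin/env Rscript
# Stage 2 — candidate reference-transcript selection.
#
# Reads the cohort files written by stage 1 and runs the selection chain:
# replicate zero-masking, source-averaging, per-source top-1000 abundance
# sets, the all-source intersection, rank-sum ordering, the 1000-RPKM
# robust-abundance filter in every source, and the protein-coding biotype
# filter. Reports how many transcripts each step retains.

library(evref)

cohort <- "results/cohort"
out <- "results"
sel <- reproduce_published_selection(
  file.path(cohort, "expression_rpkm.tsv"),
  file.path(cohort, "replicate_map.tsv"),
  file.path(cohort, "annotation.tsv"))

write_result_tsv(sel$candidate_set, file.path(out, "candidate_report.tsv"))
write_result_tsv(sel$shared$per_source, file.path(out, "shared_counts.tsv"))
write_result_tsv(utils::head(sel$rank_table, 50),
                 file.path(out, "rank_sum_top50.tsv"))

truth <- jsonlite::read_json(file.path(cohort, "truth.json"),
                             simplifyVector = TRUE)
message(sprintf("%d transcripts shared by all 12 sources' top-1000 sets",
                sel$shared$n_common))
message(sprintf("%d survive the rank-sum top-50 + RPKM>=1000 filter",
                sum(sel$candidate_set$passed_rpkm_threshold)))
message(sprintf("%d protein-coding final candidates", length(sel$candidates)))
message(sprintf("planted references recovered: %s",
                all(truth$reference_genes %in% sel$candidates)))

# the variable-target screen used by the later proof-of-concept stages
sv <- select_variable_target(sel$avg_matrix, exclude = sel$candidates)
write_result_tsv(utils::head(sv, 20), file.path(out, "variable_targets.tsv"))
message(sprintf("most rank-variable ubiquitous transcript: %s (rank SD %.2f)",
                sv$gene_id[1], sv$rank_sd[1]))
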