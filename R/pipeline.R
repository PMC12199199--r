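#' Run the candidate-selection stage on in-memory objects
#'
#' Fixed stage order: replicate zero-masking, source-averaging, per-source
#' top-N sets, cross-source intersection, rank-sum ordering, robust-
#' abundance filter, biotype filter. Masking precedes averaging so that
#' "no expression in any replicate" is equivalent to "source average is
#' 0" at selection time.
#'
#' @param matrix Replicate-level [expression_matrix()], unit `"rpkm"` (or
#'   `"counts"` together with `annotation` lengths, converted first).
#' @param replicate_map Sample-to-source map.
#' @param annotation Gene annotation (biotypes; lengths if counts given).
#' @param top_n Per-source abundance set size (default 1000).
#' @param top_k Rank-sum positions retained (default 50).
#' @param rpkm_threshold Robust-abundance cutoff (default 1000).
#' @param biotype_keep Biotypes retained by the final filter.
#' @param exclude_genes Genes excluded a priori (e.g. after manual
#'   transcript-coverage review).
#' @return List: `avg_matrix`, `top_sets`, `shared` (intersection
#'   summary), `rank_table`, `candidate_set`, `candidates` (final gene
#'   IDs).
#' @export
run_selection <- function(matrix, replicate_map, annotation,
                          top_n = 1000, top_k = 50, rpkm_threshold = 1000,
                          biotype_keep = "protein_coding",
                          exclude_genes = NULL) {
  if (identical(expression_unit(matrix), "counts"))
    matrix <- compute_rpkm(matrix, annotation)
  masked <- zero_mask(matrix, replicate_map)
  avg <- average_replicates(masked, replicate_map)
  sets <- top_n_sets(avg, n = top_n)
  shared <- intersection_summary(sets)
  tab <- rank_sum_order(avg)
  cand <- abundance_filter(tab, avg, shared$common_genes,
                           threshold = rpkm_threshold, top_k = top_k,
                           exclude = exclude_genes)
  cand <- biotype_filter(cand, annotation, keep = biotype_keep)
  list(avg_matrix = avg, top_sets = sets, shared = shared, rank_table = tab,
       candidate_set = cand, candidates = final_candidates(cand))
}

#' Reproduce the published candidate selection from deposited files
#'
#' Thin file-level driver over [run_selection()] for a deposited
#' replicate-level RPKM matrix: reads the expression TSV, replicate map
#' and annotation, then runs the full selection chain at the published
#' defaults (top 1000 per source, rank-sum top 50, 1000-RPKM robust
#' cutoff, protein-coding only).
#'
#' @param expression_tsv Path to the genes x samples RPKM TSV.
#' @param replicate_map_tsv Path to the sample-to-source TSV.
#' @param annotation_tsv Path to the gene annotation TSV.
#' @param ... Passed to [run_selection()] (e.g. `exclude_genes`).
#' @return As [run_selection()].
#' @export
reproduce_published_selection <- function(expression_tsv, replicate_map_tsv,
                                          annotation_tsv, ...) {
  m <- read_expression_tsv(expression_tsv, unit = "rpkm")
  map <- read_replicate_map(replicate_map_tsv)
  ann <- read_annotation_tsv(annotation_tsv)
  run_selection(m, map, ann, ...)
}

#' Pipeline configuration
#'
#' Collects all stage parameters at their standard defaults (top 1000 per
#' source, rank-sum top 50, 1000-RPKM robust cutoff, protein-coding
#' biotype policy) plus either input file paths or a synthetic-cohort
#' request.
#'
#' @param expression_tsv,replicate_map_tsv,annotation_tsv Input paths
#'   (ignored when `simulate = TRUE`).
#' @param simulate Generate the cohort with [generate_expression()]
#'   instead of reading files.
#' @param top_n,top_k,rpkm_threshold,biotype_keep,exclude_genes Selection
#'   parameters, see [run_selection()].
#' @param groups Optional per-sample group labels for NormFinder.
#' @param seed Seed for the synthetic cohort.
#' @param out_dir Output directory for result TSVs and the manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression_tsv = NULL, replicate_map_tsv = NULL,
                            annotation_tsv = NULL, simulate = is.null(expression_tsv),
                            top_n = 1000, top_k = 50, rpkm_threshold = 1000,
                            biotype_keep = "protein_coding", exclude_genes = NULL,
                            groups = NULL, seed = 1, out_dir = "evref-results") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline and write a consolidated report
#'
#' Executes, in fixed order: input acquisition (files or synthetic
#' cohort), candidate selection, Cq-based stability ranking of the final
#' candidates, proof-of-concept normalization of a variable target with
#' rank concordance against the expression-based normalization, and the
#' dPCR regression benchmark (the latter three stages run on synthetic
#' readouts when `simulate = TRUE`; with file inputs they require the
#' corresponding tables and are skipped when absent). Writes TSV results
#' and a machine-readable JSON manifest (parameters, package version,
#' seed, input checksums); identical configuration yields byte-identical
#' outputs. Progress is logged to standard error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[evref] ", sprintf(...))
  checksums <- list()

  if (config$simulate) {
    log_stage("simulate: generating synthetic cohort (seed %d)", config$seed)
    sim <- generate_expression(synthetic_config(seed = config$seed))
    m <- sim$matrix; map <- sim$replicate_map; ann <- sim$annotation
    groups <- stats::setNames(map$group_id, map$sample_id)
  } else {
    log_stage("expression_io: reading inputs")
    for (p in c(config$expression_tsv, config$replicate_map_tsv, config$annotation_tsv))
      if (is.null(p) || !file.exists(p))
        stop(sprintf("expression_io: required input missing: %s",
                     if (is.null(p)) "(unset path)" else p), call. = FALSE)
    m <- read_expression_tsv(config$expression_tsv, unit = "rpkm")
    map <- read_replicate_map(config$replicate_map_tsv)
    ann <- read_annotation_tsv(config$annotation_tsv)
    checksums <- as.list(tools::md5sum(c(config$expression_tsv,
                                         config$replicate_map_tsv,
                                         config$annotation_tsv)))
    sim <- NULL
    groups <- config$groups
  }

  log_stage("candidate_selection: top-%d sets, top-%d rank sums, RPKM >= %g",
            config$top_n, config$top_k, config$rpkm_threshold)
  sel <- run_selection(m, map, ann, top_n = config$top_n, top_k = config$top_k,
                       rpkm_threshold = config$rpkm_threshold,
                       biotype_keep = config$biotype_keep,
                       exclude_genes = config$exclude_genes)
  write_result_tsv(sel$candidate_set, file.path(config$out_dir, "candidate_report.tsv"))
  write_result_tsv(sel$shared$per_source, file.path(config$out_dir, "shared_counts.tsv"))

  stab <- norm <- bench <- NULL
  if (config$simulate) {
    log_stage("stability_suite: ranking %d candidates", length(sel$candidates))
    cq <- generate_cq(sim$truth, synthetic_config(seed = config$seed))
    src_groups <- stats::setNames(map$group_id[!duplicated(map$source_id)],
                                  unique(map$source_id))
    stab <- stability_suite(cq[setdiff(rownames(cq), sim$truth$variable_gene), ,
                               drop = FALSE],
                            groups = NULL)
    write_result_tsv(stab$summary, file.path(config$out_dir, "stability.tsv"))

    log_stage("normalization_benchmark: target %s", sim$truth$variable_gene)
    best_ref <- stab$summary$gene_id[1]
    a <- delta_cq_normalize(cq, sim$truth$variable_gene, best_ref)
    b <- expression_ratio_normalize(sel$avg_matrix, sim$truth$variable_gene, best_ref)
    norm <- rank_concordance(a, b)
    write_result_tsv(norm$ranks, file.path(config$out_dir, "concordance_ranks.tsv"))

    dp <- generate_dpcr(sim$truth, synthetic_config(seed = config$seed),
                        reference = best_ref)
    fit <- dpcr_regression(dp$copies_per_ul, dp$rel_value)
    bench <- c(fit, enrichment = estimate_enrichment(dp))
    write_result_tsv(data.frame(slope = fit$slope, intercept = fit$intercept,
                                r_squared = fit$r_squared, n = fit$n,
                                enrichment = bench$enrichment),
                     file.path(config$out_dir, "dpcr_benchmark.tsv"))
  }

  manifest <- list(
    package = "evref",
    version = as.character(utils::packageVersion("evref")),
    parameters = config[c("top_n", "top_k", "rpkm_threshold", "biotype_keep",
                          "seed", "simulate")],
    exclude_genes = config$exclude_genes,
    input_md5 = checksums,
    n_candidates = length(sel$candidates),
    candidates = sel$candidates)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done: %d final candidates", length(sel$candidates))
  invisible(list(selection = sel, stability = stab, concordance = norm,
                 benchmark = bench, manifest = manifest))
}

#' Published high-abundance EV candidate transcripts
#'
#' Curated table of the eleven rank-sum-ordered transcripts shared by EVs
#' from twelve cultured cell sources with averaged RPKM >= 1000 in every
#' source, together with their biotype classifications. Used by the
#' worked example: applying the
#' biotype filter to this table yields the seven protein-coding candidate
#' reference transcripts.
#'
#' @return Data.frame: `rank_sum_order`, `gene_id` (ENSEMBL), `gene_symbol`,
#'   `gene_name`, `classification`, `biotype` (the classification mapped
#'   onto the package vocabulary).
#' @export
ev_candidate_table <- function() {
  path <- system.file("extdata", "ev_candidate_transcripts.tsv",
                      package = "evref", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  map <- c("Protein-coding" = "protein_coding", "Pseudogene" = "pseudogene",
           "lncRNA" = "lncRNA", "scRNA" = "scRNA",
           "Mitochondrial" = "mitochondrial")
  df$biotype <- unname(map[df$classification])
  df
}
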