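#' Per-source top-N most abundant gene sets
#'
#' For each source column of a source-averaged RPKM matrix, returns the `n`
#' genes with the largest abundance. Ties at the boundary are broken
#' deterministically by lexical gene-ID order, so results are reproducible
#' across platforms. Genes with zero abundance are never included: a source
#' with fewer than `n` positively expressed genes is a hard error.
#'
#' @param avg_matrix Source-averaged expression matrix, unit `"rpkm"`.
#' @param n Set size (default 1000).
#' @return Named list of character vectors, one per source.
#' @export
top_n_sets <- function(avg_matrix, n = 1000) {
  .require_unit(avg_matrix, "rpkm")
  if (n > nrow(avg_matrix))
    stop("n exceeds the number of genes", call. = FALSE)
  ids <- rownames(avg_matrix)
  lex <- order(ids)
  sets <- lapply(colnames(avg_matrix), function(src) {
    v <- avg_matrix[lex, src]
    npos <- sum(v > 0)
    if (n > npos)
      stop(sprintf("source '%s' has only %d genes with positive abundance (< n = %d)",
                   src, npos, n), call. = FALSE)
    ids[lex][order(-v)[seq_len(n)]]
  })
  names(sets) <- colnames(avg_matrix)
  sets
}

#' Summarise the intersection structure of per-source gene sets
#'
#' Counts the genes common to all sets, and per source the genes unique to
#' it and those shared with some but not all other sources. For equally
#' sized, untruncated sets, `n_common + partial + unique` equals the set
#' size in every source.
#'
#' @param sets Named list of gene-ID character vectors (at least two).
#' @return List with `n_common`, the character vector `common_genes`, and a
#'   data.frame `per_source` with columns `source`, `n`, `unique`,
#'   `partial`.
#' @export
intersection_summary <- function(sets) {
  if (length(sets) < 2)
    stop("need at least two sets", call. = FALSE)
  common <- Reduce(intersect, sets)
  per_source <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    others <- unique(unlist(sets[-i]))
    uniq <- sum(!s %in% others)
    data.frame(source = names(sets)[i], n = length(s), unique = uniq,
               partial = length(s) - length(common) - uniq,
               stringsAsFactors = FALSE)
  }))
  list(n_common = length(common), common_genes = sort(common),
       per_source = per_source)
}

# Within-source ordinal abundance ranks (1 = most abundant), ties broken by
# lexical gene ID so rank sums are integers and platform-stable.
.source_ranks <- function(avg_matrix) {
  ids <- rownames(avg_matrix)
  lex <- order(ids)
  r <- apply(avg_matrix[lex, , drop = FALSE], 2,
             function(v) rank(-v, ties.method = "first"))
  rownames(r) <- ids[lex]
  r[ids, , drop = FALSE]
}

#' Rank-sum ordering of genes by cross-source abundance
#'
#' Within each source, genes are ranked by averaged abundance (rank 1 =
#' most abundant, ordinal ranks with lexical tie-break); per-gene ranks are
#' summed across sources and genes ordered ascending by the sum, so a low
#' rank sum marks a consistently abundant gene. The ordering depends only
#' on within-source order, hence is invariant under any strictly
#' increasing per-source transform of abundance.
#'
#' @param avg_matrix Source-averaged expression matrix, unit `"rpkm"`.
#' @return Data.frame ordered by ascending `rank_sum` (then lexical gene
#'   ID): `gene_id`, one `rank.<source>` column per source, `rank_sum`,
#'   `order_index`.
#' @export
rank_sum_order <- function(avg_matrix) {
  .require_unit(avg_matrix, "rpkm")
  r <- .source_ranks(avg_matrix)
  rs <- rowSums(r)
  ord <- order(rs, rownames(r))
  out <- data.frame(gene_id = rownames(r)[ord], stringsAsFactors = FALSE)
  ranks <- r[ord, , drop = FALSE]
  colnames(ranks) <- paste0("rank.", colnames(ranks))
  out <- cbind(out, as.data.frame(ranks, row.names = NULL))
  out$rank_sum <- as.integer(rs[ord])
  out$order_index <- seq_len(nrow(out))
  out
}

#' Robust-abundance filter on the shared, top-ranked genes
#'
#' Starting from the genes shared by all sources' top-N sets, keeps those
#' within the first `top_k` positions of the rank-sum ordering and flags
#' which of them have averaged RPKM at or above `threshold` in *every*
#' source — a single below-threshold source excludes the gene. The
#' rank-sum ordering restricted to the shared set is the primary ordering;
#' the gene's position in the unrestricted ordering is reported alongside.
#'
#' @param rank_table Output of [rank_sum_order()].
#' @param avg_matrix The matrix the table was computed from.
#' @param shared Character vector of genes shared by all sources
#'   (`intersection_summary()$common_genes`).
#' @param threshold RPKM cutoff (default 1000).
#' @param top_k Number of top rank-sum positions retained (default 50).
#' @param exclude Optional character vector of genes to drop a priori
#'   (e.g. candidates disqualified by manual transcript-coverage review).
#' @return A candidate-set data.frame (rows = shared genes in restricted
#'   rank-sum order) with columns `gene_id`, `shared_order`,
#'   `global_order`, `rank_sum`, `min_rpkm`, `passed_top50`,
#'   `passed_rpkm_threshold`, plus attributes `threshold` and `top_k`.
#'   Empty survivor sets are returned (with a warning), not an error.
#' @export
abundance_filter <- function(rank_table, avg_matrix, shared,
                             threshold = 1000, top_k = 50, exclude = NULL) {
  if (!all(shared %in% rank_table$gene_id))
    stop("rank table and shared set disagree on the gene universe", call. = FALSE)
  shared <- setdiff(shared, exclude)
  tab <- rank_table[rank_table$gene_id %in% shared, , drop = FALSE]
  out <- data.frame(gene_id = tab$gene_id,
                    shared_order = seq_len(nrow(tab)),
                    global_order = tab$order_index,
                    rank_sum = tab$rank_sum,
                    min_rpkm = apply(avg_matrix[tab$gene_id, , drop = FALSE], 1, min),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$passed_top50 <- out$shared_order <= top_k
  out$passed_rpkm_threshold <- out$passed_top50 & out$min_rpkm >= threshold
  if (!any(out$passed_rpkm_threshold))
    warning("no gene passed the robust-abundance filter", call. = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "top_k") <- top_k
  out
}

#' Biotype filter: retain protein-coding candidates
#'
#' Adds a `passed_biotype` flag: a gene passes only if it already passed
#' the robust-abundance filter *and* is annotated `protein_coding` —
#' non-coding RNAs, pseudogenes and mitochondrial transcripts are poor
#' RT-qPCR normalizers (no poly(A) capture, multi-copy loci, variable
#' mitochondrial load).
#'
#' @param candidate_set Output of [abundance_filter()].
#' @param annotation Annotation data.frame with `gene_id` and `biotype`.
#' @param keep Biotypes to retain (default `"protein_coding"`).
#' @return The candidate set with `biotype` and `passed_biotype` columns.
#' @export
biotype_filter <- function(candidate_set, annotation, keep = "protein_coding") {
  bt <- annotation$biotype[match(candidate_set$gene_id, annotation$gene_id)]
  unknown <- candidate_set$gene_id[is.na(bt)]
  if (length(unknown))
    stop(sprintf("biotype unknown for: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  candidate_set$biotype <- bt
  candidate_set$passed_biotype <- candidate_set$passed_rpkm_threshold & bt %in% keep
  candidate_set
}

#' Final candidate gene IDs of a candidate set
#'
#' @param candidate_set Candidate set with a `passed_biotype` column.
#' @return Character vector of surviving gene IDs, in candidate-set order.
#' @export
final_candidates <- function(candidate_set) {
  if (is.null(candidate_set$passed_biotype))
    stop("run biotype_filter() first", call. = FALSE)
  candidate_set$gene_id[candidate_set$passed_biotype]
}

#' Check membership of query genes in the rank-sum top k
#'
#' Used to ask whether previously selected reference transcripts are still
#' among the most abundant transcripts of an independent cohort (e.g.
#' biofluid-derived EVs). Genes absent from the matrix are reported as
#' non-members and flagged.
#'
#' @param avg_matrix Source-averaged expression matrix, unit `"rpkm"`.
#' @param query_genes Character vector of gene IDs to look up.
#' @param top_k Membership boundary (default 50).
#' @return Data.frame: `gene_id`, `present`, `order_index` (NA when
#'   absent), `member`.
#' @export
membership_check <- function(avg_matrix, query_genes, top_k = 50) {
  tab <- rank_sum_order(avg_matrix)
  idx <- tab$order_index[match(query_genes, tab$gene_id)]
  data.frame(gene_id = query_genes,
             present = query_genes %in% tab$gene_id,
             order_index = idx,
             member = !is.na(idx) & idx <= top_k,
             stringsAsFactors = FALSE)
}

#' Rank genes by cross-source rank variability
#'
#' Scores each gene expressed in all sources by the standard deviation of
#' its per-source abundance ranks, descending — a screen for a
#' proof-of-concept normalization target: a transcript present everywhere
#' but erratic in relative abundance, the opposite profile of a reference
#' gene.
#'
#' @param avg_matrix Source-averaged expression matrix, unit `"rpkm"`.
#' @param exclude Genes to omit (e.g. the reference candidates themselves).
#' @return Data.frame ordered by descending `rank_sd`: `gene_id`,
#'   `rank_sd`, `rank_sum`.
#' @export
select_variable_target <- function(avg_matrix, exclude = NULL) {
  .require_unit(avg_matrix, "rpkm")
  r <- .source_ranks(avg_matrix)
  keep <- rowSums(avg_matrix > 0) == ncol(avg_matrix) & !rownames(r) %in% exclude
  r <- r[keep, , drop = FALSE]
  sds <- apply(r, 1, stats::sd)
  ord <- order(-sds, rownames(r))
  data.frame(gene_id = rownames(r)[ord], rank_sd = sds[ord],
             rank_sum = as.integer(rowSums(r)[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}
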