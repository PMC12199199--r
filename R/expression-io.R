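#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `"unit"` attribute, either `"counts"` (raw read
#' counts) or `"rpkm"` (Reads Per Kilobase of transcript per Million mapped
#' reads). All abundance-based selection steps require RPKM, so the unit is
#' validated before any selection operation runs.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene IDs,
#'   ENSEMBL-style) and colnames (sample IDs). All values must be finite and
#'   non-negative.
#' @param unit `"counts"` or `"rpkm"`.
#' @return The matrix with its `"unit"` attribute set.
#' @export
expression_matrix <- function(values, unit = c("counts", "rpkm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene IDs (rownames) must be present and unique", call. = FALSE)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample IDs (colnames) must be present and unique", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("expression values must all be non-negative", call. = FALSE)
  attr(values, "unit") <- unit
  values
}

#' @rdname expression_matrix
#' @param x An expression matrix.
#' @export
expression_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("matrix carries no unit attribute; build it with expression_matrix()",
                       call. = FALSE)
  u
}

.require_unit <- function(x, unit) {
  if (!identical(expression_unit(x), unit))
    stop(sprintf("this operation requires a matrix in '%s' units (got '%s')",
                 unit, expression_unit(x)), call. = FALSE)
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows with the gene ID in the first column and a header
#' row of sample IDs.
#'
#' @param path Path to a tab-separated file.
#' @param unit Unit of the stored values, `"counts"` or `"rpkm"`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, unit = c("counts", "rpkm")) {
  unit <- match.arg(unit)
  if (!file.exists(path))
    stop(sprintf("expression matrix file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, unit)
}

#' Read a sample-to-source replicate map from TSV
#'
#' Two columns (`sample_id`, `source_id`), optional third (`group_id`, a
#' coarser category such as tissue of origin). Validated against a matrix
#' with [validate_replicate_map()].
#'
#' @param path Path to a tab-separated file with a header.
#' @return A data.frame with columns `sample_id`, `source_id` and, when
#'   present in the file, `group_id`.
#' @export
read_replicate_map <- function(path) {
  if (!file.exists(path))
    stop(sprintf("replicate map file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("replicate map needs at least columns sample_id and source_id", call. = FALSE)
  names(df)[1:2] <- c("sample_id", "source_id")
  if (ncol(df) >= 3) names(df)[3] <- "group_id"
  df
}

#' Validate a replicate map against an expression matrix
#'
#' Every sample of the matrix must appear exactly once in the map and every
#' source must own at least one replicate.
#'
#' @param matrix An expression matrix.
#' @param replicate_map Data.frame with `sample_id` and `source_id` columns.
#' @return The map, invisibly, with sources in first-appearance order.
#' @export
validate_replicate_map <- function(matrix, replicate_map) {
  if (anyDuplicated(replicate_map$sample_id))
    stop("replicate map lists a sample more than once", call. = FALSE)
  missing <- setdiff(colnames(matrix), replicate_map$sample_id)
  if (length(missing))
    stop(sprintf("samples absent from replicate map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(replicate_map$sample_id, colnames(matrix))
  if (length(extra))
    stop(sprintf("replicate map lists unknown samples: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible(replicate_map)
}

#' Read gene annotation from TSV
#'
#' Four columns: `gene_id`, `gene_symbol`, `biotype`, `length_bp`. Biotype
#' must be one of `protein_coding`, `pseudogene`, `lncRNA`, `scRNA`,
#' `mitochondrial`, `other`.
#'
#' @param path Path to a tab-separated file with a header.
#' @return Data.frame with the four columns above.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_symbol", "biotype", "length_bp")
  if (!all(need %in% names(df)))
    stop(sprintf("annotation must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  df$length_bp <- as.integer(df$length_bp)
  if (any(!is.na(df$length_bp) & df$length_bp <= 0))
    stop("length_bp must be positive where present", call. = FALSE)
  bad <- setdiff(unique(df$biotype), biotype_levels())
  if (length(bad))
    stop(sprintf("unknown biotypes: %s", paste(bad, collapse = ", ")), call. = FALSE)
  df[, need]
}

#' @rdname read_annotation_tsv
#' @export
biotype_levels <- function() {
  c("protein_coding", "pseudogene", "lncRNA", "scRNA", "mitochondrial", "other")
}

#' Read gene annotation from a GTF file
#'
#' Biotype is taken from the `gene_biotype` (or `gene_type`) attribute and
#' mapped onto the package's biotype vocabulary; genes on the mitochondrial
#' chromosome (`MT`/`chrM`) are classified `mitochondrial`. Gene length is
#' the sum of merged exon spans of the longest annotated transcript — RPKM
#' only needs a consistent length convention, and this one matches what
#' transcript-model-aware counters report for dominant isoforms.
#'
#' @param path Path to a GTF file.
#' @return Data.frame as from [read_annotation_tsv()].
#' @export
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF annotation requires the rtracklayer package", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  bt_col <- intersect(c("gene_biotype", "gene_type"), names(md))[1]
  if (is.na(bt_col))
    stop("GTF lacks a gene_biotype/gene_type attribute", call. = FALSE)
  ex <- md[md$type == "exon" & !is.na(md$transcript_id), , drop = FALSE]
  if (!nrow(ex)) stop("GTF contains no exon records", call. = FALSE)
  # merged exon span per transcript, then the longest transcript per gene
  tx_len <- vapply(split(ex, ex$transcript_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    sum(IRanges::width(ir))
  }, numeric(1))
  tx2gene <- vapply(split(ex$gene_id, ex$transcript_id), `[`, character(1), 1)
  gene_len <- tapply(tx_len, tx2gene, max)
  genes <- md[md$type == "gene", , drop = FALSE]
  if (!nrow(genes)) genes <- ex[!duplicated(ex$gene_id), , drop = FALSE]
  bt <- .map_gtf_biotype(genes[[bt_col]], as.character(genes$seqnames))
  sym <- if ("gene_name" %in% names(genes)) genes$gene_name else genes$gene_id
  data.frame(gene_id = genes$gene_id,
             gene_symbol = sym,
             biotype = bt,
             length_bp = as.integer(gene_len[genes$gene_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

.map_gtf_biotype <- function(bt, chrom) {
  out <- rep("other", length(bt))
  out[bt == "protein_coding"] <- "protein_coding"
  out[grepl("pseudogene", bt)] <- "pseudogene"
  out[bt %in% c("lncRNA", "lincRNA", "antisense")] <- "lncRNA"
  out[bt %in% c("scRNA")] <- "scRNA"
  out[bt %in% c("Mt_rRNA", "Mt_tRNA") | chrom %in% c("MT", "chrM", "chrMT")] <- "mitochondrial"
  out
}

#' Compute RPKM from raw counts
#'
#' `RPKM(g, s) = count(g, s) * 1e9 / (length_bp(g) * total_counts(s))`,
#' with the library size taken as the column sum of the provided count
#' matrix. The transform is exactly invertible given lengths and totals.
#'
#' @param counts An [expression_matrix()] with unit `"counts"`.
#' @param annotation Gene annotation data.frame providing `length_bp` for
#'   every gene in `counts`.
#' @return An expression matrix with unit `"rpkm"`.
#' @export
compute_rpkm <- function(counts, annotation) {
  .require_unit(counts, "counts")
  len <- annotation$length_bp[match(rownames(counts), annotation$gene_id)]
  bad <- rownames(counts)[is.na(len) | len <= 0]
  if (length(bad))
    stop(sprintf("missing or invalid gene length for: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop(sprintf("all-zero sample column(s): %s",
                 paste(colnames(counts)[totals == 0], collapse = ", ")), call. = FALSE)
  rpkm <- counts * 1e9 / outer(len, totals)
  expression_matrix(rpkm, "rpkm")
}

#' Zero-mask genes with missing expression in any replicate
#'
#' Within each biological source, a gene observed at zero in at least one
#' replicate is set to zero in all replicates of that source. After
#' source-averaging, such a gene averages to 0 there and can never pass an
#' abundance filter — "no expression in any replicate" becomes equivalent
#' to "source average is 0". The operation is idempotent.
#'
#' @param matrix An expression matrix with replicate columns.
#' @param replicate_map Sample-to-source map (see [read_replicate_map()]).
#' @return The masked matrix, same shape and unit.
#' @export
zero_mask <- function(matrix, replicate_map) {
  validate_replicate_map(matrix, replicate_map)
  out <- matrix
  for (src in unique(replicate_map$source_id)) {
    cols <- replicate_map$sample_id[replicate_map$source_id == src]
    sub <- out[, cols, drop = FALSE]
    hit <- rowSums(sub == 0) > 0
    out[hit, cols] <- 0
  }
  attr(out, "unit") <- expression_unit(matrix)
  out
}

#' Average replicates into one column per source
#'
#' Arithmetic mean over each source's replicates; intended to run after
#' [zero_mask()] so that masked genes average to exactly 0.
#'
#' @inheritParams zero_mask
#' @return An expression matrix with one column per source, sources in
#'   first-appearance order of the map.
#' @export
average_replicates <- function(matrix, replicate_map) {
  validate_replicate_map(matrix, replicate_map)
  sources <- unique(replicate_map$source_id)
  avg <- vapply(sources, function(src) {
    cols <- replicate_map$sample_id[replicate_map$source_id == src]
    if (!length(cols))
      stop(sprintf("source '%s' has no samples", src), call. = FALSE)
    rowMeans(matrix[, cols, drop = FALSE])
  }, numeric(nrow(matrix)))
  dimnames(avg) <- list(rownames(matrix), sources)
  expression_matrix(avg, expression_unit(matrix))
}

#' Write a result table as TSV
#'
#' All writers emit a header row; floating-point columns are formatted at 6
#' significant digits.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
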