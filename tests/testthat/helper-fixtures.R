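# Shared toy fixtures built in code.

# 4 genes x 2 sources x 2 replicates, values chosen so gene G3 is zero in
# one replicate of source A only.
toy_replicate_bundle <- function() {
  m <- matrix(c(
    # A_R1  A_R2  B_R1  B_R2
    100,  120,   80,   90,   # G1 robust everywhere
    5,      7,    6,    4,   # G2 low but present
    5,      0,    7,    9,   # G3 dropout in source A
    0,      0,    3,    2),  # G4 absent from source A
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("G", 1:4), c("A_R1", "A_R2", "B_R1", "B_R2")))
  list(matrix = expression_matrix(m, "rpkm"),
       map = data.frame(sample_id = colnames(m),
                        source_id = rep(c("A", "B"), each = 2),
                        stringsAsFactors = FALSE))
}

toy_annotation <- function(gene_ids, biotypes, lengths = 1000L) {
  data.frame(gene_id = gene_ids, gene_symbol = gene_ids,
             biotype = biotypes,
             length_bp = as.integer(rep_len(lengths, length(gene_ids))),
             stringsAsFactors = FALSE)
}

# source-averaged rpkm matrix from explicit values
avg_matrix_fixture <- function(values, genes, sources) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, sources))
  expression_matrix(m, "rpkm")
}
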