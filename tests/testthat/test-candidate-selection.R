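test_that("top_n_sets returns the n most abundant genes per source", {
  avg <- avg_matrix_fixture(c(10, 1,
                              50, 5,
                              40, 80,
                              30, 60,
                              20, 90), paste0("g", 1:5), c("A", "B"))
  sets <- top_n_sets(avg, n = 2)
  # brute-force sort oracle
  for (src in colnames(avg)) {
    v <- avg[, src]
    expect_setequal(sets[[src]], names(sort(v, decreasing = TRUE))[1:2])
  }
  # n = n_genes with all-positive abundance returns the full universe
  expect_setequal(top_n_sets(avg, n = 5)[["A"]], rownames(avg))
})

test_that("top_n boundary ties resolve by lexical gene ID and zeros error", {
  avg <- avg_matrix_fixture(c(9, 9,
                              5, 5,
                              5, 5,
                              0, 1), c("gA", "gC", "gB", "gD"), c("S1", "S2"))
  sets <- top_n_sets(avg, n = 2)
  # gB and gC tie at 5; lexical order admits gB
  expect_identical(sets[["S1"]], c("gA", "gB"))
  # a source with too few positive genes is a hard error naming it
  expect_error(top_n_sets(avg, n = 4), "S1")
})

test_that("intersection_summary decomposes sets into common/partial/unique", {
  sets <- list(s1 = c("a", "b", "c"), s2 = c("a", "b", "d"),
               s3 = c("a", "e", "f"))
  sh <- intersection_summary(sets)
  expect_equal(sh$n_common, 1)
  expect_equal(sh$common_genes, "a")
  expect_equal(sh$per_source$unique, c(1, 1, 2))
  expect_equal(sh$per_source$partial, c(1, 1, 0))
  # identical sets: everything common
  same <- list(x = letters[1:4], y = letters[1:4])
  expect_equal(intersection_summary(same)$n_common, 4)
  expect_equal(intersection_summary(same)$per_source$unique, c(0, 0))
})

test_that("common + partial + unique equals the set size on random systems", {
  set.seed(11)
  for (i in 1:30) {
    universe <- sprintf("g%03d", 1:60)
    sets <- lapply(1:4, function(j) sample(universe, 20))
    names(sets) <- paste0("s", 1:4)
    sh <- intersection_summary(sets)
    expect_equal(sh$per_source$unique + sh$per_source$partial + sh$n_common,
                 rep(20, 4))
  }
})

test_that("rank_sum_order matches exhaustive ranking on a toy matrix", {
  avg <- avg_matrix_fixture(c(100, 10, 30,
                              50, 90, 20,
                              10, 50, 60), paste0("g", 1:3), c("A", "B", "C"))
  tab <- rank_sum_order(avg)
  # hand ranking: A: g1>g2>g3 ; B: g2>g3>g1 ; C: g3>g1>g2
  # rank sums: g1 = 1+3+2 = 6, g2 = 2+1+3 = 6, g3 = 3+2+1 = 6 -> lexical
  expect_equal(tab$rank_sum, c(6L, 6L, 6L))
  expect_equal(tab$gene_id, c("g1", "g2", "g3"))
  expect_equal(tab$order_index, 1:3)
  # single source: ordering is descending abundance
  one <- avg_matrix_fixture(c(5, 50, 20), paste0("g", 1:3), "A")
  expect_equal(rank_sum_order(one)$gene_id, c("g2", "g3", "g1"))
})

test_that("rank-sum ordering is invariant under increasing per-source transforms", {
  set.seed(13)
  for (i in 1:20) {
    avg <- expression_matrix(
      matrix(rexp(60, 1 / 50), 12,
             dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:5))),
      "rpkm")
    t1 <- rank_sum_order(avg)
    # per-source strictly increasing maps: power, scaling, softplus
    fs <- list(function(x) x^1.7, function(x) 3 * x + 1,
               function(x) log1p(x), function(x) exp(x / max(x)),
               function(x) x / (1 + x))
    warped <- sapply(seq_len(ncol(avg)), function(j)
      fs[[(j %% length(fs)) + 1]](avg[, j]))
    dimnames(warped) <- dimnames(avg)
    t2 <- rank_sum_order(expression_matrix(warped, "rpkm"))
    expect_identical(t2$gene_id, t1$gene_id)
    expect_identical(t2$rank_sum, t1$rank_sum)
  }
})

test_that("abundance_filter applies the shared/top-k/threshold triple filter", {
  genes <- sprintf("g%02d", 1:8)
  set.seed(5)
  vals <- matrix(runif(24, 1100, 5000), 8,
                 dimnames = list(genes, c("A", "B", "C")))
  vals["g03", "B"] <- 900      # below threshold in exactly one source
  vals["g07", ] <- c(5, 8, 2)  # low everywhere
  avg <- expression_matrix(vals, "rpkm")
  tab <- rank_sum_order(avg)
  shared <- genes[1:6]         # pretend g07, g08 missed one top-N set
  cand <- abundance_filter(tab, avg, shared, threshold = 1000, top_k = 4)
  expect_setequal(cand$gene_id, shared)
  # brute-force triple filter
  restricted <- tab$gene_id[tab$gene_id %in% shared][1:4]
  manual <- restricted[sapply(restricted, function(g) all(vals[g, ] >= 1000))]
  expect_setequal(cand$gene_id[cand$passed_rpkm_threshold], manual)
  expect_false("g03" %in% cand$gene_id[cand$passed_rpkm_threshold] &&
                 "g03" %in% restricted)
  # flag implication chain
  expect_true(all(!cand$passed_rpkm_threshold | cand$passed_top50))
  # survivors are a subset of the shared set
  expect_true(all(cand$gene_id[cand$passed_rpkm_threshold] %in% shared))
})

test_that("abundance_filter honours an a-priori exclusion list and may warn empty", {
  avg <- avg_matrix_fixture(c(2000, 3000,
                              1500, 1200), c("g1", "g2"), c("A", "B"))
  tab <- rank_sum_order(avg)
  cand <- abundance_filter(tab, avg, c("g1", "g2"), exclude = "g1")
  expect_false("g1" %in% cand$gene_id)
  expect_warning(abundance_filter(tab, avg, c("g1", "g2"), threshold = 1e6),
                 "no gene passed")
})

test_that("biotype_filter keeps protein-coding genes and demands annotation", {
  genes <- paste0("g", 1:6)
  cand <- data.frame(gene_id = genes, shared_order = 1:6, global_order = 1:6,
                     rank_sum = 1:6, min_rpkm = 2000,
                     passed_top50 = TRUE, passed_rpkm_threshold = TRUE,
                     stringsAsFactors = FALSE)
  ann <- toy_annotation(genes, c("protein_coding", "pseudogene", "lncRNA",
                                 "scRNA", "mitochondrial", "other"))
  out <- biotype_filter(cand, ann)
  expect_identical(final_candidates(out), "g1")
  expect_error(biotype_filter(cand, ann[-2, ]), "g2")
  # empty input stays empty
  empty <- biotype_filter(cand[0, ], ann)
  expect_equal(length(final_candidates(empty)), 0)
})

test_that("membership_check flags the top-k boundary and absent genes", {
  set.seed(21)
  avg <- expression_matrix(
    matrix(rexp(40, 1 / 100), 10,
           dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4))),
    "rpkm")
  tab <- rank_sum_order(avg)
  res <- membership_check(avg, c(tab$gene_id[1], tab$gene_id[6], "missing"),
                          top_k = 5)
  expect_equal(res$member, c(TRUE, FALSE, FALSE))
  expect_false(res$present[3])
  # brute-force top-k scan over all genes
  all_res <- membership_check(avg, rownames(avg), top_k = 5)
  expect_setequal(all_res$gene_id[all_res$member], tab$gene_id[1:5])
})

test_that("select_variable_target ranks genes by SD of per-source ranks", {
  # planted erratic gene: swings between extremes of the ordering
  avg <- avg_matrix_fixture(c(100, 100, 100,
                              90,  90,  90,
                              200,  1, 150,
                              80,  80,  80), paste0("g", 1:4), c("A", "B", "C"))
  sv <- select_variable_target(avg)
  expect_equal(sv$gene_id[1], "g3")
  # brute-force SD of ranks for the planted gene
  ranks <- apply(-avg, 2, rank, ties.method = "first")
  expect_equal(sv$rank_sd[1], oracle_sd(ranks["g3", ]), tolerance = 1e-12)
  expect_false("g3" %in% select_variable_target(avg, exclude = "g3")$gene_id)
  # degenerate case: identical per-source orderings give all-zero scores
  const <- avg_matrix_fixture(c(40, 400, 4,
                                30, 300, 3,
                                20, 200, 2), paste0("g", 1:3), c("A", "B", "C"))
  expect_true(all(select_variable_target(const)$rank_sd == 0))
})
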