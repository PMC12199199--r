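test_that("delta-Ct stability matches the exhaustive pairwise-SD oracle", {
  set.seed(101)
  cq <- random_cq_table(3, 4)
  res <- delta_ct_stability(cq)
  expect_equal(res$value, oracle_delta_ct(cq), tolerance = 1e-12)
  expect_equal(sort(res$rank), sort(rank(res$value)))
  expect_error(delta_ct_stability(cq[1:2, ]), "at least 3")
})

test_that("delta-Ct: constant-offset profiles contribute zero pairwise SD", {
  set.seed(5)
  base <- seq(20, 26, length.out = 6)
  cq <- rbind(g1 = base, g2 = base + 3, g3 = base + rnorm(6, 0, 0.5))
  res <- delta_ct_stability(cq)
  # g1 and g2 differ by a constant: their mutual term is 0, so both
  # values equal the SD against g3 divided evenly
  expect_equal(res$value[1], res$value[2], tolerance = 1e-12)
  expect_lt(res$value[1], res$value[3])
})

test_that("delta-Ct and geNorm shrug off per-sample shifts and scalings", {
  set.seed(7)
  for (i in 1:20) {
    cq <- random_cq_table(5, 8)
    shift <- rnorm(8, 0, 3)
    d1 <- delta_ct_stability(cq)
    d2 <- delta_ct_stability(sweep(cq, 2, shift, "+"))
    expect_equal(d2$value, d1$value, tolerance = 1e-9)
    q <- 2^(30 - cq)
    g1 <- genorm(q, input = "expression")
    g2 <- genorm(sweep(q, 2, 2^shift, "*"), input = "expression")
    expect_equal(g2$m_values$m, g1$m_values$m, tolerance = 1e-9)
    expect_identical(g2$exclusion_order, g1$exclusion_order)
  }
})

test_that("BestKeeper SD, CV and index correlation match brute force", {
  set.seed(33)
  cq <- random_cq_table(4, 5)
  res <- bestkeeper(cq)
  orc <- oracle_bestkeeper(cq)
  expect_equal(res$sd, unname(orc$sd), tolerance = 1e-12)
  expect_equal(res$cv, unname(orc$cv), tolerance = 1e-12)
  expect_equal(res$r, unname(orc$r), tolerance = 1e-12)
  # constant gene: SD 0, best rank, advisory flag acceptable
  cq2 <- rbind(cq, flat = rep(24, 5))
  res2 <- bestkeeper(cq2)
  expect_equal(res2$sd[res2$gene_id == "flat"], 0)
  expect_equal(res2$rank[res2$gene_id == "flat"], 1)
  # single-gene table: index is the gene's own profile, r = 1
  one <- bestkeeper(cq[1, , drop = FALSE])
  expect_equal(one$r, 1, tolerance = 1e-12)
  # constant index -> NA correlations with a warning
  flatall <- matrix(25, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_warning(resf <- bestkeeper(flatall), "zero variance")
  expect_true(all(is.na(resf$r)))
})

test_that("NormFinder: pure sample effects give zero stability for all genes", {
  sample_eff <- rnorm(6, 0, 2)
  cq <- outer(c(20, 23, 26, 28), rep(1, 6)) + outer(rep(1, 4), sample_eff)
  dimnames(cq) <- list(paste0("g", 1:4), paste0("s", 1:6))
  res <- normfinder(cq)
  expect_equal(res$value, rep(0, 4), tolerance = 1e-9)
})

test_that("NormFinder values equal the hand-assembled df-corrected estimator", {
  set.seed(55)
  cq <- random_cq_table(4, 6)
  res <- normfinder(cq)
  expect_equal(res$value, unname(oracle_normfinder(-cq)), tolerance = 1e-12)
  # ordering matches the plain residual-SD ordering (the correction is
  # monotone in the per-gene mean square)
  r <- -cq - rowMeans(-cq) - rep(colMeans(-cq), each = 4) + mean(-cq)
  expect_identical(order(res$value), order(rowSums(r^2)))
  # expression input: log2 is taken internally, so 2^(-cq) reproduces -cq
  res2 <- normfinder(2^(-cq), input = "expression")
  expect_equal(res2$value, res$value, tolerance = 1e-9)
})

test_that("inflating one gene's noise raises its NormFinder value", {
  set.seed(77)
  worse <- 0
  for (s in 1:50) {
    base <- matrix(rnorm(5 * 10, 0, 0.3), 5, 10)
    sample_eff <- rnorm(10, 0, 1)
    y <- sweep(base, 2, sample_eff, "+") + c(20, 21, 22, 23, 24)
    dimnames(y) <- list(paste0("g", 1:5), paste0("s", 1:10))
    noisy <- y
    noisy["g3", ] <- noisy["g3", ] + rnorm(10, 0, 1)
    v0 <- normfinder(y, input = "expression")$value[3]
    v1 <- normfinder(noisy, input = "expression")$value[3]
    if (v1 > v0) worse <- worse + 1
  }
  expect_gte(worse, 45)
})

test_that("NormFinder grouped mode needs balanced groups and penalises bias", {
  set.seed(91)
  cq <- random_cq_table(4, 8)
  groups <- rep(c("a", "b"), each = 4)
  expect_error(normfinder(cq, groups = c(groups[-1], "c")), "at least 2")
  res <- normfinder(cq, groups = groups)
  expect_true(all(res$value >= 0))
  # a gene with a strong group-specific shift becomes least stable
  biased <- cq
  biased["G02", groups == "b"] <- biased["G02", groups == "b"] + 5
  resb <- normfinder(biased, groups = groups)
  expect_equal(resb$gene_id[which.max(resb$value)], "G02")
})

test_that("geNorm M, exclusion order and final pair match brute force", {
  set.seed(202)
  cq <- random_cq_table(4, 5)
  g <- genorm(cq)
  q <- 2^(apply(cq, 1, min) - cq)
  expect_equal(g$m_values$m, oracle_genorm_m(q), tolerance = 1e-12)
  orc <- oracle_genorm_exclusion(cq)
  expect_identical(g$exclusion_order, orc$exclusion_order)
  expect_identical(g$final_pair, orc$final_pair)
  # ranking: first exclusion gets rank k, final pair shares 1.5
  expect_equal(sort(g$ranking$rank), c(1.5, 1.5, 3, 4))
  expect_error(genorm(cq[1:2, ]), "at least 3")
  expect_error(genorm(-q, input = "expression"), "non-negative|positive")
})

test_that("geNorm pairwise variation V(n/n+1) matches brute force", {
  set.seed(203)
  cq <- random_cq_table(5, 7)
  v <- genorm_pairwise_variation(cq)
  expect_equal(v$v, oracle_genorm_v(cq), tolerance = 1e-12)
  expect_equal(v$n, 2:4)
})

test_that("two genes with constant log-ratio have zero pairwise variation", {
  s <- 2^seq(1, 4, length.out = 6)
  q <- rbind(g1 = s, g2 = 3 * s, g3 = 2^rnorm(6, 2, 1))
  colnames(q) <- paste0("s", 1:6)
  g <- genorm(q, input = "expression")
  # V(g1,g2) = 0 so both M values equal their (equal) SD against g3
  expect_equal(g$m_values$m[1], g$m_values$m[2], tolerance = 1e-12)
  expect_identical(g$final_pair, c("g1", "g2"))
})

test_that("with two samples SD-based values reduce to |difference|/sqrt(2)", {
  cq <- matrix(c(20, 21,
                 22, 24,
                 25, 25.5), 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  res <- delta_ct_stability(cq)
  # pairwise SD over two samples is |d1 - d2| / sqrt(2)
  d12 <- abs((20 - 22) - (21 - 24)) / sqrt(2)
  d13 <- abs((20 - 25) - (21 - 25.5)) / sqrt(2)
  expect_equal(res$value[1], mean(c(d12, d13)), tolerance = 1e-12)
  bk <- bestkeeper(cq)
  expect_equal(bk$sd, abs(cq[, 1] - cq[, 2]) / sqrt(2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("comprehensive rank is the geometric mean with documented tie-breaks", {
  ranks <- list(
    delta_ct = c(a = 1, b = 2, c = 3),
    bestkeeper = c(a = 2, b = 1, c = 3),
    normfinder = c(a = 1, b = 2, c = 3),
    genorm = c(a = 2, b = 1, c = 3))
  res <- comprehensive_rank(ranks)
  # a and b both have geometric mean (1*2*1*2)^(1/4) = sqrt(2)
  expect_equal(res$comprehensive_value[1:2], rep(sqrt(2), 2), tolerance = 1e-12)
  # tie broken lexically: a before b
  expect_identical(res$gene_id, c("a", "b", "c"))
  # all four agree -> identical ordering
  same <- lapply(1:4, function(i) c(x = 2, y = 1, z = 3))
  names(same) <- names(ranks)
  expect_identical(comprehensive_rank(same)$gene_id, c("y", "x", "z"))
  # mismatched universes are rejected
  bad <- ranks; names(bad$genorm) <- c("a", "b", "z")
  expect_error(comprehensive_rank(bad), "universe")
})

test_that("random rank vectors sort exactly as the brute-force geometric mean", {
  set.seed(303)
  for (i in 1:20) {
    genes <- paste0("g", 1:5)
    ranks <- lapply(1:4, function(j)
      stats::setNames(sample(5), genes))
    names(ranks) <- paste0("alg", 1:4)
    res <- comprehensive_rank(ranks)
    m <- do.call(cbind, lapply(ranks, function(r) r[genes]))
    geo <- oracle_geo_rank(m)
    expect_equal(stats::setNames(res$comprehensive_value, res$gene_id)[genes],
                 stats::setNames(geo, genes), tolerance = 1e-12)
    expect_identical(res$gene_id, genes[order(geo, rowMeans(m), genes)])
  }
})

test_that("stability_suite excludes incomplete genes and aggregates all four", {
  set.seed(404)
  cq <- random_cq_table(5, 10)
  cq["G05", 3] <- NA
  expect_warning(st <- stability_suite(cq), "G05")
  expect_setequal(st$summary$gene_id, paste0("G0", 1:4))
  # per-algorithm ranks are permutations (ties averaged) of 1..n
  for (col in c("delta_ct_rank", "bestkeeper_rank", "normfinder_rank"))
    expect_equal(sort(st$summary[[col]]), 1:4)
  expect_equal(sum(st$summary$genorm_rank), sum(1:4))
  expect_equal(sort(st$summary$comprehensive_rank), 1:4)
  # long-format CSV reader round-trips into the same suite input
  td <- withr::local_tempdir()
  f <- file.path(td, "cq.csv")
  long <- expand.grid(gene = rownames(cq), sample = colnames(cq),
                      stringsAsFactors = FALSE)
  long$cq <- cq[cbind(long$gene, long$sample)]
  utils::write.csv(long[!is.na(long$cq), ], f, row.names = FALSE)
  parsed <- read_cq_csv(f)
  expect_equal(parsed$cq[paste0("G0", 1:4), ], cq[paste0("G0", 1:4), ],
               tolerance = 1e-12)
  expect_true(is.na(parsed$cq["G05", 3]))
})
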