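# Independent brute-force oracles: naive scalar-loop implementations of
# every formula, kept deliberately separate from the package's vectorised
# code paths.

oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_rpkm <- function(counts, lengths) {
  out <- counts
  for (s in seq_len(ncol(counts))) {
    total <- sum(counts[, s])
    for (g in seq_len(nrow(counts)))
      out[g, s] <- counts[g, s] * 1e9 / (lengths[g] * total)
  }
  out
}

oracle_delta_ct <- function(cq) {
  k <- nrow(cq)
  vapply(seq_len(k), function(i) {
    vals <- c()
    for (j in seq_len(k)) if (j != i)
      vals <- c(vals, oracle_sd(cq[i, ] - cq[j, ]))
    mean(vals)
  }, numeric(1))
}

oracle_bestkeeper <- function(cq) {
  k <- nrow(cq); n <- ncol(cq)
  index <- numeric(n)
  for (s in seq_len(n)) index[s] <- prod(cq[, s])^(1 / k)
  list(sd = apply(cq, 1, oracle_sd),
       cv = apply(cq, 1, function(v) oracle_sd(v) / mean(v) * 100),
       r = apply(cq, 1, function(v) oracle_pearson(v, index)))
}

oracle_genorm_m <- function(q) {
  k <- nrow(q)
  vapply(seq_len(k), function(j) {
    vals <- c()
    for (l in seq_len(k)) if (l != j)
      vals <- c(vals, oracle_sd(log2(q[j, ] / q[l, ])))
    mean(vals)
  }, numeric(1))
}

oracle_genorm_exclusion <- function(cq, efficiency = 2) {
  q <- cq
  for (g in seq_len(nrow(cq)))
    q[g, ] <- efficiency^(min(cq[g, ]) - cq[g, ])
  active <- rownames(cq)
  excluded <- character(0)
  while (length(active) > 2) {
    m <- oracle_genorm_m(q[active, , drop = FALSE])
    names(m) <- active
    worst <- sort(names(m)[m == max(m)])[1]
    excluded <- c(excluded, worst)
    active <- setdiff(active, worst)
  }
  list(exclusion_order = excluded, final_pair = sort(active))
}

oracle_genorm_v <- function(cq, efficiency = 2) {
  q <- cq
  for (g in seq_len(nrow(cq)))
    q[g, ] <- efficiency^(min(cq[g, ]) - cq[g, ])
  ex <- oracle_genorm_exclusion(cq, efficiency)
  stable <- c(ex$final_pair, rev(ex$exclusion_order))
  k <- length(stable)
  nf <- function(n) {
    out <- numeric(ncol(q))
    for (s in seq_len(ncol(q)))
      out[s] <- prod(q[stable[seq_len(n)], s])^(1 / n)
    out
  }
  vapply(2:(k - 1), function(n) oracle_sd(log2(nf(n) / nf(n + 1))), numeric(1))
}

# NormFinder ungrouped estimator assembled step by step from the additive
# two-way model: double-centred residuals, per-gene mean squares, then the
# bias-corrected gene-wise variance.
oracle_normfinder <- function(y) {
  k <- nrow(y); n <- ncol(y)
  r <- y
  for (i in seq_len(k)) for (j in seq_len(n))
    r[i, j] <- y[i, j] - mean(y[i, ]) - mean(y[, j]) + mean(y)
  mss <- numeric(k)
  for (i in seq_len(k)) mss[i] <- sum(r[i, ]^2) / (n - 1)
  s_hat <- sum(mss) * k / (k - 1)
  sqrt(pmax(k / (k - 2) * (mss - s_hat / k^2), 0))
}

oracle_geo_rank <- function(ranks) {
  # ranks: genes x 4 matrix
  apply(ranks, 1, function(r) prod(r)^(1 / length(r)))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  oracle_pearson(rx, ry)
}

oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - sy / n)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# random complete Cq table, genes named for lexical determinism
random_cq_table <- function(n_genes = 5, n_samples = 12) {
  cq <- matrix(stats::rnorm(n_genes * n_samples, 25, 2), n_genes, n_samples,
               dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                               sprintf("S%02d", seq_len(n_samples))))
  cq
}
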