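#' Read a long-format Cq table
#'
#' Comma-separated, header `gene,sample,cq` with optional `efficiency`
#' (per-gene amplification efficiency, in (1, 2]) and `group` (per-sample
#' category) columns. Missing (gene, sample) combinations become `NA`.
#'
#' @param path Path to the CSV file.
#' @return List: `cq` (genes x samples numeric matrix), `efficiency`
#'   (named per-gene vector, default 2), `groups` (named per-sample
#'   vector or `NULL`).
#' @export
read_cq_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("Cq file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "cq")
  if (!all(need %in% names(df)))
    stop("Cq table needs columns gene, sample, cq", call. = FALSE)
  genes <- unique(df$gene)
  samples <- unique(df$sample)
  cq <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  cq[cbind(match(df$gene, genes), match(df$sample, samples))] <- df$cq
  eff <- stats::setNames(rep(2, length(genes)), genes)
  if ("efficiency" %in% names(df)) {
    e <- tapply(df$efficiency, df$gene, function(x) x[1])
    eff[names(e)] <- unname(e)
    if (any(eff <= 1 | eff > 2))
      stop("amplification efficiency must lie in (1, 2]", call. = FALSE)
  }
  groups <- NULL
  if ("group" %in% names(df)) {
    g <- tapply(df$group, df$sample, function(x) x[1])
    groups <- stats::setNames(as.character(g), names(g))[samples]
  }
  list(cq = cq, efficiency = eff, groups = groups)
}

.check_cq <- function(cq, min_genes = 3) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop("Cq data must be a numeric genes x samples matrix", call. = FALSE)
  if (nrow(cq) < min_genes)
    stop(sprintf("need at least %d genes", min_genes), call. = FALSE)
  if (any(!is.finite(cq)))
    stop("Cq values must be complete and finite; drop incomplete genes first",
         call. = FALSE)
  invisible(cq)
}

.rank_avg <- function(values) rank(values, ties.method = "average")

#' Comparative delta-Ct stability
#'
#' For each candidate gene, the stability value is the mean over all other
#' candidates of the standard deviation (across samples) of the pairwise
#' Cq difference. A gene whose profile tracks every other gene up to a
#' constant scores 0; per-sample additive shifts common to all genes (e.g.
#' input-amount differences) cancel in the differences. Lower = more
#' stable.
#'
#' @param cq Complete genes x samples Cq matrix (at least 3 genes).
#' @return Data.frame `gene_id`, `value`, `rank` (ascending by value, ties
#'   averaged), in input gene order.
#' @export
delta_ct_stability <- function(cq) {
  .check_cq(cq, min_genes = 3)
  k <- nrow(cq)
  value <- vapply(seq_len(k), function(i) {
    mean(vapply(setdiff(seq_len(k), i),
                function(j) stats::sd(cq[i, ] - cq[j, ]), numeric(1)))
  }, numeric(1))
  data.frame(gene_id = rownames(cq), value = value, rank = .rank_avg(value),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' BestKeeper descriptive stability
#'
#' Per-gene standard deviation of Cq and coefficient of variation
#' (SD/mean x 100), plus the Pearson correlation of each gene with the
#' BestKeeper index — the per-sample geometric mean of all candidate
#' genes' Cq. Ranking is ascending by Cq SD (the aggregation convention
#' used downstream); the correlation is reported alongside, and the
#' classical SD > 1 "unacceptable" rule is emitted as an advisory flag
#' only.
#'
#' @param cq Complete genes x samples Cq matrix (Cq > 0; a single gene is
#'   permitted, its index is its own profile).
#' @return Data.frame `gene_id`, `sd`, `cv`, `r`, `acceptable`, `rank`.
#'   With a zero-variance index the correlation is `NA` with a warning.
#' @export
bestkeeper <- function(cq) {
  .check_cq(cq, min_genes = 1)
  if (any(cq <= 0))
    stop("BestKeeper index requires positive Cq values", call. = FALSE)
  sds <- apply(cq, 1, stats::sd)
  cvs <- sds / rowMeans(cq) * 100
  index <- exp(colMeans(log(cq)))
  if (stats::sd(index) == 0) {
    warning("BestKeeper index has zero variance; correlations undefined",
            call. = FALSE)
    r <- rep(NA_real_, nrow(cq))
  } else {
    r <- apply(cq, 1, function(v)
      if (stats::sd(v) == 0) NA_real_ else stats::cor(v, index))
  }
  data.frame(gene_id = rownames(cq), sd = sds, cv = cvs, r = r,
             acceptable = sds <= 1, rank = .rank_avg(sds),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Double-centered residuals of a genes x samples block.
.two_way_residuals <- function(y) {
  sweep(sweep(y, 1, rowMeans(y)), 2, colMeans(y)) + mean(y)
}

# Unbiased gene-wise residual variances of the additive two-way model
# y_ij = alpha_i + beta_j + eps_ij with gene-specific Var(eps) = sigma_i^2.
# With k genes, n samples, MSS_i = sum_j r_ij^2 / (n - 1):
#   E[MSS_i] = sigma_i^2 (1 - 2/k) + S / k^2,  S = sum sigma^2
# so S-hat = k/(k-1) * sum(MSS) and
#   sigma_i^2-hat = k/(k-2) * (MSS_i - S-hat/k^2), truncated at 0.
.normfinder_vars <- function(y) {
  k <- nrow(y); n <- ncol(y)
  r <- .two_way_residuals(y)
  mss <- rowSums(r^2) / (n - 1)
  s_hat <- sum(mss) * k / (k - 1)
  pmax(k / (k - 2) * (mss - s_hat / k^2), 0)
}

#' NormFinder model-based stability
#'
#' Fits the additive two-way model `y_ij = alpha_i + beta_j + eps_ij` on
#' linear-scale log2 quantities (`y = -Cq`, since Cq falls by one cycle
#' per doubling of template; all algorithms in the suite then share one
#' abundance scale) and estimates each gene's own residual SD with a
#' degrees-of-freedom-corrected moment estimator; negative variance
#' estimates are truncated at 0. With sample groups, the stability value
#' combines the intra-group variance with a shrunken estimate of the
#' gene-by-group bias: `stability_i = mean_g(|d~_ig| + sqrt(v_ig))`, where
#' `d~` is the interaction effect shrunk by its reliability
#' `gamma^2 / (gamma^2 + sigma_ig^2/n_g)` and `v_ig` the corresponding
#' posterior variance (the sampling variance `sigma_ig^2/n_g` when the
#' interaction variance `gamma^2` estimates to 0). Lower = more stable.
#'
#' @param x Complete genes x samples matrix: Cq values
#'   (`input = "cq"`) or positive linear-scale expression
#'   (`input = "expression"`, log2 is taken internally).
#' @param groups Optional per-sample group labels (named or in column
#'   order); each group needs at least 2 samples.
#' @param input Scale of `x`.
#' @return Data.frame `gene_id`, `value`, `rank`.
#' @export
normfinder <- function(x, groups = NULL, input = c("cq", "expression")) {
  input <- match.arg(input)
  .check_cq(x, min_genes = 3)
  y <- if (input == "cq") -x else {
    if (any(x <= 0)) stop("expression input must be positive", call. = FALSE)
    log2(x)
  }
  k <- nrow(y)
  if (is.null(groups)) {
    value <- sqrt(.normfinder_vars(y))
  } else {
    groups <- as.character(groups)
    if (length(groups) != ncol(y))
      stop("one group label per sample required", call. = FALSE)
    if (any(table(groups) < 2))
      stop("every group needs at least 2 samples", call. = FALSE)
    gl <- unique(groups)
    G <- length(gl)
    if (G < 2) stop("grouped mode needs at least 2 groups", call. = FALSE)
    vars <- sapply(gl, function(g) .normfinder_vars(y[, groups == g, drop = FALSE]))
    ng <- stats::setNames(as.vector(table(groups)[gl]), gl)
    gm <- sapply(gl, function(g) rowMeans(y[, groups == g, drop = FALSE]))
    d <- .two_way_residuals(gm)                       # gene x group interaction
    samp <- sweep(vars, 2, ng, "/")                   # sigma^2_ig / n_g
    gamma2 <- max(0, (sum(d^2) - (1 - 1/k) * (1 - 1/G) * sum(samp)) /
                       ((k - 1) * (G - 1)))
    if (gamma2 > 0) {
      shrink <- gamma2 / (gamma2 + samp)
      dtilde <- d * shrink
      v <- samp * shrink
    } else {
      dtilde <- d * 0
      v <- samp
    }
    value <- rowMeans(abs(dtilde) + sqrt(v))
  }
  data.frame(gene_id = rownames(x), value = unname(value),
             rank = .rank_avg(value), stringsAsFactors = FALSE, row.names = NULL)
}

# Relative quantities from Cq: Q_gs = E_g ^ (min_s Cq_gs - Cq_gs), so the
# best-expressed sample of each gene has Q = 1.
.cq_to_quantity <- function(cq, efficiency = 2) {
  if (length(efficiency) == 1)
    efficiency <- stats::setNames(rep(efficiency, nrow(cq)), rownames(cq))
  e <- efficiency[rownames(cq)]
  if (any(is.na(e) | e <= 1 | e > 2))
    stop("amplification efficiency must lie in (1, 2] for every gene", call. = FALSE)
  # per-gene min and efficiency recycle column-wise against the genes x
  # samples matrix, keeping each gene's own baseline
  q <- e ^ (apply(cq, 1, min) - cq)
  dimnames(q) <- dimnames(cq)
  q
}

.genorm_m <- function(q) {
  k <- nrow(q)
  lg <- log2(q)
  vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j),
                function(l) stats::sd(lg[j, ] - lg[l, ]), numeric(1)))
  }, numeric(1))
}

#' geNorm expression stability and stepwise exclusion
#'
#' Computes per-gene M values — the mean, over all other candidates, of
#' the standard deviation across samples of the pairwise log2 expression
#' ratio — then progressively removes the gene with the highest M
#' (recomputing after each removal) until the two most stable genes
#' remain. Because M is built from ratios, multiplying all of one
#' sample's quantities by a constant (a pure loading difference) changes
#' nothing. Cq input is converted to relative quantities
#' `Q = E^(Cq_min - Cq)` with perfect-doubling efficiency `E = 2` by
#' default.
#'
#' @param x Complete genes x samples matrix (at least 3 genes): Cq values
#'   or positive linear-scale expression.
#' @param input Scale of `x`.
#' @param efficiency Scalar or per-gene named vector in (1, 2]; only used
#'   for Cq input.
#' @return List: `m_values` (data.frame `gene_id`, `m`, `rank` for the
#'   full starting set), `exclusion_order` (genes in removal order),
#'   `final_pair`, `ranking` (data.frame `gene_id`, `rank`; the final two
#'   genes share ranks 1-2, reported as 1.5 each), and `steps` (per-round
#'   M values).
#' @export
genorm <- function(x, input = c("cq", "expression"), efficiency = 2) {
  input <- match.arg(input)
  .check_cq(x, min_genes = 3)
  q <- if (input == "cq") .cq_to_quantity(x, efficiency) else x
  if (any(q <= 0))
    stop("geNorm requires strictly positive quantities", call. = FALSE)
  genes <- rownames(q)
  m0 <- .genorm_m(q)
  excluded <- character(0)
  steps <- list()
  active <- genes
  while (length(active) > 2) {
    m <- .genorm_m(q[active, , drop = FALSE])
    names(m) <- active
    steps[[length(steps) + 1]] <- m
    worst <- sort(names(m)[m == max(m)])[1]   # lexical tie-break
    excluded <- c(excluded, worst)
    active <- setdiff(active, worst)
  }
  rank <- stats::setNames(rep(1.5, length(genes)), genes)
  if (length(excluded))
    rank[excluded] <- seq(length(genes), 3L)
  list(m_values = data.frame(gene_id = genes, m = m0,
                             rank = unname(rank[genes]),
                             stringsAsFactors = FALSE, row.names = NULL),
       exclusion_order = excluded,
       final_pair = sort(active),
       ranking = data.frame(gene_id = genes, rank = unname(rank[genes]),
                            stringsAsFactors = FALSE, row.names = NULL),
       steps = steps)
}

#' geNorm pairwise variation V(n/n+1)
#'
#' For n = 2 .. k-1, the standard deviation across samples of
#' `log2(NF_n / NF_(n+1))`, where `NF_n` is the per-sample geometric mean
#' of the n most stable genes (stability order = reverse geNorm exclusion
#' order). Used, optionally, to judge how many reference genes a
#' normalization factor needs; descriptive only.
#'
#' @inheritParams genorm
#' @return Data.frame `n`, `v` with one row per consecutive pair.
#' @export
genorm_pairwise_variation <- function(x, input = c("cq", "expression"),
                                      efficiency = 2) {
  input <- match.arg(input)
  g <- genorm(x, input, efficiency)
  q <- if (input == "cq") .cq_to_quantity(x, efficiency) else x
  stable_order <- c(g$final_pair, rev(g$exclusion_order))
  k <- length(stable_order)
  nf <- function(n) exp(colMeans(log(q[stable_order[seq_len(n)], , drop = FALSE])))
  data.frame(n = 2:(k - 1),
             v = vapply(2:(k - 1), function(n)
               stats::sd(log2(nf(n) / nf(n + 1))), numeric(1)))
}

#' Comprehensive (RefFinder-style) aggregation of stability ranks
#'
#' The comprehensive stability value of a gene is the geometric mean of
#' its four per-algorithm ranks (ties within an algorithm averaged before
#' aggregation); the final ordering is ascending by that value, with ties
#' broken by the arithmetic mean of ranks and then lexical gene ID.
#'
#' @param ranks Named list of four numeric rank vectors (each named by
#'   gene) over the same gene universe, e.g. from [delta_ct_stability()],
#'   [bestkeeper()], [normfinder()] and [genorm()].
#' @return Data.frame: `gene_id`, one column per input ranking,
#'   `comprehensive_value`, `final_rank`, ordered by `final_rank`.
#' @export
comprehensive_rank <- function(ranks) {
  if (length(ranks) != 4)
    stop("expected four rank vectors", call. = FALSE)
  universe <- sort(names(ranks[[1]]))
  for (r in ranks)
    if (!setequal(names(r), universe))
      stop("rank vectors cover different gene universes", call. = FALSE)
  m <- vapply(ranks, function(r) r[universe], numeric(length(universe)))
  geo <- exp(rowMeans(log(m)))
  ari <- rowMeans(m)
  ord <- order(geo, ari, universe)
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  colnames(m) <- names(ranks)
  out <- cbind(out, as.data.frame(m, row.names = NULL))
  out$comprehensive_value <- geo
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full reference-gene stability suite
#'
#' Applies the comparative delta-Ct, BestKeeper, NormFinder and geNorm
#' algorithms to one Cq table and aggregates their rankings into the
#' comprehensive geometric-mean rank. Genes with any missing Cq are
#' excluded up front with a warning (all four algorithms assume complete
#' profiles; no imputation is attempted).
#'
#' @param cq Genes x samples Cq matrix; `NA` marks missing values.
#' @param groups Optional per-sample group labels for NormFinder.
#' @param efficiency Scalar or per-gene named amplification efficiency in
#'   (1, 2], used in the geNorm quantity transform.
#' @return List with elements `summary` (one row per gene: all values and
#'   ranks plus the comprehensive rank), `delta_ct`, `bestkeeper`,
#'   `normfinder`, `genorm`, `comprehensive`.
#' @export
stability_suite <- function(cq, groups = NULL, efficiency = 2) {
  incomplete <- rownames(cq)[rowSums(!is.finite(cq)) > 0]
  if (length(incomplete)) {
    warning(sprintf("excluding genes with missing Cq: %s",
                    paste(incomplete, collapse = ", ")), call. = FALSE)
    cq <- cq[setdiff(rownames(cq), incomplete), , drop = FALSE]
  }
  .check_cq(cq, min_genes = 3)
  dct <- delta_ct_stability(cq)
  bk <- bestkeeper(cq)
  nf <- normfinder(cq, groups = groups, input = "cq")
  gn <- genorm(cq, input = "cq", efficiency = efficiency)
  ranks <- list(
    delta_ct = stats::setNames(dct$rank, dct$gene_id),
    bestkeeper = stats::setNames(bk$rank, bk$gene_id),
    normfinder = stats::setNames(nf$rank, nf$gene_id),
    genorm = stats::setNames(gn$ranking$rank, gn$ranking$gene_id))
  comp <- comprehensive_rank(ranks)
  summary <- data.frame(gene_id = rownames(cq), stringsAsFactors = FALSE)
  summary$delta_ct_value <- dct$value[match(summary$gene_id, dct$gene_id)]
  summary$delta_ct_rank <- dct$rank[match(summary$gene_id, dct$gene_id)]
  summary$bestkeeper_sd <- bk$sd[match(summary$gene_id, bk$gene_id)]
  summary$bestkeeper_cv <- bk$cv[match(summary$gene_id, bk$gene_id)]
  summary$bestkeeper_r <- bk$r[match(summary$gene_id, bk$gene_id)]
  summary$bestkeeper_rank <- bk$rank[match(summary$gene_id, bk$gene_id)]
  summary$normfinder_value <- nf$value[match(summary$gene_id, nf$gene_id)]
  summary$normfinder_rank <- nf$rank[match(summary$gene_id, nf$gene_id)]
  summary$genorm_m <- gn$m_values$m[match(summary$gene_id, gn$m_values$gene_id)]
  summary$genorm_rank <- gn$ranking$rank[match(summary$gene_id, gn$ranking$gene_id)]
  idx <- match(summary$gene_id, comp$gene_id)
  summary$comprehensive_value <- comp$comprehensive_value[idx]
  summary$comprehensive_rank <- comp$final_rank[idx]
  summary <- summary[order(summary$comprehensive_rank), , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, delta_ct = dct, bestkeeper = bk, normfinder = nf,
       genorm = gn, comprehensive = comp)
}
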