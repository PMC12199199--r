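#' Configuration for the synthetic EV-cohort generator
#'
#' Defaults emulate the study conditions the pipeline is designed for: 12
#' biological EV sources with replicates, log-normal transcript abundance
#' with a heavy upper tail (so a 1000-RPKM cutoff isolates a handful of
#' genes), a planted set of high-abundance low-variance reference
#' transcripts, one variably expressed RAB13-like target, Cq values affine
#' in log2 abundance with Gaussian noise, and dPCR copies proportional to
#' abundance with Poisson counting noise.
#'
#' @param n_sources Number of biological sources (default 12).
#' @param replicates_per_source Replicates per source (default 3).
#' @param n_genes Total genes (default 5000).
#' @param n_reference Planted reference genes (default 5).
#' @param n_variable Planted variable target genes (default 1).
#' @param baseline_log2_mean,baseline_log2_sd Background gene baseline
#'   log2-RPKM distribution, normal(5, 3).
#' @param background_source_sd Between-source SD of background genes on
#'   the log2 scale (default 1).
#' @param ref_log2_range Range the planted references' baseline log2-RPKM
#'   is drawn from, uniform on [13, 15] — tens of thousands of RPKM,
#'   comfortably above the robust-abundance cutoff in every source.
#' @param ref_source_sd Between-source SD of the references (default 0.2).
#' @param var_log2_mean,var_source_sd Baseline and between-source SD of
#'   the variable target (8 and 2): present everywhere, erratic in rank.
#' @param rep_sd Replicate noise SD, log2 scale (default 0.3).
#' @param dropout_log2_threshold,dropout_prob Below this log2 abundance a
#'   replicate observation is zeroed with this probability (1 and 0.5),
#'   exercising the replicate zero-masking rule.
#' @param cq_intercept,cq_sd Cq model `Cq = c0 - log2(abundance) + noise`
#'   with c0 = 35 and noise SD 0.25 cycles.
#' @param ref_cq_extra_sd Per-reference additional Cq noise SD, default
#'   `c(0, 0, 0.8, 1.1, 1.4)`: two near-ideal assays and three
#'   increasingly unstable ones (the worst near the classical one-cycle
#'   "unacceptable" zone), giving the stability suite a defined truth.
#' @param dpcr_scale Copies per microlitre per abundance unit (default 10).
#' @param dpcr_base_abundance Control-arm base template abundance
#'   (default 100, i.e. about 1000 copies/ul at the default scale).
#' @param dpcr_condition_sd Per-condition log2 spread shared by the paired
#'   loaded/control arms (default 0.5).
#' @param dpcr_n_conditions Paired conditions per arm (default 4).
#' @param fold_enrichment True loaded/control fold enrichment f (default 8).
#' @param seed Integer seed; one seed drives three independent substreams
#'   (expression / Cq / dPCR), so regenerating one readout never perturbs
#'   another.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_sources = 12, replicates_per_source = 3,
                             n_genes = 5000, n_reference = 5, n_variable = 1,
                             baseline_log2_mean = 5, baseline_log2_sd = 3,
                             background_source_sd = 1,
                             ref_log2_range = c(13, 15), ref_source_sd = 0.2,
                             var_log2_mean = 8, var_source_sd = 2,
                             rep_sd = 0.3,
                             dropout_log2_threshold = 1, dropout_prob = 0.5,
                             cq_intercept = 35, cq_sd = 0.25,
                             ref_cq_extra_sd = c(0, 0, 0.8, 1.1, 1.4),
                             dpcr_scale = 10, dpcr_base_abundance = 100,
                             dpcr_condition_sd = 0.5, dpcr_n_conditions = 4,
                             fold_enrichment = 8, seed = 1) {
  cfg <- as.list(environment())
  sds <- c(cfg$baseline_log2_sd, cfg$background_source_sd, cfg$ref_source_sd,
           cfg$var_source_sd, cfg$rep_sd, cfg$cq_sd, cfg$ref_cq_extra_sd,
           cfg$dpcr_condition_sd)
  if (any(sds < 0)) stop("all SD parameters must be >= 0", call. = FALSE)
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]", call. = FALSE)
  if (cfg$n_reference + cfg$n_variable > cfg$n_genes)
    stop("n_reference + n_variable exceeds n_genes", call. = FALSE)
  if (length(cfg$ref_cq_extra_sd) != cfg$n_reference)
    stop("ref_cq_extra_sd needs one entry per planted reference", call. = FALSE)
  if (cfg$fold_enrichment <= 0) stop("fold_enrichment must be > 0", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

# Three reproducible substream seeds derived from the global seed.
.substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 3)
}

#' Generate a synthetic multi-source EV expression cohort
#'
#' Replicate values are `2^(source log2 abundance + replicate noise)`,
#' reported in RPKM units, with Bernoulli dropout zeros below the
#' low-abundance threshold. Planted references are protein-coding and
#' drawn so their source-averaged values exceed the robust-abundance
#' cutoff in every source; background genes carry a realistic mix of
#' biotypes. Fully deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return List: `matrix` (replicate-level [expression_matrix()], unit
#'   rpkm), `replicate_map` (with a 5-level `group_id` emulating
#'   tissue-origin categories), `annotation`, and `truth` — the planted
#'   ground truth (`reference_genes`, `variable_gene`, `log2_abundance`
#'   gene x source matrix, `fold_enrichment`, `seed`).
#' @export
generate_expression <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- .substream_seeds(config$seed)
  set.seed(seeds[1])
  ns <- config$n_sources; nr <- config$replicates_per_source
  ng <- config$n_genes
  n_bg <- ng - config$n_reference - config$n_variable
  ref_ids <- sprintf("SYNREF%02d", seq_len(config$n_reference))
  var_ids <- sprintf("SYNVAR%02d", seq_len(config$n_variable))
  bg_ids <- sprintf("SYNG%05d", seq_len(n_bg))
  ids <- c(ref_ids, var_ids, bg_ids)
  sources <- sprintf("SRC%02d", seq_len(ns))

  base <- c(stats::runif(config$n_reference, config$ref_log2_range[1],
                         config$ref_log2_range[2]),
            rep(config$var_log2_mean, config$n_variable),
            stats::rnorm(n_bg, config$baseline_log2_mean, config$baseline_log2_sd))
  src_sd <- c(rep(config$ref_source_sd, config$n_reference),
              rep(config$var_source_sd, config$n_variable),
              rep(config$background_source_sd, n_bg))
  log2_ab <- base + matrix(stats::rnorm(ng * ns), ng, ns) * src_sd
  dimnames(log2_ab) <- list(ids, sources)

  samples <- as.vector(t(outer(sources, seq_len(nr),
                               function(s, r) sprintf("%s_R%d", s, r))))
  rep_noise <- matrix(stats::rnorm(ng * ns * nr, 0, config$rep_sd), ng, ns * nr)
  vals <- 2^(log2_ab[, rep(seq_len(ns), each = nr)] + rep_noise)
  low <- log2_ab[, rep(seq_len(ns), each = nr)] < config$dropout_log2_threshold
  drop <- matrix(stats::runif(ng * ns * nr) < config$dropout_prob, ng, ns * nr)
  vals[low & drop] <- 0
  dimnames(vals) <- list(ids, samples)

  groups <- rep(sprintf("G%d", 1:5), times = c(2, 2, 2, 2, 4), length.out = ns)
  replicate_map <- data.frame(sample_id = samples,
                              source_id = rep(sources, each = nr),
                              group_id = rep(groups, each = nr),
                              stringsAsFactors = FALSE)

  bg_biotype <- sample(biotype_levels(), n_bg, replace = TRUE,
                       prob = c(0.70, 0.10, 0.12, 0.03, 0.02, 0.03))
  annotation <- data.frame(
    gene_id = ids,
    gene_symbol = ids,
    biotype = c(rep("protein_coding", config$n_reference + config$n_variable),
                bg_biotype),
    length_bp = pmax(200L, as.integer(round(2^stats::rnorm(ng, log2(1500), 0.5)))),
    stringsAsFactors = FALSE)

  truth <- list(reference_genes = ref_ids,
                variable_gene = var_ids[1],
                log2_abundance = log2_ab,
                fold_enrichment = config$fold_enrichment,
                seed = config$seed)
  list(matrix = expression_matrix(vals, "rpkm"),
       replicate_map = replicate_map,
       annotation = annotation,
       truth = truth)
}

#' Generate a synthetic Cq table from planted truth
#'
#' `Cq = c0 - log2(source abundance) + N(0, cq_sd)` with independent noise
#' per (gene, source); planted references additionally receive their
#' per-assay extra noise from `ref_cq_extra_sd`. One Cq column per source.
#' Zero-abundance entries have undefined Cq and are reported `NA`.
#'
#' @param truth Truth component of [generate_expression()] output.
#' @param config The same [synthetic_config()].
#' @param genes Genes to assay (default: planted references + target).
#' @return Genes x sources Cq matrix.
#' @export
generate_cq <- function(truth, config = synthetic_config(), genes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(genes))
    genes <- c(truth$reference_genes, truth$variable_gene)
  if (!all(genes %in% rownames(truth$log2_abundance)))
    stop("requested genes absent from the planted truth", call. = FALSE)
  seeds <- .substream_seeds(truth$seed)
  set.seed(seeds[2])
  ab <- truth$log2_abundance[genes, , drop = FALSE]
  extra <- stats::setNames(rep(0, length(genes)), genes)
  hit <- intersect(genes, truth$reference_genes)
  extra[hit] <- config$ref_cq_extra_sd[match(hit, truth$reference_genes)]
  noise_sd <- sqrt(config$cq_sd^2 + extra^2)
  cq <- config$cq_intercept - ab +
    matrix(stats::rnorm(length(ab)), nrow(ab), ncol(ab)) * noise_sd
  cq[!is.finite(ab)] <- NA_real_
  cq
}

#' Generate a synthetic paired dPCR benchmark
#'
#' Paired loaded/control conditions: each condition draws a shared
#' template abundance `base * 2^N(0, condition_sd)`; the loaded arm's
#' expectation is `fold_enrichment` times the control's. Absolute copies
#' are `dpcr_scale * abundance` with Poisson counting noise (or exactly
#' the expectation with `noise = FALSE`). Matched target/reference Cq
#' values follow the same Cq model, the reference held at its planted
#' cross-source mean abundance.
#'
#' @param truth Truth component of [generate_expression()] output.
#' @param config The same [synthetic_config()].
#' @param target Target gene (default the planted variable gene).
#' @param reference Reference gene (default the first planted reference).
#' @param noise If `FALSE`, expectation mode: no Poisson or Cq noise.
#' @return Data.frame: `condition`, `arm`, `copies_per_ul`, `cq_target`,
#'   `cq_reference`, `rel_value` (`2^-dCq`).
#' @export
generate_dpcr <- function(truth, config = synthetic_config(),
                          target = truth$variable_gene,
                          reference = truth$reference_genes[1],
                          noise = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- .substream_seeds(truth$seed)
  set.seed(seeds[3])
  nc <- config$dpcr_n_conditions
  cond_ab <- config$dpcr_base_abundance *
    2^stats::rnorm(nc, 0, config$dpcr_condition_sd)
  ab <- c(cond_ab, cond_ab * config$fold_enrichment)
  arm <- rep(c("control", "loaded"), each = nc)
  lambda <- config$dpcr_scale * ab
  copies <- if (noise) stats::rpois(2 * nc, lambda) else lambda
  ref_ab <- 2^mean(truth$log2_abundance[reference, ])
  cq_noise <- function(n) if (noise) stats::rnorm(n, 0, config$cq_sd) else 0
  cq_t <- config$cq_intercept - log2(ab) + cq_noise(2 * nc)
  cq_r <- config$cq_intercept - log2(ref_ab) + cq_noise(2 * nc)
  data.frame(condition = rep(sprintf("C%d", seq_len(nc)), 2),
             arm = arm,
             copies_per_ul = as.numeric(copies),
             cq_target = cq_t,
             cq_reference = cq_r,
             rel_value = 2^(-(cq_t - cq_r)),
             stringsAsFactors = FALSE)
}
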