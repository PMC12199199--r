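#' Delta-Cq relative quantification of a target against one reference
#'
#' Per sample, `dCq = Cq_target - Cq_reference` and the relative value is
#' `2^(-dCq)` (perfect doubling per cycle). Samples where either Cq is
#' missing are skipped with a warning. `log2` of the relative value
#' recovers `-dCq` exactly.
#'
#' @param cq Genes x samples Cq matrix (`NA` = missing).
#' @param target Target gene ID.
#' @param reference Reference gene ID (must differ from the target).
#' @return Data.frame `sample_id`, `delta_cq`, `rel_value`, with
#'   attributes `target`, `reference` and `method`.
#' @param method Free-text provenance tag carried on the output (e.g.
#'   which cDNA preparation the Cq values came from).
#' @export
delta_cq_normalize <- function(cq, target, reference, method = "qPCR") {
  if (identical(target, reference))
    stop("target and reference must differ", call. = FALSE)
  if (!all(c(target, reference) %in% rownames(cq)))
    stop("target or reference gene absent from the Cq table", call. = FALSE)
  ok <- is.finite(cq[target, ]) & is.finite(cq[reference, ])
  if (!all(ok))
    warning(sprintf("skipping samples with missing Cq: %s",
                    paste(colnames(cq)[!ok], collapse = ", ")), call. = FALSE)
  dcq <- cq[target, ok] - cq[reference, ok]
  out <- data.frame(sample_id = colnames(cq)[ok], delta_cq = unname(dcq),
                    rel_value = unname(2^(-dcq)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "target") <- target
  attr(out, "reference") <- reference
  attr(out, "method") <- method
  out
}

#' Expression-ratio normalization of a target against one reference
#'
#' Per source, the relative value is `RPKM_target / RPKM_reference`.
#' Sources where the reference is unexpressed are excluded with a
#' warning. Ratios are invariant to any per-source scale factor common to
#' both genes (library size cancels).
#'
#' @param avg_matrix Source-averaged expression matrix, unit `"rpkm"`.
#' @inheritParams delta_cq_normalize
#' @return Data.frame `sample_id`, `rel_value`, with attributes `target`,
#'   `reference`, `method = "rnaseq"`.
#' @export
expression_ratio_normalize <- function(avg_matrix, target, reference) {
  .require_unit(avg_matrix, "rpkm")
  if (identical(target, reference))
    stop("target and reference must differ", call. = FALSE)
  if (!all(c(target, reference) %in% rownames(avg_matrix)))
    stop("target or reference gene absent from the matrix", call. = FALSE)
  ok <- avg_matrix[reference, ] > 0
  if (!all(ok))
    warning(sprintf("excluding sources with zero reference RPKM: %s",
                    paste(colnames(avg_matrix)[!ok], collapse = ", ")),
            call. = FALSE)
  out <- data.frame(sample_id = colnames(avg_matrix)[ok],
                    rel_value = unname(avg_matrix[target, ok] /
                                         avg_matrix[reference, ok]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "target") <- target
  attr(out, "reference") <- reference
  attr(out, "method") <- "rnaseq"
  out
}

#' Spearman rank concordance between two normalized series
#'
#' Both series are ranked ascending so that the highest expression
#' receives rank n, and the Spearman correlation coefficient rho is
#' computed on the ranks (average ranks for ties). rho = 1 for identical
#' orderings, -1 for exactly reversed ones, and the coefficient is
#' invariant under any strictly increasing transform of either series.
#'
#' @param a,b Data.frames with `sample_id` and `rel_value` columns (e.g.
#'   from [delta_cq_normalize()] / [expression_ratio_normalize()]).
#' @return List: `rho`, `n`, and a data.frame `ranks` with per-sample
#'   ranks of both series over their common samples.
#' @export
rank_concordance <- function(a, b) {
  common <- intersect(a$sample_id, b$sample_id)
  if (length(common) < 3)
    stop("need at least 3 common samples", call. = FALSE)
  va <- a$rel_value[match(common, a$sample_id)]
  vb <- b$rel_value[match(common, b$sample_id)]
  ra <- rank(va, ties.method = "average")
  rb <- rank(vb, ties.method = "average")
  list(rho = stats::cor(ra, rb),
       n = length(common),
       ranks = data.frame(sample_id = common, rank_a = ra, rank_b = rb,
                          stringsAsFactors = FALSE, row.names = NULL))
}

#' Linear-regression benchmark of relative against absolute quantification
#'
#' Ordinary least squares of the relative quantity (`2^-dCq`, y-axis)
#' on absolute dPCR copies per microlitre (x-axis), not forced through
#' the origin. R-squared = 1 corresponds to a perfect linear fit.
#'
#' @param copies Numeric vector of absolute copies per microlitre.
#' @param relquant Numeric vector of matched `2^-dCq` values.
#' @return List `slope`, `intercept`, `r_squared`, `n`.
#' @export
dpcr_regression <- function(copies, relquant) {
  if (length(copies) != length(relquant))
    stop("copies and relquant must be paired", call. = FALSE)
  if (length(copies) < 3)
    stop("need at least 3 paired conditions", call. = FALSE)
  if (stats::sd(copies) == 0)
    stop("zero variance in absolute copies; regression undefined", call. = FALSE)
  fit <- stats::lm(relquant ~ copies)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((relquant - mean(relquant))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss == 0) 0 else 1 - rss / tss,
       n = length(copies))
}

#' Estimate loading enrichment from a dPCR benchmark table
#'
#' The ratio of mean absolute copies in the actively loaded arm to the
#' passively loaded (control) arm. With paired conditions the shared
#' condition-level variation cancels, leaving counting noise only.
#'
#' @param dpcr Data.frame with columns `arm` (`"loaded"`/`"control"`) and
#'   `copies_per_ul`, e.g. from [generate_dpcr()].
#' @return Estimated fold enrichment (scalar).
#' @export
estimate_enrichment <- function(dpcr) {
  if (!all(c("loaded", "control") %in% dpcr$arm))
    stop("need both a loaded and a control arm", call. = FALSE)
  mean(dpcr$copies_per_ul[dpcr$arm == "loaded"]) /
    mean(dpcr$copies_per_ul[dpcr$arm == "control"])
}
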