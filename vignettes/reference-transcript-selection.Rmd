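---
title: "Selecting and validating EV reference transcripts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating EV reference transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evref)
```

## The problem

Extracellular vesicles carry small, variable amounts of mRNA. Relative
quantification of an EV transcript by RT-qPCR needs a reference transcript
whose abundance is high (so it is reliably detected in sparse vesicle RNA)
and stable across biological sources (so the normalization does not inject
its own variation). Cellular housekeeping genes earn neither property
automatically in vesicles. `evref` operationalises a two-arm answer:
*selection* of candidates from multi-source RNA-seq abundance, and
*validation* by stability scoring, cross-platform concordance, and an
absolute-quantification benchmark.

## Selection model

The unit of selection is the biological source (a cell type or fluid), not
the sequencing replicate. Three preprocessing rules define the abundance
signal:

1. **Zero masking.** Within a source, a gene with zero reads in *any*
   replicate is set to zero in *all* of that source's replicates. This makes
   "no expression in any replicate" exactly equivalent to "source average is
   zero", so downstream filters need only look at averages. Masking is
   idempotent and applied before averaging — the order is fixed in
   `run_selection()`.
2. **Averaging.** Arithmetic mean over a source's replicates, one column per
   source.
3. **RPKM.** When raw counts arrive, `RPKM = count · 10⁹ / (length_bp ·
   library_size)` with the library size taken as the column sum of the count
   matrix. The transform is exactly invertible given lengths and totals, and
   a test asserts that round trip.

Selection then composes four set operations, each with a deterministic tie
policy:

- **Top-N sets** (N = 1000 per source). Boundary ties resolve by lexical
  gene-ID order; zero-abundance genes are never admitted, and a source with
  fewer than N expressed genes is a hard error rather than a silently short
  set.
- **Intersection summary** — the genes common to all sources, plus
  per-source partial/unique counts (the numbers a Venn-style figure would
  show).
- **Rank-sum ordering.** Within-source ranks are *ordinal* (ties again
  lexical), so rank sums are integers; the ordering depends only on
  within-source order and is therefore invariant under any strictly
  increasing per-source transform — a property test randomises over such
  transforms.
- **Robust-abundance filter.** A candidate must lie in the rank-sum top k
  (k = 50) *and* have averaged RPKM ≥ 1000 in every source: one
  below-threshold source excludes the gene. The threshold is a point on the
  overall RPKM distribution separating the consistently massive transcripts
  from the merely well-expressed; the per-source reading (rather than a
  cross-source mean) is what makes the abundance "robust".
- **Biotype filter.** Only protein-coding transcripts remain: non-coding
  RNAs and pseudogenes amplify unreliably from oligo-dT-primed cDNA, and
  mitochondrial transcripts track mitochondrial load rather than cellular
  transcription.

Two genuinely open design points, decided here once: the top-50 window is
taken on the rank-sum ordering *restricted to the all-source shared set*
(the unrestricted position is reported alongside as `global_order`), and
candidates disqualified by manual transcript-coverage review enter as an
explicit `exclude_genes` list rather than as a coverage algorithm — a
judgment made on genome-browser evidence should stay a declarative input.
The variable-target screen (`select_variable_target()`) scores genes
expressed in all sources by the SD of their per-source abundance ranks; the
informal notion of "wide variance in rank" admits several formalisations and
SD-of-ranks is the simplest that is invariant to abundance scale.

## Stability algorithms

All four algorithms consume a complete genes × samples Cq matrix; a gene
with any missing Cq is dropped with a warning (no imputation — every
algorithm below assumes complete profiles). Cq is inversely proportional to
log2 template abundance, so where a linear scale is needed the package uses
y = −Cq (NormFinder) or relative quantities Q = E^(Cq_min − Cq) with
perfect-doubling efficiency E = 2 (geNorm). Per-gene efficiencies in (1, 2]
are accepted as input but never estimated.

- **Comparative ΔCt**: value_i = mean_{j≠i} SD_s(Cq_i − Cq_j). Per-sample
  additive shifts cancel in the differences.
- **BestKeeper**: per-gene SD and CV of Cq; index = per-sample geometric
  mean of all candidates' Cq; per-gene Pearson r against the index. The
  ranking key is the Cq SD (the convention downstream aggregation expects);
  the classical SD > 1 "unacceptable" rule is an advisory flag. SDs use the
  n−1 denominator throughout the package and its test oracles.
- **NormFinder**: additive two-way model y_ij = α_i + β_j + ε_ij with
  gene-specific Var(ε) = σ_i². From the double-centred residual mean squares
  MSS_i = Σ_j r_ij²/(n−1), the estimator Ŝ = k/(k−1)·ΣMSS and σ̂_i² =
  k/(k−2)·(MSS_i − Ŝ/k²) is unbiased under the model (derived by hand;
  the derivation is exercised by the pure-sample-effects test in which all
  values vanish). Negative estimates truncate at 0. With sample groups, the
  per-group variances σ̂²_ig are combined with the gene-by-group interaction
  d_ig (double-centred group means): the interaction variance γ² is
  estimated by moments, d is shrunk by γ̂²/(γ̂² + σ̂²_ig/n_g), and
  stability_i = mean_g(|d̃_ig| + √v_ig) with v the corresponding posterior
  variance (falling back to the sampling variance when γ̂² = 0). Grouped
  mode is exposed but ungrouped is the default: with a dozen heterogeneous
  EV sources there is no compelling grouping, and the group sizes (2–4) make
  the interaction estimate fragile.
- **geNorm**: M_j = mean_{k≠j} SD_s(log2 Q_j/Q_k); the gene with the highest
  M is removed (lexical tie-break) and M recomputed until two genes remain —
  the final pair shares ranks 1–2, reported as 1.5 each. The optional
  V(n/n+1) statistic (SD of log2 NF_n/NF_{n+1}, NF = geometric-mean
  normalization factor of the n most stable genes) is implemented as a
  descriptive aid only.
- **Comprehensive rank**: geometric mean of the four per-algorithm ranks
  (ties averaged within an algorithm first), the aggregation popularised by
  the RefFinder tool; ties in the final ordering break by arithmetic mean of
  ranks, then lexical gene ID. Whether such an aggregation should be fed raw
  or efficiency-corrected Cq is unspecified in common practice; the package
  defaults to raw Cq with E = 2 and documents the knob.

## Validation arms

`delta_cq_normalize()` returns 2^−ΔCq per sample,
`expression_ratio_normalize()` the per-source RPKM ratio; both series are
compared by Spearman ρ on ranks assigned so the highest expression gets
rank n (average ranks on ties — the documented policy even though real
12-sample Cq data essentially never ties). The dPCR benchmark regresses
2^−ΔCq on absolute copies/µl by OLS with copies on the x axis and no
forcing through the origin; R² is reported descriptively, and no
multiple-testing machinery is added because nothing here is a hypothesis
test.

## The synthetic cohort

`synthetic_config()` freezes the simulated study conditions: 12 sources ×
3 replicates × 5000 genes; background baseline log2-RPKM ~ N(5, 3) with
between-source SD 1.0 (log-normal abundance with a heavy upper tail, so the
1000-RPKM cutoff isolates a few dozen of the shared genes — same order of
magnitude as a real EV cohort); five planted references with baseline
uniform on [13, 15] log2 (tens of thousands of RPKM, the ACTB/GAPDH range)
and between-source SD 0.2; one variable target at baseline 8 with
between-source SD 2; replicate noise SD 0.3 (log2); dropout: below log2
abundance 1 each replicate observation is zeroed with probability 0.5,
exercising the zero-mask rule. Cq = 35 − log2(abundance) + N(0, 0.25), and
the five reference assays carry extra per-gene Cq noise of (0, 0, 0.8, 1.1,
1.4) cycles — two near-ideal assays and a ladder of increasingly unstable
ones, the worst sitting in the classical "unacceptable" zone, chosen a
priori so the stability suite has a defined truth to recover. dPCR:
copies = 10 × abundance with Poisson counting noise; 4 paired
loaded/control conditions sharing a per-condition log2 spread of SD 0.5;
fold enrichment 8. One global seed derives three independent substreams
(expression / Cq / dPCR), so regenerating one readout never perturbs the
others.

What the generator does *not* emulate: read-level sampling (no fastq, no
mapping ambiguity), fragment-length or GC bias, correlated gene modules,
amplification-efficiency drift across a plate, or dPCR partition
saturation. Passing recovery tests therefore shows the pipeline's logic is
sound under a faithful abstraction of the measurement chain — not that any
particular real cohort will yield a particular gene list.

## Problem sizes and tolerances

The test suite runs the full selection chain on 100 simulated cohorts of
5000 genes (about ten seconds), checks all stability algorithms against
independent brute-force oracles on 50 random 5 × 12 Cq tables at 1e-9
relative tolerance, and randomises 100 cases per invariance family
(per-sample Cq shifts, per-sample quantity scalings, monotone per-source
warps). Exact identities (RPKM inversion, ΔCq round trip, noise-free ρ = 1
and fold = 8) are asserted at 1e-12. The recovery thresholds — planted
references surviving selection in ≥ 95/100 seeds, geNorm's final pair
matching the two quiet references in ≥ 95/100, comprehensive top-2 in
≥ 90/100 — are properties of the frozen default conditions above, not tuned
quantities.

## Known limitations

- RPKM is the only supported abundance unit because the selection rules are
  defined on it; TPM or CPM matrices would need their own thresholds.
- The NormFinder grouped-mode estimator is a principled moment/shrinkage
  implementation of the published model, not a numerical clone of any
  particular released script; rankings agree in the regimes tested, exact
  values may differ in the third decimal.
- BestKeeper's descriptive output (index correlations, CV) follows the
  package's SD conventions; the original spreadsheet tool's exact output is
  out of scope.
- Gene length from GTF uses the merged exon span of the longest transcript —
  a convention, adequate because RPKM comparisons here are within-gene
  across samples.
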