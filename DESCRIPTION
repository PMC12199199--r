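Package: evref
Title: Selection and Validation of Reference mRNA Transcripts for
    Extracellular Vesicle Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies robust, abundant reference mRNA transcripts from
    multi-source extracellular vesicle (EV) expression data and validates
    them by RT-qPCR stability analysis and digital-PCR benchmarking.
    Implements RPKM computation with replicate zero-masking and averaging,
    per-source top-N abundance sets with cross-source intersection
    summaries, rank-sum ordering, robust-abundance and biotype filters,
    the four canonical reference-gene stability algorithms (comparative
    delta-Ct, BestKeeper, NormFinder, geNorm) with a comprehensive
    geometric-mean-of-ranks aggregation, delta-Cq and expression-ratio
    normalization with Spearman rank concordance, linear-regression
    benchmarking of relative quantification against absolute digital-PCR
    copies, and a synthetic-data generator with planted ground truth for
    end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    rtracklayer,
    IRanges,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
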