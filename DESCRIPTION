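Package: ucptx
Title: Replicate-Free Transcriptome, Pathway and Metabolite Differential
    Analysis for Uncoupling-Protein Overexpressor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the statistical pipeline used to
    compare unreplicated RNA-seq libraries from transgenic overexpressor lines
    against a wild-type control: RPKM expression with quantile normalization,
    differential-expression calling by the pooled two-proportion (Kal) Z-test
    with fold-change and p-value cutoffs and an across-line intersection rule,
    hypergeometric GO-term enrichment with Benjamini-Hochberg correction,
    a resampling-based pathway Z-score built on Enzyme Commission (EC) number
    fold changes, metabolite statistics (median normalization, log10 transform,
    Pareto scaling, volcano selection), and qPCR 2^-ddCt concordance analysis.
    A synthetic-data module generates negative-binomial count tables, GO/EC
    annotations, pathway maps, metabolite matrices and Ct tables with known
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
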