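#' Comparative-Ct relative expression
#'
#' Computes `2^-ddCt` for every target gene and sample of a Ct table, with
#' `ddCt = (Ct_target,sample - Ct_ref,sample) - (Ct_target,calib -
#' Ct_ref,calib)`. The amplification efficiency is taken as the ideal
#' doubling per cycle. The calibrator sample maps to exactly 1 for every
#' gene; the reference gene itself is not reported as a target.
#'
#' @param qpcr A `ucp_qpcr` tibble (see [qpcr_table()]).
#' @param reference_gene,calibrator Override the table's designated
#'   reference gene / calibrator sample.
#' @return A `ucp_relexpr` tibble: `gene_id`, `sample_id`, `delta_delta_ct`,
#'   `rel_expr` (fold, calibrator = 1).
#' @export
ddct <- function(qpcr, reference_gene = attr(qpcr, "reference_gene"),
                 calibrator = attr(qpcr, "calibrator")) {
  ct_of <- function(gene, sample) {
    v <- qpcr$ct[qpcr$gene_id == gene & qpcr$sample_id == sample]
    if (length(v) == 0) {
      abort(paste0("missing Ct for gene '", gene, "', sample '", sample, "'"))
    }
    mean(v) # technical replicates averaged
  }
  targets <- setdiff(unique(qpcr$gene_id), reference_gene)
  samples <- unique(qpcr$sample_id)
  out <- tidyr::expand_grid(gene_id = targets, sample_id = samples) %>%
    mutate(
      delta_delta_ct = purrr::map2_dbl(.data$gene_id, .data$sample_id, function(g, s) {
        (ct_of(g, s) - ct_of(reference_gene, s)) -
          (ct_of(g, calibrator) - ct_of(reference_gene, calibrator))
      }),
      rel_expr = 2^(-.data$delta_delta_ct)
    )
  class(out) <- c("ucp_relexpr", class(out))
  out
}

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation and its two-sided t-distribution p-value.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with non-zero variance.
#' @return A tibble with columns `r`, `p` and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("Pearson correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = unname(ct$p.value), n = length(x))
}

#' Coefficient of determination of two expression vectors
#'
#' The square of the Pearson correlation, as used for paired log-scale
#' expression of the two overexpressor lines after removing zero-count
#' genes upstream.
#'
#' @inheritParams pearson_r
#' @return A single numeric R-squared value.
#' @export
r_squared <- function(x, y) {
  pearson_r(x, y)$r^2
}

#' RNA-seq vs qPCR concordance per overexpressor line
#'
#' Joins per-gene RNA-seq log2 fold changes with qPCR relative expression
#' (log2 of 2^-ddCt) and reports the Pearson correlation per assayed sample.
#' Both axes are log-scale effect measures against the same wild-type
#' baseline.
#'
#' @param deg A `ucp_deg` tibble (one OE-vs-WT comparison) or any tibble
#'   with `gene_id` and `log2fc` columns.
#' @param relexpr A `ucp_relexpr` tibble from [ddct()].
#' @param sample Sample id of the OE line in `relexpr` to correlate; defaults
#'   to every non-calibrator sample, one row each.
#' @return A tibble: `sample_id`, `n`, `r`, `p`, `r_squared`, plus the
#'   joined per-gene scatter table in the `scatter` attribute.
#' @export
qpcr_concordance <- function(deg, relexpr, sample = NULL) {
  samples <- unique(relexpr$sample_id)
  if (!is.null(sample)) samples <- intersect(samples, sample)
  scatter <- relexpr %>%
    filter(.data$sample_id %in% samples, .data$rel_expr > 0) %>%
    mutate(qpcr_log2fc = log2(.data$rel_expr)) %>%
    dplyr::inner_join(
      tibble(gene_id = deg$gene_id, rnaseq_log2fc = deg$log2fc),
      by = "gene_id"
    )
  out <- scatter %>%
    group_by(.data$sample_id) %>%
    filter(dplyr::n() >= 3, sd(.data$qpcr_log2fc) > 0) %>%
    summarise(
      res = list(pearson_r(.data$rnaseq_log2fc, .data$qpcr_log2fc)),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res") %>%
    mutate(r_squared = .data$r^2)
  attr(out, "scatter") <- scatter
  out
}
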