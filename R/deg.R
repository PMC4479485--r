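#' RPKM expression from a count table
#'
#' Reads per kilobase of transcript per million library reads:
#' `count / ((length/1000) * (library_total/1e6))`. Library totals are taken
#' from the count table's `library_totals` attribute (column sums unless
#' supplied externally).
#'
#' @param counts A `ucp_counts` tibble (see [count_table()]).
#' @return A `ucp_expr` tibble (`gene_id` plus one RPKM column per sample)
#'   with `stage` attribute `"rpkm"`.
#' @export
#' @examples
#' ct <- count_table("g1", 1000, data.frame(s1 = 1000), library_totals = c(s1 = 1e6))
#' rpkm(ct)  # 1000 RPKM
rpkm <- function(counts) {
  totals <- library_totals(counts)
  if (is.null(totals) || any(totals <= 0)) abort("library totals must be positive")
  if (any(counts$length <= 0)) abort("gene lengths must be positive")
  out <- tibble(gene_id = counts$gene_id)
  for (s in setdiff(names(counts), c("gene_id", "length"))) {
    out[[s]] <- counts[[s]] / ((counts$length / 1000) * (totals[[s]] / 1e6))
  }
  attr(out, "stage") <- "rpkm"
  class(out) <- c("ucp_expr", class(out))
  out
}

#' Quantile-normalize an expression table
#'
#' Forces every sample to share a common distribution: each column's sorted
#' values are replaced by the across-sample mean of sorted values, preserving
#' within-column ranks; ties receive the mean of their rank positions
#' (delegated to [limma::normalizeQuantiles()]).
#'
#' @param expr A `ucp_expr` tibble with at least two sample columns.
#' @return A `ucp_expr` tibble with `stage` attribute `"quantile"`.
#' @export
quantile_normalize <- function(expr) {
  samples <- setdiff(names(expr), "gene_id")
  if (length(samples) < 2) abort("quantile normalization needs >= 2 samples")
  m <- as.matrix(expr[, samples])
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- tibble(gene_id = expr$gene_id) %>%
    dplyr::bind_cols(as_tibble(as.data.frame(qn)))
  attr(out, "stage") <- "quantile"
  class(out) <- c("ucp_expr", class(out))
  out
}

#' Kal's Z-test for two unreplicated count libraries
#'
#' Pooled two-proportion z-statistic for comparing a gene's read fraction
#' between two libraries. With `p1 = x1/N1`, `p2 = x2/N2` and pooled
#' `p0 = (x1+x2)/(N1+N2)`:
#' `Z = (p1 - p2) / sqrt(p0 (1-p0) (1/N1 + 1/N2))`, with a two-sided
#' standard-normal p-value.
#'
#' @param x1,x2 Read counts for the gene in libraries 1 and 2 (vectorized).
#' @param N1,N2 Library totals (reads), > 0.
#' @return A tibble with columns `z` and `p`.
#' @export
#' @examples
#' kal_z_test(10, 1000, 20, 2000)  # z = 0, p = 1
kal_z_test <- function(x1, N1, x2, N2) {
  if (any(N1 <= 0) || any(N2 <= 0)) abort("library totals must be positive")
  if (any(x1 < 0) || any(x2 < 0)) abort("counts must be non-negative")
  if (any(x1 + x2 == 0)) {
    abort("x1 = x2 = 0: the test is undefined; filter zero genes or pseudo-count")
  }
  p1 <- x1 / N1
  p2 <- x2 / N2
  p0 <- (x1 + x2) / (N1 + N2)
  se <- sqrt(p0 * (1 - p0) * (1 / N1 + 1 / N2))
  z <- ifelse(se == 0, ifelse(p1 == p2, 0, sign(p1 - p2) * Inf), (p1 - p2) / se)
  tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' Call differentially expressed genes for one OE-vs-WT comparison
#'
#' The test runs on raw count proportions ([kal_z_test()], with the library
#' totals of the count table) while the log2 fold change comes from the
#' supplied (typically quantile-normalized RPKM) expression table via
#' [log2_ratio()]. A gene is called `up` iff `log2fc >= log2(fc_cutoff)` and
#' `p <= p_cutoff`, `down` iff `log2fc <= -log2(fc_cutoff)` and
#' `p <= p_cutoff`, else `none`. Genes with zero counts in both compared
#' samples are excluded from testing.
#'
#' @param counts A `ucp_counts` tibble (raw counts; the test input).
#' @param expr A `ucp_expr` tibble (the fold-change input).
#' @param oe,wt Sample column names of the overexpressor and wild-type
#'   libraries.
#' @param fc_cutoff Fold-change cutoff on the linear scale (default 2, i.e.
#'   `|log2fc| >= 1`, boundary inclusive).
#' @param p_cutoff Raw p-value cutoff (default 0.001; no multiplicity
#'   adjustment at this stage).
#' @param pseudo Pseudo-count for [log2_ratio()] when one side is zero.
#' @return A `ucp_deg` tibble: `gene_id`, counts `x_oe`/`x_wt`, `z`, `p`,
#'   `log2fc`, `call` in `up`/`down`/`none`; comparison recorded in the
#'   `comparison` attribute.
#' @export
call_degs <- function(counts, expr, oe, wt, fc_cutoff = 2, p_cutoff = 0.001,
                      pseudo = 1) {
  .check_samples(counts, c(oe, wt))
  .check_samples(expr, c(oe, wt))
  totals <- library_totals(counts)
  lfc_cut <- log2(fc_cutoff)

  keep <- counts[[oe]] + counts[[wt]] > 0
  x_oe <- counts[[oe]][keep]
  x_wt <- counts[[wt]][keep]
  ztab <- kal_z_test(x_oe, totals[[oe]], x_wt, totals[[wt]])

  eidx <- match(counts$gene_id[keep], expr$gene_id)
  if (anyNA(eidx)) abort("expression table is missing genes present in the count table")
  lfc <- log2_ratio(expr[[oe]][eidx], expr[[wt]][eidx], pseudo = pseudo)

  out <- tibble(
    gene_id = counts$gene_id[keep],
    x_oe = x_oe,
    x_wt = x_wt,
    z = ztab$z,
    p = ztab$p,
    log2fc = lfc,
    call = case_when(
      .data$p <= p_cutoff & lfc >= lfc_cut ~ "up",
      .data$p <= p_cutoff & lfc <= -lfc_cut ~ "down",
      TRUE ~ "none"
    )
  )
  attr(out, "comparison") <- c(oe = oe, wt = wt)
  attr(out, "universe") <- counts$gene_id
  class(out) <- c("ucp_deg", class(out))
  out
}

#' Intersect DEG calls across the two overexpressor lines
#'
#' Only genes called in the *same* direction in both comparisons are kept;
#' genes called in opposite directions are excluded from both sets.
#'
#' @param res_a,res_b `ucp_deg` tibbles from [call_degs()] over the same gene
#'   universe.
#' @return A `ucp_deg_common` tibble with columns `gene_id` and `direction`
#'   (`up` or `down`).
#' @export
intersect_degs <- function(res_a, res_b) {
  ua <- attr(res_a, "universe")
  ub <- attr(res_b, "universe")
  if (is.null(ua) || is.null(ub) || !setequal(ua, ub)) {
    abort("the two comparisons must share the same gene universe")
  }
  sets <- function(res, dir) res$gene_id[res$call == dir]
  out <- dplyr::bind_rows(
    tibble(gene_id = intersect(sets(res_a, "up"), sets(res_b, "up")), direction = "up"),
    tibble(gene_id = intersect(sets(res_a, "down"), sets(res_b, "down")), direction = "down")
  )
  class(out) <- c("ucp_deg_common", class(out))
  out
}
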