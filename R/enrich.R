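#' Upper-tail hypergeometric probability
#'
#' Exact `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`: the chance of seeing
#' at least `k` annotated genes in a selection of `n` from a universe of `M`
#' genes of which `K` carry the annotation.
#'
#' @param M Universe size (genes).
#' @param K Universe genes carrying the term.
#' @param n Selected-set size.
#' @param k Selected genes carrying the term.
#' @return Upper-tail p-value (vectorized).
#' @export
#' @examples
#' hypergeom_tail(20, 5, 5, 5)  # 1 / choose(20, 5)
hypergeom_tail <- function(M, K, n, k) {
  if (any(k < 0) || any(k > n) || any(n > M) || any(K > M) || any(K < 0)) {
    abort("inconsistent hypergeometric counts: need 0 <= k <= n <= M and 0 <= K <= M")
  }
  phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in the
#' input order.
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

# gene -> GO long tibble restricted to a gene set
.go_long <- function(annotation, genes) {
  ann <- annotation[annotation$gene_id %in% genes, c("gene_id", "go")]
  tidyr::unnest(ann, "go") %>% distinct()
}

#' Hypergeometric GO-term enrichment
#'
#' Tests each GO term with at least one carrier in the universe for
#' over-representation in the selected gene set (typically the common up- or
#' down-regulated DEGs) against the universe of all expressed genes, with
#' Benjamini-Hochberg correction. No GO-graph propagation is performed:
#' enrichment is on the literal term sets of the annotation.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param annotation A `ucp_annotation` tibble.
#' @param universe Character vector of all expressed gene ids.
#' @param alpha Significance level for the `enriched` flag on the adjusted
#'   p-value (default 0.05).
#' @return A `ucp_enrich` tibble, one row per term: `term`, `M`, `K`, `n`,
#'   `k`, `p`, `p_adj`, `enriched`, sorted by raw p.
#' @export
enrich <- function(selected, annotation, universe, alpha = 0.05) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe)) {
    abort("selected genes must be a subset of the universe")
  }
  uni_go <- .go_long(annotation, universe)
  if (nrow(uni_go) == 0) {
    out <- tibble(
      term = character(), M = integer(), K = integer(), n = integer(),
      k = integer(), p = numeric(), p_adj = numeric(), enriched = logical()
    )
    class(out) <- c("ucp_enrich", class(out))
    return(out)
  }
  M <- length(universe)
  n_sel <- length(selected)
  counts <- uni_go %>%
    group_by(.data$go) %>%
    summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% selected),
      .groups = "drop"
    )
  out <- tibble(
    term = counts$go,
    M = M,
    K = counts$K,
    n = n_sel,
    k = counts$k,
    p = hypergeom_tail(M, counts$K, n_sel, counts$k)
  ) %>%
    mutate(p_adj = bh_adjust(.data$p), enriched = .data$p_adj < alpha) %>%
    arrange(.data$p)
  class(out) <- c("ucp_enrich", class(out))
  out
}

#' GO category counts and truncated percentages for a gene set
#'
#' Distribution of GO terms over a selected gene set, as printed in category
#' histograms: per-term transcript count and the percentage of the selected
#' set, *truncated* (toward zero) to two decimals, sorted by count
#' descending.
#'
#' @param selected Non-empty character vector of selected gene ids.
#' @param annotation A `ucp_annotation` tibble.
#' @param terms Optional character vector restricting to a term subset (e.g.
#'   the terms of one GO namespace).
#' @return A tibble with `term`, `count` and `percentage` columns.
#' @export
#' @examples
#' ann <- annotation_table(c("g1", "g2"), list("GO:0005524", "GO:0005524"),
#'                         list(character(), character()))
#' summarize_go_categories(c("g1", "g2"), ann)
summarize_go_categories <- function(selected, annotation, terms = NULL) {
  selected <- unique(selected)
  if (length(selected) == 0) abort("selected gene set must be non-empty")
  long <- .go_long(annotation, selected)
  if (!is.null(terms)) long <- long[long$go %in% terms, ]
  out <- long %>%
    group_by(.data$go) %>%
    summarise(count = dplyr::n(), .groups = "drop") %>%
    rename(term = "go")
  if (!is.null(terms)) {
    # requested terms absent from the selection are reported with count 0
    out <- tibble(term = terms) %>%
      left_join(out, by = "term") %>%
      mutate(count = dplyr::coalesce(.data$count, 0L))
  }
  out %>%
    mutate(percentage = trunc2(100 * .data$count / length(selected))) %>%
    arrange(desc(.data$count), .data$term)
}
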