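#' Tidy a DEG table
#'
#' @param x A `ucp_deg` tibble.
#' @param ... Unused.
#' @return A plain tibble with the per-gene test results.
#' @exportS3Method generics::tidy
tidy.ucp_deg <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a DEG table
#'
#' @param x A `ucp_deg` tibble.
#' @param ... Unused.
#' @return A tibble with `comparison`, `n_tested`, `n_up`, `n_down`.
#' @exportS3Method generics::glance
glance.ucp_deg <- function(x, ...) {
  cmp <- attr(x, "comparison")
  tibble(
    comparison = paste(cmp["oe"], "vs", cmp["wt"]),
    n_tested = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down")
  )
}

#' Tidy a pathway score table
#'
#' @param x A `ucp_pathway_score` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-pathway scores.
#' @exportS3Method generics::tidy
tidy.ucp_pathway_score <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of pathway scores
#'
#' @param x A `ucp_pathway_score` tibble.
#' @param ... Unused.
#' @return A tibble with `n_pathways`, `n_up`, `n_down`.
#' @exportS3Method generics::glance
glance.ucp_pathway_score <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down")
  )
}

#' Tidy an enrichment table
#'
#' @param x A `ucp_enrich` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-term enrichment rows.
#' @exportS3Method generics::tidy
tidy.ucp_enrich <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of an enrichment table
#'
#' @param x A `ucp_enrich` tibble.
#' @param ... Unused.
#' @return A tibble with `n_terms` and `n_enriched`.
#' @exportS3Method generics::glance
glance.ucp_enrich <- function(x, ...) {
  tibble(n_terms = nrow(x), n_enriched = sum(x$enriched))
}
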