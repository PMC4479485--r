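#' Per-EC log2 fold changes
#'
#' Maps EC numbers back to their coding genes and aggregates gene-level log2
#' fold changes (`log2(ExpA/ExpB)`, overexpressor over wild type, computed
#' with the shared [log2_ratio()] pseudo-count policy) to one value per EC:
#' the unweighted mean over the EC's genes. ECs with no expressed gene are
#' dropped with a warning.
#'
#' @param expr A `ucp_expr` tibble (typically quantile-normalized RPKM).
#' @param annotation A `ucp_annotation` tibble carrying the gene-to-EC sets.
#' @param oe,wt Sample column names of the compared libraries.
#' @param pseudo Pseudo-count for [log2_ratio()].
#' @return A `ucp_ecfc` tibble: `ec`, `log2fc`, `n_genes`.
#' @export
ec_fold_changes <- function(expr, annotation, oe, wt, pseudo = 1) {
  .check_samples(expr, c(oe, wt))
  ec_long <- annotation[, c("gene_id", "ec")] %>%
    tidyr::unnest("ec") %>%
    distinct()
  all_ecs <- unique(ec_long$ec)
  ec_long <- ec_long[ec_long$gene_id %in% expr$gene_id, ]
  dropped <- setdiff(all_ecs, ec_long$ec)
  if (length(dropped) > 0) {
    warn(paste0(
      "dropping EC number(s) with no expressed gene: ",
      paste(dropped, collapse = ", ")
    ))
  }
  idx <- match(ec_long$gene_id, expr$gene_id)
  ec_long$gene_fc <- log2_ratio(expr[[oe]][idx], expr[[wt]][idx], pseudo = pseudo)
  out <- ec_long %>%
    group_by(.data$ec) %>%
    summarise(log2fc = mean(.data$gene_fc), n_genes = dplyr::n(), .groups = "drop")
  class(out) <- c("ucp_ecfc", class(out))
  out
}

#' Retain pathways with enough mapped EC numbers
#'
#' A pathway is retained iff at least `min_ec` of its member ECs carry a fold
#' change ("mapped" means fold-change-bearing).
#'
#' @param pathways A `ucp_pathways` tibble.
#' @param ec_fc A `ucp_ecfc` tibble from [ec_fold_changes()].
#' @param min_ec Minimum mapped-EC count (default 5, boundary inclusive).
#' @return The retained `ucp_pathways` rows with an added `n_mapped` column.
#' @export
filter_pathways <- function(pathways, ec_fc, min_ec = 5) {
  mapped <- ec_fc$ec
  out <- pathways %>%
    mutate(n_mapped = purrr::map_int(.data$ec, ~ length(intersect(.x, mapped)))) %>%
    filter(.data$n_mapped >= min_ec)
  class(out) <- c("ucp_pathways", setdiff(class(out), "ucp_pathways"))
  out
}

#' Resampling Z-score for pathway-level differential expression
#'
#' For each retained pathway with `k` fold-change-bearing ECs, the observed
#' mean EC log2 fold change is compared with the means of `n_sets` random
#' subsets of size `k` drawn (without replacement within a set) from the pool
#' of distinct mapped ECs over all retained pathways. From the null mean and
#' standard deviation of those subset means a Z-score and a two-sided
#' normal-theory p-value are computed; an empirical-rank p-value over the
#' resampled sets is reported alongside. Positive Z marks an up-regulated
#' pathway, negative Z a down-regulated one.
#'
#' @param pathways Retained pathways (output of [filter_pathways()]).
#' @param ec_fc A `ucp_ecfc` tibble.
#' @param n_sets Number of random sets (default 100), or `"exhaustive"` to
#'   enumerate every k-subset of the pool (small pools only).
#' @param seed Optional integer seed for the resampling draws.
#' @param alpha Significance level for the direction call (default 0.05,
#'   applied to the normal-theory p).
#' @return A `ucp_pathway_score` tibble: `pathway_id`, `name`, `k`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `p`, `p_empirical`,
#'   `direction` in `up`/`down`/`ns`.
#' @export
pathway_z <- function(pathways, ec_fc, n_sets = 100, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  fc <- setNames(ec_fc$log2fc, ec_fc$ec)
  mapped_sets <- lapply(pathways$ec, function(e) intersect(e, ec_fc$ec))
  pool <- unique(unlist(mapped_sets))
  pool_fc <- fc[pool]
  exhaustive <- identical(n_sets, "exhaustive")
  if (!exhaustive && (!is.numeric(n_sets) || n_sets < 2)) {
    abort("n_sets must be >= 2 or \"exhaustive\"")
  }

  rows <- purrr::map(seq_len(nrow(pathways)), function(i) {
    ecs <- mapped_sets[[i]]
    k <- length(ecs)
    if (length(pool) <= k) {
      abort(paste0(
        "resampling pool (", length(pool), " ECs) must exceed pathway size k = ", k
      ))
    }
    observed <- mean(fc[ecs])
    if (exhaustive) {
      if (choose(length(pool), k) > 2e5) {
        abort("exhaustive enumeration requested on too large a pool")
      }
      null_means <- combn(pool_fc, k, mean)
    } else {
      null_means <- vapply(
        seq_len(n_sets),
        function(j) mean(sample(pool_fc, k, replace = FALSE)),
        numeric(1)
      )
    }
    mu <- mean(null_means)
    sdv <- sd(null_means)
    if (sdv == 0) {
      if (isTRUE(all.equal(observed, mu))) {
        z <- 0
        p <- 1
      } else {
        abort("degenerate resampling pool: null sd is 0 but observed differs from null mean")
      }
    } else {
      z <- (observed - mu) / sdv
      p <- 2 * pnorm(-abs(z))
    }
    p_emp <- (1 + sum(abs(null_means - mu) >= abs(observed - mu))) /
      (length(null_means) + 1)
    tibble(
      pathway_id = pathways$pathway_id[i],
      name = pathways$name[i],
      k = k,
      observed = observed,
      null_mean = mu,
      null_sd = sdv,
      z = z,
      p = p,
      p_empirical = p_emp
    )
  })
  out <- dplyr::bind_rows(rows) %>%
    mutate(direction = case_when(
      .data$p < alpha & .data$z > 0 ~ "up",
      .data$p < alpha & .data$z < 0 ~ "down",
      TRUE ~ "ns"
    ))
  class(out) <- c("ucp_pathway_score", class(out))
  out
}

#' Split scored pathways into up- and down-regulated lists
#'
#' Partitions pathway scores by `p < alpha` and the sign of Z.
#'
#' @param scores A `ucp_pathway_score` tibble from [pathway_z()].
#' @param alpha Significance level (default 0.05).
#' @return A list with character vectors `up` and `down` of pathway ids.
#' @export
classify_pathways <- function(scores, alpha = 0.05) {
  list(
    up = scores$pathway_id[scores$p < alpha & scores$z > 0],
    down = scores$pathway_id[scores$p < alpha & scores$z < 0]
  )
}
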