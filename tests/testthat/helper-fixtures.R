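# In-code fixtures and independent oracles shared across test files.

# tiny 3-gene x 3-sample count table
toy_counts <- function() {
  count_table(
    gene_id = c("g1", "g2", "g3"),
    length = c(1000L, 2000L, 500L),
    counts = data.frame(WT = c(10L, 0L, 5L), OE1 = c(20L, 4L, 5L), OE2 = c(18L, 3L, 6L))
  )
}

# write a tab-separated count file and return its path
write_toy_count_file <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  writeLines(lines, path)
  path
}

# a minimal ucp_deg table built by hand (for intersection-rule tests)
fake_deg <- function(gene_id, call, universe, comparison = c(oe = "OE", wt = "WT")) {
  out <- tibble::tibble(
    gene_id = gene_id,
    x_oe = 1, x_wt = 1, z = 0, p = 1, log2fc = 0,
    call = call
  )
  attr(out, "comparison") <- comparison
  attr(out, "universe") <- universe
  class(out) <- c("ucp_deg", class(out))
  out
}

# independent pooled two-proportion z via the chi-square statistic of
# prop.test (without continuity correction): z^2 == X^2, sign from p1 - p2
oracle_pooled_z <- function(x1, N1, x2, N2) {
  stat <- suppressWarnings(
    prop.test(c(x1, x2), c(N1, N2), correct = FALSE)$statistic
  )
  sign(x1 / N1 - x2 / N2) * sqrt(unname(stat))
}

# brute-force hypergeometric upper tail by summing the pmf
oracle_hyper_tail <- function(M, K, n, k) {
  j <- k:n
  sum(choose(K, j) * choose(M - K, n - j)) / choose(M, n)
}

# hand step-up BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# a per-EC fold-change table built directly
fake_ecfc <- function(ec, log2fc) {
  out <- tibble::tibble(ec = ec, log2fc = log2fc, n_genes = 1L)
  class(out) <- c("ucp_ecfc", class(out))
  out
}

# metabolite matrix built by hand, bypassing positivity validation
raw_metab <- function(vals, group = NULL) {
  vals <- as.data.frame(vals)
  n <- nrow(vals)
  if (is.null(group)) group <- rep(c("WT", "OE"), length.out = n)
  out <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    group = group
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  class(out) <- c("ucp_metab", class(out))
  out
}
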