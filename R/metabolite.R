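# the chain keeps the untransformed intensities in the "raw" attribute so the
# volcano fold change can be computed on the original scale
.keep_raw <- function(out, input) {
  raw <- attr(input, "raw")
  attr(out, "raw") <- if (is.null(raw)) input else raw
  out
}

.metab_cols <- function(m) setdiff(names(m), c("sample_id", "group"))

#' Median normalization of metabolite intensities
#'
#' Divides each sample row by its median intensity, so every row's median
#' becomes 1. This removes sample-to-sample loading/dilution differences
#' before the log transform.
#'
#' @param m A `ucp_metab` tibble (see [metabolite_matrix()]).
#' @return A `ucp_metab` tibble, same shape, `stage` attribute
#'   `"median_normalized"`.
#' @export
median_normalize <- function(m) {
  mets <- .metab_cols(m)
  vals <- as.matrix(m[, mets])
  meds <- apply(vals, 1, median)
  if (any(meds == 0)) {
    abort(paste0("zero median intensity for sample '", m$sample_id[which(meds == 0)[1]], "'"))
  }
  out <- m
  out[, mets] <- as.data.frame(vals / meds)
  attr(out, "stage") <- "median_normalized"
  .keep_raw(out, m)
}

#' Log10 transform of metabolite intensities
#'
#' @param m A `ucp_metab` tibble with strictly positive values.
#' @return A `ucp_metab` tibble of log10 intensities, `stage` attribute
#'   `"log10"`.
#' @export
log10_transform <- function(m) {
  mets <- .metab_cols(m)
  vals <- as.matrix(m[, mets])
  if (any(vals <= 0)) {
    bad <- which(vals <= 0, arr.ind = TRUE)[1, ]
    abort(paste0(
      "non-positive value at sample '", m$sample_id[bad[1]],
      "', metabolite '", mets[bad[2]], "': cannot log10-transform"
    ))
  }
  out <- m
  out[, mets] <- as.data.frame(log10(vals))
  attr(out, "stage") <- "log10"
  .keep_raw(out, m)
}

#' Pareto scaling of metabolite columns
#'
#' Per metabolite: subtract the mean and divide by the *square root* of the
#' standard deviation — intermediate between no scaling and unit-variance
#' scaling, damping the dominance of high-abundance metabolites without
#' inflating near-constant ones. After scaling each column has mean 0 and
#' variance equal to its pre-scaling standard deviation. Constant columns are
#' set to 0 with a warning. Pre-scaling means and sds are retained in the
#' `center` and `scale_sd` attributes.
#'
#' @param m A `ucp_metab` tibble with >= 2 samples.
#' @return A `ucp_metab` tibble, `stage` attribute `"pareto"`.
#' @export
pareto_scale <- function(m) {
  mets <- .metab_cols(m)
  if (nrow(m) < 2) abort("Pareto scaling needs >= 2 samples")
  vals <- as.matrix(m[, mets])
  ctr <- colMeans(vals)
  sds <- apply(vals, 2, sd)
  if (any(sds == 0)) {
    warn(paste0(
      "constant metabolite column(s) set to 0: ",
      paste(mets[sds == 0], collapse = ", ")
    ))
  }
  scaled <- sweep(vals, 2, ctr)
  scl <- ifelse(sds == 0, 1, sqrt(sds))
  scaled <- sweep(scaled, 2, scl, "/")
  scaled[, sds == 0] <- 0
  out <- m
  out[, mets] <- as.data.frame(scaled)
  attr(out, "stage") <- "pareto"
  attr(out, "center") <- ctr
  attr(out, "scale_sd") <- sds
  .keep_raw(out, m)
}

#' Run the full metabolite scaling chain
#'
#' Median normalization, then log10 transform, then Pareto scaling — in that
#' order; the chain is not commutative.
#'
#' @param m A `ucp_metab` tibble of raw intensities.
#' @return A Pareto-scaled `ucp_metab` tibble carrying the raw intensities in
#'   its `raw` attribute.
#' @export
scale_metabolites <- function(m) {
  m %>% median_normalize() %>% log10_transform() %>% pareto_scale()
}

#' Volcano selection of significant metabolites
#'
#' Per metabolite, an unpaired equal-variance two-sample t-test on the scaled
#' values gives the p-value, while the fold change is the ratio of group
#' means of the *raw* (pre-scaling) intensities. A metabolite is selected iff
#' `p < p_cutoff` and `|log2(fold change)| >= log2(fc_cutoff)`.
#'
#' @param scaled A `ucp_metab` tibble after [scale_metabolites()] (or the
#'   explicit chain); must carry two groups with >= 2 samples each.
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param fc_cutoff Fold-change cutoff on the linear scale (default 2).
#' @param raw Raw-intensity `ucp_metab` tibble; defaults to the `raw`
#'   attribute stored by the chain.
#' @param case,control Group labels of the numerator and denominator of the
#'   fold change; default the two labels in `scaled$group`, non-"WT" over
#'   "WT" when present.
#' @return A `ucp_volcano` tibble: `metabolite`, `fc`, `log2fc`, `p`,
#'   `selected`.
#' @export
volcano_select <- function(scaled, p_cutoff = 0.05, fc_cutoff = 2,
                           raw = attr(scaled, "raw"),
                           case = NULL, control = NULL) {
  groups <- unique(scaled$group)
  if (length(groups) != 2) abort("volcano selection needs exactly two groups")
  if (is.null(control)) control <- if ("WT" %in% groups) "WT" else groups[1]
  if (is.null(case)) case <- setdiff(groups, control)
  if (any(table(scaled$group) < 2)) abort("each group needs >= 2 samples for the t-test")
  if (is.null(raw)) abort("raw intensities are required for the fold change")
  mets <- .metab_cols(scaled)
  in_case <- scaled$group == case
  in_ctrl <- scaled$group == control
  raw_case <- raw$group == case
  raw_ctrl <- raw$group == control

  out <- purrr::map_dfr(mets, function(mcol) {
    a <- scaled[[mcol]][in_case]
    b <- scaled[[mcol]][in_ctrl]
    p <- if (sd(c(a, b)) == 0) 1 else unname(t.test(a, b, var.equal = TRUE)$p.value)
    fc <- mean(raw[[mcol]][raw_case]) / mean(raw[[mcol]][raw_ctrl])
    tibble(metabolite = mcol, fc = fc, log2fc = log2(fc), p = p)
  }) %>%
    mutate(selected = .data$p < p_cutoff & abs(.data$log2fc) >= log2(fc_cutoff))
  class(out) <- c("ucp_volcano", class(out))
  out
}
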