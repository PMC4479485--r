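#' Simulate a replicate-free two-genotype count table
#'
#' Emulates the study design of one pooled wild-type library and two pooled
#' overexpressor libraries sequenced without biological replicates. Baseline
#' gene abundances are drawn from a long-tailed log-normal distribution and
#' scaled to the requested library size; counts are negative-binomial with
#' the given dispersion (Poisson when `dispersion = 0`). A fraction of genes
#' is spiked at the given absolute log2 fold change, with the sign of each
#' spike drawn at random, applied identically to *both* OE samples (the two
#' OE lines act as each other's replicas). Gene lengths are uniform on
#' 197-5386 bp, the contig-length range typical of a short-read de novo
#' assembly.
#'
#' @param n_genes Number of genes (>= 50; default 5000).
#' @param library_size Expected reads per library (>= 1e4; default 5e5).
#' @param de_fraction Fraction of genes spiked as truly differential
#'   (in \[0, 0.5); default 0.05 — the universe must stay mostly null).
#' @param de_log2fc Absolute log2 fold change of spiked genes (default 2);
#'   may be a vector recycled over the spiked genes.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts. Default 0.1.
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @return A list with elements `counts` (a `ucp_counts` tibble with samples
#'   `WT`, `OE1`, `OE2`) and `truth` (a `ucp_truth` list recording the
#'   spiked genes and their signed log2 fold changes).
#' @export
simulate_counts <- function(n_genes = 5000, library_size = 5e5,
                            de_fraction = 0.05, de_log2fc = 2,
                            dispersion = 0.1, seed = 1) {
  if (n_genes < 50) abort("n_genes must be >= 50")
  if (library_size < 1e4) abort("library_size must be >= 1e4")
  if (de_fraction < 0 || de_fraction >= 0.5) {
    abort("de_fraction must lie in [0, 0.5): the universe must be mostly null")
  }
  if (dispersion < 0) abort("dispersion must be >= 0")
  set.seed(seed)

  gene_id <- sprintf("g%05d", seq_len(n_genes))
  lengths <- sample(197:5386, n_genes, replace = TRUE)
  w <- rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
  mu_wt <- library_size * w / sum(w)

  n_de <- round(n_genes * de_fraction)
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer()
  lfc <- numeric(n_genes)
  if (n_de > 0) {
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      rep_len(abs(de_log2fc), n_de)
  }
  mu_oe <- mu_wt * 2^lfc

  draw <- function(mu) {
    if (dispersion == 0) rpois(n_genes, mu) else rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  counts <- data.frame(WT = draw(mu_wt), OE1 = draw(mu_oe), OE2 = draw(mu_oe))

  truth <- structure(
    list(
      de_genes = tibble(
        gene_id = gene_id[de_idx],
        log2fc = lfc[de_idx],
        baseline_mean = mu_wt[de_idx]
      ),
      gene_ids = gene_id,
      enriched_term = NULL,
      spiked_pathway = NULL,
      pathway_shift = NULL,
      shifted_metabolites = NULL,
      seed = seed
    ),
    class = "ucp_truth"
  )
  list(counts = count_table(gene_id, lengths, counts), truth = truth)
}

#' Simulate GO/EC annotations and a pathway map with spiked signal
#'
#' Background GO terms are assigned to genes at random; one additional term
#' (the enriched term) is preferentially attached to the true differentially
#' expressed genes with probability `spike_prob`. ECs are laid out into
#' `n_pathways` pathways of `ecs_per_pathway` ECs each; the ECs of one spiked
#' pathway map to spiked up-regulated genes (so the pathway carries a
#' coordinated fold-change shift), all other ECs map to null genes. Every EC
#' maps to at least one gene.
#'
#' @param counts A `ucp_counts` tibble from [simulate_counts()].
#' @param truth The matching `ucp_truth` object (updated in the return).
#' @param n_go_terms Number of background GO terms (default 40).
#' @param go_per_gene Mean number of background GO terms per gene (default 2).
#' @param spike_prob Probability that a true DE gene carries the enriched
#'   term (default 0.9).
#' @param n_pathways Number of pathways (default 6).
#' @param ecs_per_pathway ECs per pathway (default 8; must allow the >= 5
#'   mapped-EC retention filter to keep pathways).
#' @param seed Integer seed.
#' @return A list with `annotation` (`ucp_annotation`), `pathways`
#'   (`ucp_pathways`) and the updated `truth` (fields `enriched_term`,
#'   `spiked_pathway`, `pathway_shift`: per-EC shift in log2 units).
#' @export
simulate_annotations <- function(counts, truth, n_go_terms = 40, go_per_gene = 2,
                                 spike_prob = 0.9, n_pathways = 6,
                                 ecs_per_pathway = 8, seed = 1) {
  set.seed(seed)
  genes <- counts$gene_id
  n_genes <- length(genes)
  n_ec <- n_pathways * ecs_per_pathway

  de_up <- truth$de_genes$gene_id[truth$de_genes$log2fc > 0]
  null_genes <- setdiff(genes, truth$de_genes$gene_id)
  if (length(de_up) < ecs_per_pathway) {
    abort("not enough up-regulated spiked genes to carry the spiked pathway's ECs")
  }
  if (length(null_genes) < n_ec - ecs_per_pathway) {
    abort("fewer genes than EC numbers demanded")
  }

  go_pool <- sprintf("GO:%07d", seq_len(n_go_terms))
  enriched_term <- sprintf("GO:%07d", n_go_terms + 1)
  go <- lapply(seq_len(n_genes), function(i) {
    k <- rpois(1, go_per_gene)
    sample(go_pool, min(k, n_go_terms))
  })
  names(go) <- genes
  spiked <- truth$de_genes$gene_id[runif(nrow(truth$de_genes)) < spike_prob]
  for (g in spiked) go[[g]] <- union(go[[g]], enriched_term)

  ecs <- sprintf("%d.%d.%d.%d",
    sample(1:6, n_ec, replace = TRUE),
    sample(1:20, n_ec, replace = TRUE),
    sample(1:30, n_ec, replace = TRUE),
    seq_len(n_ec)
  )
  pathway_id <- sprintf("PWY-%03d", seq_len(n_pathways))
  ec_sets <- split(ecs, rep(seq_len(n_pathways), each = ecs_per_pathway))
  spiked_pathway <- pathway_id[1]

  # spiked pathway ECs -> coordinated up-regulated genes; others -> null genes
  ec_gene <- character(n_ec)
  names(ec_gene) <- ecs
  ec_gene[ec_sets[[1]]] <- sample(de_up, ecs_per_pathway)
  other_ecs <- unlist(ec_sets[-1], use.names = FALSE)
  ec_gene[other_ecs] <- sample(null_genes, length(other_ecs))

  ec_by_gene <- split(names(ec_gene), ec_gene)
  ec <- lapply(genes, function(g) {
    v <- ec_by_gene[[g]]
    if (is.null(v)) character() else v
  })

  annotation <- annotation_table(genes, go, ec)
  pathways <- pathway_map(pathway_id, paste("pathway", seq_len(n_pathways)), unname(ec_sets))

  shift_tbl <- tibble(
    ec = ec_sets[[1]],
    shift = truth$de_genes$log2fc[match(ec_gene[ec_sets[[1]]], truth$de_genes$gene_id)]
  )
  truth$enriched_term <- enriched_term
  truth$enriched_term_genes <- spiked
  truth$spiked_pathway <- spiked_pathway
  truth$pathway_shift <- shift_tbl
  list(annotation = annotation, pathways = pathways, truth = truth)
}

#' Simulate a metabolite intensity matrix with shifted metabolites
#'
#' Log-normal intensities: each metabolite has a baseline log10 level drawn
#' uniformly on 2-5 with within-group noise of 0.15 on the log10 scale;
#' `n_shifted` metabolites differ between the groups by `shift` log10 units
#' (added to the OE group).
#'
#' @param n_metabolites Number of metabolites (default 125, the panel size
#'   of a typical GC-MS seedling profile).
#' @param n_per_group Samples per group (>= 2; default 6).
#' @param n_shifted Number of truly shifted metabolites
#'   (<= `n_metabolites`; default 2).
#' @param shift Between-group shift in log10 units (default 0.6).
#' @param noise_sd Within-group sd on the log10 scale (default 0.15).
#' @param truth Optional `ucp_truth` to update; a fresh one is created
#'   otherwise.
#' @param seed Integer seed.
#' @return A list with `metabolites` (`ucp_metab`, groups `WT`/`OE`) and the
#'   updated `truth` (field `shifted_metabolites`).
#' @export
simulate_metabolites <- function(n_metabolites = 125, n_per_group = 6,
                                 n_shifted = 2, shift = 0.6, noise_sd = 0.15,
                                 truth = NULL, seed = 1) {
  if (n_per_group < 2) abort("n_per_group must be >= 2: the t-test is undefined otherwise")
  if (n_shifted > n_metabolites) abort("n_shifted must be <= n_metabolites")
  set.seed(seed)
  mets <- sprintf("met_%03d", seq_len(n_metabolites))
  base <- runif(n_metabolites, 2, 5)
  shifted <- if (n_shifted > 0) sort(sample.int(n_metabolites, n_shifted)) else integer()
  n_samples <- 2 * n_per_group
  group <- rep(c("WT", "OE"), each = n_per_group)
  log_mu <- matrix(base, n_samples, n_metabolites, byrow = TRUE)
  log_mu[group == "OE", shifted] <- log_mu[group == "OE", shifted] + shift
  vals <- 10^(log_mu + matrix(rnorm(n_samples * n_metabolites, sd = noise_sd),
    n_samples, n_metabolites
  ))
  colnames(vals) <- mets
  m <- metabolite_matrix(
    sample_id = paste0(group, "_", rep(seq_len(n_per_group), 2)),
    group = group,
    intensities = vals
  )
  if (is.null(truth)) {
    truth <- structure(list(seed = seed), class = "ucp_truth")
  }
  truth$shifted_metabolites <- tibble(metabolite = mets[shifted], shift = shift)
  list(metabolites = m, truth = truth)
}

#' Simulate a qPCR Ct table consistent with the spiked fold changes
#'
#' Builds Ct values whose expected `2^-ddCt` equals the simulated fold
#' change: the reference gene has constant Ct across samples (up to noise),
#' and each assayed gene's OE-sample Ct is its WT Ct minus the true log2
#' fold change (one cycle per doubling). Assayed genes are drawn from the
#' spiked genes first, padded with null genes.
#'
#' @param truth A `ucp_truth` from [simulate_counts()] (needs `gene_ids` and
#'   `de_genes`).
#' @param n_genes_assayed Number of target genes on the panel (default 17,
#'   a typical validation panel size).
#' @param ct_noise_sd Measurement noise sd on each Ct (cycles, >= 0;
#'   default 0.2).
#' @param samples Sample ids; the first is the calibrator (default
#'   `c("WT", "OE1", "OE2")`).
#' @param seed Integer seed.
#' @return A `ucp_qpcr` tibble with reference gene `NtEF` and the first
#'   sample as calibrator; assayed truth recorded in the `assayed` attribute
#'   (`gene_id`, `log2fc`).
#' @export
simulate_qpcr <- function(truth, n_genes_assayed = 17, ct_noise_sd = 0.2,
                          samples = c("WT", "OE1", "OE2"), seed = 1) {
  if (ct_noise_sd < 0) abort("ct_noise_sd must be >= 0")
  set.seed(seed)
  de <- truth$de_genes
  nulls <- setdiff(truth$gene_ids, de$gene_id)
  if (n_genes_assayed > nrow(de) + length(nulls)) {
    abort("n_genes_assayed exceeds the number of available genes")
  }
  n_de <- min(nrow(de), n_genes_assayed)
  panel_de <- if (n_de > 0) de[sample.int(nrow(de), n_de), ] else de[0, ]
  n_null <- n_genes_assayed - n_de
  panel <- dplyr::bind_rows(
    panel_de[, c("gene_id", "log2fc")],
    tibble(gene_id = sample(nulls, n_null), log2fc = 0)
  )

  ref <- "NtEF"
  ct_ref_base <- 20
  ct_wt_base <- runif(n_genes_assayed, 22, 30)
  rows <- purrr::map_dfr(seq_along(samples), function(si) {
    s <- samples[si]
    fc <- if (si == 1) 0 else panel$log2fc
    tibble(
      gene_id = c(panel$gene_id, ref),
      sample_id = s,
      ct = c(ct_wt_base - fc, ct_ref_base) +
        rnorm(n_genes_assayed + 1, sd = ct_noise_sd)
    )
  })
  out <- qpcr_table(rows$gene_id, rows$sample_id, rows$ct,
    reference_gene = ref, calibrator = samples[1]
  )
  attr(out, "assayed") <- panel
  out
}

#' Write a complete synthetic input set to disk
#'
#' Generates counts, annotations, pathways, metabolites and qPCR inputs with
#' one master seed and writes them in the package's file formats plus a
#' truth table, so the whole pipeline can be exercised from files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param ... Passed to [simulate_counts()].
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(out_dir, seed = 1, ...) {
  sim <- simulate_counts(seed = seed, ...)
  ann <- simulate_annotations(sim$counts, sim$truth, seed = seed + 1)
  met <- simulate_metabolites(truth = ann$truth, seed = seed + 2)
  qp <- simulate_qpcr(met$truth, seed = seed + 3)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cts <- sim$counts
  readr::write_tsv(as_tibble(cts), file.path(out_dir, "counts.tsv"), progress = FALSE)
  ann_tab <- tibble(
    gene_id = ann$annotation$gene_id,
    go = vapply(ann$annotation$go, paste, character(1), collapse = ";"),
    ec = vapply(ann$annotation$ec, paste, character(1), collapse = ";")
  )
  readr::write_tsv(ann_tab, file.path(out_dir, "annotation.tsv"),
    col_names = FALSE, progress = FALSE
  )
  pw_tab <- tibble(
    pathway_id = ann$pathways$pathway_id,
    name = ann$pathways$name,
    ec = vapply(ann$pathways$ec, paste, character(1), collapse = ";")
  )
  readr::write_tsv(pw_tab, file.path(out_dir, "pathways.tsv"),
    col_names = FALSE, progress = FALSE
  )
  readr::write_csv(as_tibble(met$metabolites), file.path(out_dir, "metabolites.csv"),
    progress = FALSE
  )
  readr::write_tsv(as_tibble(qp), file.path(out_dir, "qpcr.tsv"), progress = FALSE)
  readr::write_tsv(met$truth$de_genes, file.path(out_dir, "truth_de_genes.tsv"),
    progress = FALSE
  )
  invisible(list(
    counts = sim$counts, truth = met$truth, annotation = ann$annotation,
    pathways = ann$pathways, metabolites = met$metabolites, qpcr = qp
  ))
}
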