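#' Construct a count table
#'
#' A count table is a tibble with a `gene_id` column, a `length` column
#' (transcript length in bp) and one non-negative integer column of read
#' counts per sample. Per-sample library totals are stored in the
#' `library_totals` attribute; by default they are the column sums, but
#' externally determined totals (e.g. total mapped reads) may be supplied.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param length Positive integer vector of per-gene lengths (bp).
#' @param counts Data frame or matrix of non-negative integer counts,
#'   genes in rows, one column per sample.
#' @param library_totals Optional named numeric vector of per-sample totals;
#'   defaults to the column sums of `counts`. Must be >= the column sums.
#' @return A `ucp_counts` tibble.
#' @export
count_table <- function(gene_id, length, counts, library_totals = NULL) {
  counts <- as.data.frame(counts)
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    abort(paste0("duplicate gene id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (length(gene_id) != nrow(counts) || length(length) != nrow(counts)) {
    abort("gene_id, length and counts must have matching dimensions")
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != round(length))) {
    abort("gene lengths must be positive integers (bp); missing lengths are an error")
  }
  for (s in names(counts)) {
    x <- counts[[s]]
    bad <- which(is.na(x) | x < 0 | x != round(x))
    if (length(bad) > 0) {
      abort(paste0(
        "invalid count at gene '", gene_id[bad[1]], "', sample '", s,
        "': counts must be non-negative integers"
      ))
    }
  }
  colsums <- vapply(counts, sum, numeric(1))
  if (is.null(library_totals)) {
    library_totals <- colsums
  } else {
    library_totals <- library_totals[names(counts)]
    if (any(is.na(library_totals)) || any(library_totals <= 0)) {
      abort("library_totals must be positive and named for every sample")
    }
    if (any(library_totals < colsums)) {
      abort("library_totals cannot be smaller than the column sums")
    }
  }
  out <- tibble(gene_id = as.character(gene_id), length = as.integer(length)) %>%
    dplyr::bind_cols(as_tibble(counts))
  attr(out, "library_totals") <- setNames(as.numeric(library_totals), names(counts))
  class(out) <- c("ucp_counts", class(out))
  out
}

#' Per-sample library totals of a count table
#' @param x A `ucp_counts` tibble.
#' @return Named numeric vector of totals (reads).
#' @export
library_totals <- function(x) attr(x, "library_totals")

#' Read a gene-level count table
#'
#' Expects a UTF-8 tab-separated file whose header row names the samples; the
#' first two columns are the gene identifier and the gene length in bp, the
#' remaining columns are integer read counts.
#'
#' @param path Path to the tab-separated file.
#' @param totals Optional named numeric vector of per-sample library totals
#'   (e.g. total mapped reads); defaults to column sums.
#' @return A `ucp_counts` tibble (see [count_table()]).
#' @export
read_count_table <- function(path, totals = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 3) abort("count table needs gene id, length and >=1 sample column")
  count_table(
    gene_id = as.character(raw[[1]]),
    length = raw[[2]],
    counts = raw[, -(1:2), drop = FALSE],
    library_totals = totals
  )
}

#' Construct a gene annotation table
#'
#' Maps gene identifiers to sets of GO terms and sets of EC numbers. Either
#' set may be empty. EC numbers must match the dotted four-field pattern
#' (partial ECs written with `-` are allowed); malformed tokens are dropped
#' with a warning.
#'
#' @param gene_id Character vector of gene identifiers (unique).
#' @param go List of character vectors of GO term ids, one per gene.
#' @param ec List of character vectors of EC numbers, one per gene.
#' @return A `ucp_annotation` tibble with list-columns `go` and `ec`.
#' @export
annotation_table <- function(gene_id, go, ec) {
  if (anyDuplicated(gene_id)) abort("duplicate gene id in annotation")
  stopifnot(length(go) == length(gene_id), length(ec) == length(gene_id))
  go <- unname(lapply(go, as.character))
  ec <- unname(lapply(ec, as.character))
  ec <- lapply(seq_along(ec), function(i) {
    v <- ec[[i]]
    ok <- .is_valid_ec(v)
    if (any(!ok)) {
      warn(paste0(
        "gene '", gene_id[i], "': skipping malformed EC token(s): ",
        paste(v[!ok], collapse = ", ")
      ))
    }
    v[ok]
  })
  out <- tibble(gene_id = as.character(gene_id), go = go, ec = ec)
  class(out) <- c("ucp_annotation", class(out))
  out
}

#' Read a gene annotation table
#'
#' Tab-separated, three columns: gene id, semicolon-joined GO term ids,
#' semicolon-joined EC numbers. Either list may be empty.
#'
#' @param path Path to the tab-separated file.
#' @return A `ucp_annotation` tibble (see [annotation_table()]).
#' @export
read_annotation <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("gene_id", "go", "ec"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  annotation_table(
    gene_id = raw$gene_id,
    go = .split_semicolon(raw$go),
    ec = .split_semicolon(raw$ec)
  )
}

#' Construct a pathway map
#'
#' @param pathway_id Character vector of unique pathway identifiers.
#' @param name Character vector of pathway names.
#' @param ec List of non-empty character vectors of member EC numbers.
#' @return A `ucp_pathways` tibble with list-column `ec`.
#' @export
pathway_map <- function(pathway_id, name, ec) {
  if (anyDuplicated(pathway_id)) {
    abort(paste0(
      "duplicate pathway id(s): ",
      paste(unique(pathway_id[duplicated(pathway_id)]), collapse = ", ")
    ))
  }
  n_ec <- vapply(ec, length, integer(1))
  if (any(n_ec == 0)) {
    abort(paste0(
      "pathway(s) with no EC numbers: ",
      paste(pathway_id[n_ec == 0], collapse = ", ")
    ))
  }
  out <- tibble(pathway_id = as.character(pathway_id), name = as.character(name), ec = ec)
  class(out) <- c("ucp_pathways", class(out))
  out
}

#' Read a pathway map
#'
#' Tab-separated, three columns: pathway id, pathway name, semicolon-joined
#' EC numbers (Gramene-style). Pathways with no EC numbers and duplicated
#' pathway ids are rejected.
#'
#' @param path Path to the tab-separated file.
#' @return A `ucp_pathways` tibble (see [pathway_map()]).
#' @export
read_pathways <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("pathway_id", "name", "ec"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  pathway_map(raw$pathway_id, raw$name, .split_semicolon(raw$ec))
}

#' Construct a metabolite intensity matrix
#'
#' Samples in rows (with a WT/OE group label), metabolites in columns,
#' strictly positive intensities in arbitrary units.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param group Character vector of group labels (e.g. "WT", "OE").
#' @param intensities Data frame or matrix of positive intensities,
#'   samples x metabolites.
#' @return A `ucp_metab` tibble (`sample_id`, `group`, metabolite columns).
#' @export
metabolite_matrix <- function(sample_id, group, intensities) {
  intensities <- as.data.frame(intensities)
  if (length(sample_id) != nrow(intensities) || length(group) != nrow(intensities)) {
    abort("sample_id, group and intensities must have matching dimensions")
  }
  for (m in names(intensities)) {
    bad <- which(is.na(intensities[[m]]) | intensities[[m]] <= 0)
    if (length(bad) > 0) {
      abort(paste0(
        "non-positive intensity at sample '", sample_id[bad[1]],
        "', metabolite '", m, "'"
      ))
    }
  }
  out <- tibble(sample_id = as.character(sample_id), group = as.character(group)) %>%
    dplyr::bind_cols(as_tibble(intensities))
  class(out) <- c("ucp_metab", class(out))
  out
}

#' Read a metabolite intensity matrix
#'
#' Comma-separated; first column sample id, second column group label
#' (WT/OE), remaining columns metabolite intensities.
#'
#' @param path Path to the CSV file.
#' @return A `ucp_metab` tibble (see [metabolite_matrix()]).
#' @export
read_metabolite_matrix <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  metabolite_matrix(
    sample_id = as.character(raw[[1]]),
    group = as.character(raw[[2]]),
    intensities = raw[, -(1:2), drop = FALSE]
  )
}

#' Construct a qPCR Ct table
#'
#' Long table of cycle-threshold measurements with a designated reference
#' (housekeeping) gene and calibrator sample.
#'
#' @param gene_id,sample_id,ct Equal-length vectors: target gene, sample and
#'   measured Ct (cycles).
#' @param reference_gene Identifier of the internal-control gene; must be
#'   measured in every sample.
#' @param calibrator Identifier of the calibrator sample (relative
#'   expression 1).
#' @return A `ucp_qpcr` tibble with attributes `reference_gene` and
#'   `calibrator`.
#' @export
qpcr_table <- function(gene_id, sample_id, ct, reference_gene, calibrator) {
  if (any(!is.finite(ct))) abort("all Ct values must be finite")
  out <- tibble(
    gene_id = as.character(gene_id),
    sample_id = as.character(sample_id),
    ct = as.numeric(ct)
  )
  samples <- unique(out$sample_id)
  ref_samples <- out$sample_id[out$gene_id == reference_gene]
  if (!all(samples %in% ref_samples)) {
    abort(paste0("reference gene '", reference_gene, "' must be measured in every sample"))
  }
  if (!calibrator %in% samples) {
    abort(paste0("calibrator sample '", calibrator, "' not present"))
  }
  attr(out, "reference_gene") <- reference_gene
  attr(out, "calibrator") <- calibrator
  class(out) <- c("ucp_qpcr", class(out))
  out
}

#' Read a qPCR Ct table
#'
#' Tab-separated, three columns with header: `gene_id`, `sample_id`, `ct`.
#'
#' @inheritParams qpcr_table
#' @param path Path to the tab-separated file.
#' @return A `ucp_qpcr` tibble (see [qpcr_table()]).
#' @export
read_qpcr_table <- function(path, reference_gene, calibrator) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  qpcr_table(raw$gene_id, raw$sample_id, raw$ct, reference_gene, calibrator)
}

#' Write result tables to a directory
#'
#' Writes each table of a named list as `<name>.tsv` (UTF-8, tab-separated,
#' full numeric precision) under `out_dir`, creating the directory if needed.
#' Column orders are those documented for each result type; re-reading with
#' [readr::read_tsv()] reproduces the numeric values to at least 6
#' significant digits.
#'
#' @param tables Named list of data frames (DEG tables, enrichment tables,
#'   pathway scores, metabolite selections, ...).
#' @param out_dir Output directory.
#' @return Invisibly, the character vector of written file paths.
#' @export
write_results <- function(tables, out_dir) {
  if (is.data.frame(tables)) tables <- list(result = tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("write_results needs a named list of tables")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    tab <- as_tibble(tables[[nm]])
    # list-columns (EC/GO sets) are serialized semicolon-joined
    for (col in names(tab)) {
      if (is.list(tab[[col]])) {
        tab[[col]] <- vapply(tab[[col]], paste, character(1), collapse = ";")
      }
    }
    readr::write_tsv(tab, p, progress = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}
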