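#' Log2 ratio with a zero-guard pseudo-count
#'
#' Computes `log2(a / b)` elementwise. Where either side is exactly zero, the
#' pseudo-count is added to *both* sides before taking the ratio, so the
#' statistic stays finite without altering well-supported ratios. This is the
#' single fold-change policy shared by the gene-level and the EC-level fold
#' changes.
#'
#' @param a,b Non-negative numeric vectors (expression values), recycled.
#' @param pseudo Pseudo-count added to both sides when either is zero
#'   (default 1 expression unit).
#' @return Numeric vector of log2 fold changes.
#' @export
#' @examples
#' log2_ratio(8, 2)   # 2
#' log2_ratio(0, 1)   # log2(1/2) = -1
log2_ratio <- function(a, b, pseudo = 1) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    abort("expression values must be non-negative")
  }
  zero <- (a == 0) | (b == 0)
  num <- ifelse(zero, a + pseudo, a)
  den <- ifelse(zero, b + pseudo, b)
  log2(num / den)
}

# Truncate (toward zero) to 2 decimals. Category percentages are reported
# truncated, not rounded; the small epsilon protects exact decimal boundaries
# from binary floating-point representation.
trunc2 <- function(x) trunc(x * 100 + 1e-9) / 100

# shared identifier-column names for count/expression tibbles
.id_cols <- function(x) intersect(c("gene_id", "length"), names(x))

.sample_cols <- function(x) setdiff(names(x), c("gene_id", "length"))

.check_samples <- function(x, samples) {
  missing <- setdiff(samples, .sample_cols(x))
  if (length(missing) > 0) {
    abort(paste0(
      "sample(s) not present in table: ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

.ec_pattern <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.(n?[0-9]+|-)$"

.is_valid_ec <- function(x) grepl(.ec_pattern, x)

.split_semicolon <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}
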