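#' Counts-per-million normalization
#'
#' Scales each sample (column) by its library size: entry (g, s) becomes
#' `count(g, s) * 1e6 / total(s)`, so every column sums to one million.
#'
#' @param counts Nonnegative gene x sample count matrix.
#' @return CPM matrix with the same dimnames and `attr(, "scale_tag") = "cpm"`.
#' @export
normalize_cpm <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  libs <- colSums(counts)
  if (any(libs == 0))
    stop("zero-library sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  cpm <- edgeR::cpm(counts, normalized.lib.sizes = FALSE, log = FALSE)
  dimnames(cpm) <- dimnames(counts)
  attr(cpm, "scale_tag") <- "cpm"
  cpm
}

#' Filter non-expressed genes
#'
#' A gene is dropped when its CPM is below `cpm_threshold` in at least
#' `fraction` of the samples (count rule: number of below-threshold samples
#' >= `fraction * m`).
#'
#' @param counts Count matrix (CPM is computed internally).
#' @param cpm_threshold CPM expression floor (default 5).
#' @param fraction Fraction of samples (default 0.8).
#' @return Integer indices of the kept genes, in original order.
#' @export
filter_nonexpressed <- function(counts, cpm_threshold = 5, fraction = 0.8) {
  stopifnot(fraction > 0, fraction <= 1)
  cpm <- normalize_cpm(counts)
  m <- ncol(counts)
  n_below <- rowSums(cpm < cpm_threshold)
  # removed iff n_below >= fraction * m, guarded against float fuzz
  keep <- which(n_below < fraction * m - 1e-9)
  if (length(keep) == 0)
    stop("all genes filtered out; lower cpm_threshold or fraction")
  log_msg("filter_nonexpressed: kept %d of %d genes (CPM<%g in >=%g of %d samples removed)",
          length(keep), nrow(counts), cpm_threshold, fraction, m)
  keep
}

#' Select high-variability genes by interquartile range
#'
#' Ranks genes by the IQR (Q3 - Q1, linear-interpolation quantiles) of
#' log2(CPM + 1) across samples and keeps the `floor(top_fraction * n)`
#' genes with the largest IQR; ties are broken by original gene order and
#' the output preserves the input row order.
#'
#' @param expr Nonnegative expression matrix on the CPM scale.
#' @param top_fraction Fraction of genes to keep, in (0, 1].
#' @return The row-subset expression matrix (values untouched).
#' @export
select_by_iqr <- function(expr, top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  n <- nrow(expr)
  n_keep <- floor(top_fraction * n)
  if (n_keep < 1) stop("top_fraction keeps zero genes")
  iqr <- apply(log2(expr + 1), 1, IQR, type = 7)
  ord <- order(-iqr, seq_len(n))          # ties -> original order
  keep <- sort(ord[seq_len(n_keep)])
  log_msg("select_by_iqr: kept %d of %d genes (top %g%% by IQR of log2(CPM+1))",
          n_keep, n, 100 * top_fraction)
  expr[keep, , drop = FALSE]
}

#' Preprocess counts into the matrix fed to NMF
#'
#' Fixed order: CPM-normalize, drop non-expressed genes, keep the top
#' IQR fraction. The factorized matrix holds CPM values (or log2(CPM+1)
#' when `config$log_transform` is set).
#'
#' @param counts Count matrix.
#' @param config An [analysis_config()].
#' @return The selected expression matrix with a `"provenance"` attribute
#'   recording gene counts before/after each step and the scale tag.
#' @export
preprocess_counts <- function(counts, config = analysis_config()) {
  validate_config(config)
  keep <- filter_nonexpressed(counts, config$cpm_threshold,
                              config$nonexpressed_fraction)
  cpm <- normalize_cpm(counts)[keep, , drop = FALSE]
  expr <- select_by_iqr(cpm, config$iqr_top_fraction)
  if (config$log_transform) {
    expr <- log2(expr + 1)
    attr(expr, "scale_tag") <- "log2cpm1"
  } else {
    attr(expr, "scale_tag") <- "cpm"
  }
  attr(expr, "provenance") <- list(
    n_input = nrow(counts),
    n_after_expression_filter = length(keep),
    n_selected = nrow(expr),
    scale_tag = attr(expr, "scale_tag")
  )
  expr
}
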