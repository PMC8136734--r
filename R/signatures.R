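#' Silhouette widths of a clustering
#'
#' For sample i with mean within-cluster distance a(i) and smallest mean
#' distance to any other cluster b(i), the silhouette is
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, computed with Euclidean
#' distance over the sample columns of `X`. Samples in singleton clusters
#' get s = 0 by convention.
#'
#' @param X Expression matrix (genes x samples); distances are between
#'   sample columns.
#' @param labels Cluster label per sample (at least 2 clusters).
#' @return Silhouette widths in \[-1, 1\], named by sample, in input order.
#' @export
silhouette_scores <- function(X, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  if (length(labels) != ncol(X)) stop("one label per sample column required")
  sil <- cluster::silhouette(labels, dist(t(X)))
  setNames(sil[, "sil_width"], colnames(X))
}

#' Core-sample mask
#'
#' Samples with positive silhouette width are "core"; outliers with
#' silhouette <= 0 (exact zero is conservatively treated as an outlier) are
#' excluded from signature and association analyses.
#'
#' @param scores Silhouette widths in \[-1, 1\].
#' @return Logical vector, TRUE for core samples.
#' @export
core_sample_mask <- function(scores) {
  stopifnot(all(scores >= -1 - 1e-9), all(scores <= 1 + 1e-9))
  scores > 0
}

#' Assemble a per-sample subtype assignment table
#'
#' @param labels Named subtype label per sample.
#' @param silhouette Silhouette width per sample (same order).
#' @return Class `subtype_assignment` data.frame: `sample_id`, `label`,
#'   `silhouette`, `is_core`.
#' @export
subtype_assignment <- function(labels, silhouette) {
  stopifnot(length(labels) == length(silhouette))
  structure(data.frame(sample_id = names(labels),
                       label = as.integer(labels),
                       silhouette = as.numeric(silhouette),
                       is_core = core_sample_mask(silhouette),
                       stringsAsFactors = FALSE),
            class = c("subtype_assignment", "data.frame"))
}

# variance per row without forming large intermediates repeatedly
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Pairwise differential expression between two subtypes
#'
#' Welch two-sample t-test per gene on log2(CPM + 1), comparing core samples
#' of subtype `pair[1]` against subtype `pair[2]`; the reported log2 fold
#' change is `log2((mean_a + 1) / (mean_b + 1))` on the CPM scale. P-values
#' are Benjamini-Hochberg adjusted across all tested genes. Genes with zero
#' variance in both groups get p = 1 when the group means are equal and
#' p = 0 (flagged `degenerate`) when they differ.
#'
#' @param X CPM matrix (genes x samples) over the tested samples' universe.
#' @param labels Subtype label per sample column (already restricted to core
#'   samples by the caller, or use `mask`).
#' @param pair Length-2 vector: the two subtype labels to compare.
#' @param mask Optional logical core-sample mask over columns.
#' @return Class `de_table` data.frame: `gene`, per-subtype means (CPM),
#'   `log2_fold_change`, `p_value`, `fdr`, `up_in`, `degenerate`.
#' @export
differential_expression <- function(X, labels, pair, mask = NULL) {
  stopifnot(length(pair) == 2)
  if (!is.null(mask)) {
    X <- X[, mask, drop = FALSE]
    labels <- labels[mask]
  }
  ia <- which(labels == pair[1]); ib <- which(labels == pair[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("need at least 2 samples per subtype")
  la <- log2(X[, ia, drop = FALSE] + 1)
  lb <- log2(X[, ib, drop = FALSE] + 1)
  n1 <- length(ia); n2 <- length(ib)
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  v1 <- row_vars(la); v2 <- row_vars(lb)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  mean_a <- rowMeans(X[, ia, drop = FALSE])
  mean_b <- rowMeans(X[, ib, drop = FALSE])
  out <- data.frame(
    gene = rownames(X),
    mean_a = mean_a, mean_b = mean_b,
    log2_fold_change = log2((mean_a + 1) / (mean_b + 1)),
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
    up_in = ifelse(mean_a >= mean_b, pair[1], pair[2]),
    degenerate = degen,
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(out)[names(out) == "mean_a"] <- paste0("mean_", pair[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", pair[2])
  attr(out, "pair") <- pair
  class(out) <- c("de_table", "data.frame")
  out
}

#' Define per-subtype signature genes
#'
#' Keeps genes passing both gates — `|log2FC| >= log2(fc_cutoff)` and
#' `FDR <= fdr_cutoff` — from one or more pairwise differential-expression
#' tables (for more than two subtypes, a gene qualifies if it passes any
#' pair), and assigns each kept gene to the subtype in which its mean CPM
#' over core samples is highest, so the per-subtype lists are disjoint.
#' Lists are ordered by ascending FDR.
#'
#' @param de A `de_table` or list of `de_table`s from
#'   [differential_expression()].
#' @param fc_cutoff Linear fold-change gate (> 1).
#' @param fdr_cutoff FDR gate in (0, 1).
#' @param X CPM matrix used for the highest-mean assignment.
#' @param labels Subtype label per column of `X` (core samples).
#' @param mask Optional logical core mask over columns of `X`.
#' @return Class `signature_set`: list with `signatures` (per-subtype
#'   data.frames: `gene`, `log2_fold_change`, `fdr`) and `universe`.
#' @export
define_signatures <- function(de, fc_cutoff = 1.5, fdr_cutoff = 0.05,
                              X = NULL, labels = NULL, mask = NULL) {
  stopifnot(fc_cutoff > 1, fdr_cutoff > 0, fdr_cutoff < 1)
  if (inherits(de, "de_table")) de <- list(de)
  if (!is.null(mask)) {
    X <- X[, mask, drop = FALSE]
    labels <- labels[mask]
  }
  hits <- lapply(de, function(d)
    d[abs(d$log2_fold_change) >= log2(fc_cutoff) & d$fdr <= fdr_cutoff,
      c("gene", "log2_fold_change", "fdr")])
  hits <- do.call(rbind, hits)
  # a gene passing several pairs keeps its smallest-FDR record
  hits <- hits[order(hits$fdr), , drop = FALSE]
  hits <- hits[!duplicated(hits$gene), , drop = FALSE]
  subtypes <- sort(unique(as.integer(labels)))
  group_means <- vapply(subtypes, function(t)
    rowMeans(X[, labels == t, drop = FALSE]), numeric(nrow(X)))
  rownames(group_means) <- rownames(X)
  assigned <- subtypes[max.col(group_means[hits$gene, , drop = FALSE],
                               ties.method = "first")]
  sigs <- lapply(subtypes, function(t) {
    s <- hits[assigned == t, , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  names(sigs) <- as.character(subtypes)
  empty <- names(sigs)[vapply(sigs, nrow, integer(1)) == 0]
  if (length(empty))
    warning("empty signature for subtype(s): ", paste(empty, collapse = ", "))
  structure(list(signatures = sigs, universe = rownames(X)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Signature set over", length(x$universe), "genes:\n")
  for (nm in names(x$signatures))
    cat(sprintf("  subtype %s: %d gene(s)\n", nm, nrow(x$signatures[[nm]])))
  invisible(x)
}

#' All signature genes of a signature set
#'
#' @param signatures A `signature_set`.
#' @return Character vector of signature genes (subtype blocks concatenated).
#' @export
signature_genes <- function(signatures) {
  unlist(lapply(signatures$signatures, `[[`, "gene"), use.names = FALSE)
}

#' Discovery pipeline: preprocess, cluster, filter, and define signatures
#'
#' Runs the full subtype-discovery chain on a count matrix: CPM
#' normalization and gene filtering, consensus NMF over the candidate
#' cluster numbers with cophenetic model selection, silhouette-based core
#' sample filtering, pairwise differential expression among core samples,
#' and signature definition.
#'
#' @param counts Gene x sample count matrix.
#' @param config An [analysis_config()].
#' @return Class `subtype_discovery`: list with `expr` (factorized matrix),
#'   `cpm` (CPM of expression-filtered genes, the DE universe), `consensus`
#'   (a `consensus_selection`), `k`, `assignment` (a `subtype_assignment`),
#'   `de` (list of pairwise `de_table`s) and `signatures`.
#' @export
subtype_discovery <- function(counts, config = analysis_config()) {
  validate_config(config)
  expr <- preprocess_counts(counts, config)
  keep <- filter_nonexpressed(counts, config$cpm_threshold,
                              config$nonexpressed_fraction)
  cpm <- normalize_cpm(counts)[keep, , drop = FALSE]
  sel <- consensus_cluster(expr, config)
  labels <- sel$labels
  sil <- silhouette_scores(expr, labels)
  assign <- subtype_assignment(labels, sil)
  subtypes <- sort(unique(labels))
  pairs <- utils::combn(subtypes, 2, simplify = FALSE)
  de <- lapply(pairs, function(p)
    differential_expression(cpm, labels, p, mask = assign$is_core))
  sigs <- define_signatures(de, config$fc_cutoff, config$fdr_cutoff,
                            X = cpm, labels = labels, mask = assign$is_core)
  structure(list(expr = expr, cpm = cpm, consensus = sel, k = sel$k,
                 assignment = assign, de = de, signatures = sigs,
                 config = config),
            class = "subtype_discovery")
}
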