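#' Project discovery signature genes onto an independent dataset
#'
#' Restricts the new expression matrix to the signature genes (signature
#' order preserved). Unmatched signature genes are listed and warned about;
#' fewer than 50% matched is an error, since the projection is then not
#' meaningful. When the input contains negative values (e.g. log-ratio
#' microarray scales), each gene row is min-shifted so its minimum is
#' exactly 0, preserving within-gene rank order while meeting the
#' nonnegativity required by NMF.
#'
#' @param expr_new Gene x sample expression matrix of the independent
#'   dataset (same gene identifier namespace as the signatures).
#' @param signatures A `signature_set` from [define_signatures()].
#' @return Class `projected_dataset`: list with `matrix` (nonnegative
#'   signature-gene x sample), `matched_genes`, `missing_genes`,
#'   `source_scale_tag`.
#' @export
project_signatures <- function(expr_new, signatures) {
  genes <- signature_genes(signatures)
  matched <- genes[genes %in% rownames(expr_new)]
  missing <- setdiff(genes, matched)
  if (length(matched) < 0.5 * length(genes))
    stop(sprintf("only %d of %d signature genes matched (<50%%); projection not meaningful",
                 length(matched), length(genes)))
  if (length(missing))
    warning(length(missing), " signature gene(s) absent from the new dataset: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  m <- expr_new[matched, , drop = FALSE]
  tag <- "asis"
  if (any(m < 0)) {
    mins <- apply(m, 1, min)
    m <- m - pmin(mins, 0)          # per-gene min-shift, only where negative
    tag <- "minshifted"
  }
  structure(list(matrix = m, matched_genes = matched,
                 missing_genes = missing, source_scale_tag = tag),
            class = "projected_dataset")
}

#' Consensus-cluster a projected dataset
#'
#' Runs the consensus NMF machinery on the signature-projected matrix over
#' the configured candidate cluster numbers and selects k by cophenetic
#' coefficient.
#'
#' @param proj A `projected_dataset`.
#' @param config An [analysis_config()].
#' @return A `consensus_selection` (see [consensus_cluster()]).
#' @export
cluster_projected <- function(proj, config = analysis_config()) {
  stopifnot(inherits(proj, "projected_dataset"))
  if (ncol(proj$matrix) < 3) stop("need at least 3 samples")
  consensus_cluster(proj$matrix, config)
}

#' Assign discovery subtype identities to validation clusters
#'
#' Scores every (cluster, subtype) pair as the mean — over the cluster's
#' samples — of the mean per-gene standardized expression of that subtype's
#' signature genes, then matches clusters to subtypes one-to-one, greedily
#' taking the highest remaining score (ties broken by subtype order). The
#' score matrix is returned so the call is auditable.
#'
#' @param proj A `projected_dataset`.
#' @param labels Cluster label per sample of the projected matrix.
#' @param signatures The discovery `signature_set`.
#' @return List with `map` (named character: cluster -> subtype name),
#'   `score_matrix` (clusters x subtypes), and `sample_subtype` (subtype
#'   name per sample).
#' @export
assign_subtype_identity <- function(proj, labels, signatures) {
  stopifnot(inherits(proj, "projected_dataset"))
  clusters <- sort(unique(as.integer(labels)))
  subtypes <- names(signatures$signatures)
  if (length(clusters) != length(subtypes))
    stop("number of clusters (", length(clusters),
         ") must equal number of subtypes (", length(subtypes), ")")
  Z <- standardize_rows(proj$matrix)
  score <- matrix(NA_real_, length(clusters), length(subtypes),
                  dimnames = list(as.character(clusters), subtypes))
  for (t in subtypes) {
    g <- intersect(signatures$signatures[[t]]$gene, rownames(Z))
    if (!length(g)) stop("no matched signature genes for subtype ", t)
    per_sample <- colMeans(Z[g, , drop = FALSE])
    for (cl in clusters)
      score[as.character(cl), t] <- mean(per_sample[labels == cl])
  }
  # greedy one-to-one matching on the score matrix
  map <- setNames(character(length(clusters)), as.character(clusters))
  s <- score
  for (step in seq_along(clusters)) {
    best <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, "row"], best[, "col"]), , drop = FALSE][1, ]
    map[rownames(s)[best["row"]]] <- colnames(s)[best["col"]]
    s[best["row"], ] <- NA
    s[, best["col"]] <- NA
    if (all(is.na(s))) break
  }
  list(map = map,
       score_matrix = score,
       sample_subtype = setNames(unname(map[as.character(labels)]),
                                 colnames(proj$matrix)))
}

# per-gene z-score; constant rows become 0 (display/score scale only)
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  z
}

#' Signature-gene heatmap of a (re-)clustered dataset
#'
#' Draws per-gene standardized expression (display scale only) with genes
#' grouped by signature subtype and samples grouped by cluster, with row and
#' column annotation bars, and writes the figure to `out_path` (PNG or
#' other extension understood by pheatmap).
#'
#' @param proj A `projected_dataset` (or any expression matrix restricted to
#'   signature genes).
#' @param labels Cluster label per sample.
#' @param signatures The `signature_set` used for grouping.
#' @param out_path Output figure path.
#' @return Invisibly, `out_path`.
#' @export
plot_signature_heatmap <- function(proj, labels, signatures, out_path) {
  m <- if (inherits(proj, "projected_dataset")) proj$matrix else proj
  gene_grp <- unlist(lapply(names(signatures$signatures), function(t)
    setNames(rep(t, nrow(signatures$signatures[[t]])),
             signatures$signatures[[t]]$gene)))
  gene_grp <- gene_grp[names(gene_grp) %in% rownames(m)]
  genes <- names(gene_grp)[order(gene_grp)]
  samples <- colnames(m)[order(labels)]
  Z <- standardize_rows(m)[genes, samples, drop = FALSE]
  Z[Z > 3] <- 3; Z[Z < -3] <- -3
  ann_row <- data.frame(signature = gene_grp[genes], row.names = genes)
  ann_col <- data.frame(cluster = factor(sort(labels)),
                        row.names = samples)
  pheatmap::pheatmap(Z, cluster_rows = FALSE, cluster_cols = FALSE,
                     annotation_row = ann_row, annotation_col = ann_col,
                     show_rownames = FALSE, show_colnames = FALSE,
                     filename = out_path, silent = TRUE)
  invisible(out_path)
}
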