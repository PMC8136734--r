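#' Consensus-matrix heatmap
#'
#' Draws the consensus matrix with samples in dendrogram leaf order, the
#' standard display for judging clustering stability (crisp blocks near 0/1
#' indicate a stable k).
#'
#' @param res A `consensus_result`.
#' @param out_path Output figure path (extension chooses the device).
#' @return Invisibly, `out_path`.
#' @export
plot_consensus_heatmap <- function(res, out_path) {
  ord <- res$leaf_order
  ann <- data.frame(cluster = factor(res$consensus_labels[ord]),
                    row.names = colnames(res$C)[ord])
  pheatmap::pheatmap(res$C[ord, ord], cluster_rows = FALSE,
                     cluster_cols = FALSE, annotation_col = ann,
                     show_rownames = FALSE, show_colnames = FALSE,
                     main = sprintf("k = %d (rho = %.3f)", res$k, res$rho),
                     filename = out_path, silent = TRUE)
  invisible(out_path)
}

#' Cophenetic-coefficient curve
#'
#' Line plot of the cophenetic correlation against the candidate number of
#' clusters; the selected k maximizes the curve.
#'
#' @param rho Named numeric vector (names = k).
#' @param out_path Output PNG path.
#' @return Invisibly, `out_path`.
#' @export
plot_rho_curve <- function(rho, out_path) {
  grDevices::png(out_path, width = 600, height = 450)
  on.exit(grDevices::dev.off())
  k <- as.integer(names(rho))
  plot(k, rho, type = "b", pch = 19, xlab = "number of clusters k",
       ylab = "cophenetic correlation", xaxt = "n")
  graphics::axis(1, at = k)
  invisible(out_path)
}

#' Per-sample silhouette plot
#'
#' Barplot of silhouette widths grouped by subtype and sorted within group,
#' marking the zero line that separates core samples from outliers.
#'
#' @param assign A `subtype_assignment`.
#' @param out_path Output PNG path.
#' @return Invisibly, `out_path`.
#' @export
plot_silhouette <- function(assign, out_path) {
  grDevices::png(out_path, width = 700, height = 450)
  on.exit(grDevices::dev.off())
  ord <- order(assign$label, -assign$silhouette)
  cols <- grDevices::hcl.colors(max(assign$label), "Dark 3")
  graphics::barplot(assign$silhouette[ord], col = cols[assign$label[ord]],
                    border = NA, ylab = "silhouette width",
                    xlab = "samples (grouped by subtype)")
  graphics::abline(h = 0)
  graphics::legend("topright", legend = paste("subtype", sort(unique(assign$label))),
                   fill = cols[sort(unique(assign$label))], bty = "n")
  invisible(out_path)
}
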