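#' Connectivity matrix of a hard clustering
#'
#' @param labels One cluster label per sample.
#' @return Binary m x m matrix with entry (i, j) = 1 iff samples i and j
#'   share a label; symmetric with unit diagonal.
#' @export
connectivity_matrix <- function(labels) {
  cm <- 1 * outer(labels, labels, `==`)
  dimnames(cm) <- list(names(labels), names(labels))
  cm
}

#' Consensus matrix over repeated NMF runs
#'
#' Runs `n_runs` randomly initialized NMF fits at rank `k` and averages their
#' connectivity matrices: entry (i, j) of the consensus matrix `C` estimates
#' the probability that samples i and j cluster together. Consensus labels
#' come from cutting the average-linkage tree of the distance `1 - C` into
#' `k` groups, so the reported clustering is a deterministic function of `C`.
#' Run r at rank k uses seed `base_seed + k * 1e6 + r` (disjoint seed
#' streams per k).
#'
#' @param A Nonnegative expression matrix (genes x samples).
#' @param k Number of clusters.
#' @param n_runs Number of NMF runs (default 40).
#' @param base_seed Base seed.
#' @param max_iter,tol Passed to [nmf_fit()].
#' @return An object of class `consensus_result`: `k`, `C`, `rho`
#'   (cophenetic coefficient), `consensus_labels`, `run_seeds`,
#'   `run_labels` (per-run argmax labels, for diagnostics), `leaf_order`
#'   (dendrogram leaf permutation for heatmaps).
#' @export
consensus_matrix <- function(A, k, n_runs = 40L, base_seed = 1L,
                             max_iter = 2000L, tol = 1e-6) {
  stopifnot(n_runs >= 1)
  m <- ncol(A)
  seeds <- as.integer(base_seed + k * 1e6 + seq_len(n_runs))
  stopifnot(all(seeds < .Machine$integer.max))
  Csum <- matrix(0, m, m)
  run_labels <- matrix(NA_integer_, n_runs, m)
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(nmf_fit(A, k, seed = seeds[r], max_iter = max_iter, tol = tol),
                    error = function(e) stop("NMF run ", r, " (k=", k, ") failed: ",
                                             conditionMessage(e)))
    lab <- assign_clusters(fit$H)
    run_labels[r, ] <- lab
    Csum <- Csum + connectivity_matrix(lab)
  }
  C <- Csum / n_runs
  dimnames(C) <- list(colnames(A), colnames(A))
  hc <- hclust(as.dist(1 - C), method = "average")
  res <- structure(list(
    k = as.integer(k),
    C = C,
    rho = cophenetic_coefficient(C),
    consensus_labels = setNames(as.integer(cutree(hc, k)), colnames(A)),
    run_seeds = seeds,
    run_labels = run_labels,
    leaf_order = hc$order
  ), class = "consensus_result")
  log_msg("consensus_matrix: k=%d, %d runs, rho=%.4f", k, n_runs, res$rho)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus over %d NMF runs, k = %d: rho = %.4f; cluster sizes: %s\n",
              length(x$run_seeds), x$k, x$rho,
              paste(table(x$consensus_labels), collapse = ", ")))
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Pearson correlation between the consensus-induced pairwise distances
#' `1 - C` (off-diagonal pairs) and the cophenetic distances of their
#' average-linkage dendrogram. Values near 1 indicate that the dendrogram —
#' and hence a discrete clustering — faithfully represents the consensus.
#'
#' @param C Symmetric consensus matrix with unit diagonal, at least 3
#'   samples.
#' @return The coefficient in \[-1, 1\], or `NA` (with a warning) when the
#'   pairwise distances have zero variance and the coefficient is undefined.
#' @export
cophenetic_coefficient <- function(C) {
  if (!isSymmetric(unname(C), tol = 1e-8)) stop("C must be symmetric")
  if (nrow(C) < 3) stop("need at least 3 samples")
  d <- as.dist(1 - C)
  if (sd(d) == 0 ) {
    warning("all pairwise consensus distances identical; cophenetic coefficient undefined")
    return(NA_real_)
  }
  hc <- hclust(d, method = "average")
  t <- cophenetic(hc)
  if (sd(t) == 0) {
    warning("degenerate dendrogram (all cophenetic distances equal)")
    return(NA_real_)
  }
  cor(as.vector(d), as.vector(t))
}

#' Choose the number of clusters from cophenetic coefficients
#'
#' @param results List of `consensus_result` objects (one per candidate k).
#' @return The smallest k achieving the maximal cophenetic coefficient;
#'   candidates with undefined coefficients are excluded with a warning.
#' @export
select_k <- function(results) {
  stopifnot(length(results) >= 2)
  ks <- vapply(results, `[[`, integer(1), "k")
  rhos <- vapply(results, `[[`, numeric(1), "rho")
  ord <- order(ks)
  ks <- ks[ord]; rhos <- rhos[ord]
  if (anyNA(rhos)) {
    warning("excluding k with undefined cophenetic coefficient: ",
            paste(ks[is.na(rhos)], collapse = ", "))
    ks <- ks[!is.na(rhos)]; rhos <- rhos[!is.na(rhos)]
  }
  if (!length(ks)) stop("no candidate k has a defined cophenetic coefficient")
  unname(ks[which.max(rhos)])   # first max -> smallest k on ties
}

#' Consensus clustering over candidate cluster numbers
#'
#' Builds a consensus matrix for every candidate k and selects the best k by
#' cophenetic coefficient.
#'
#' @param A Nonnegative expression matrix.
#' @param config An [analysis_config()] (supplies `k_candidates`,
#'   `n_nmf_runs`, `base_seed`, `max_iter`, `tol`).
#' @return Class `consensus_selection`: list with `results` (named by k),
#'   `rho` (named vector), `k` (selected), and `labels` (consensus labels at
#'   the selected k).
#' @export
consensus_cluster <- function(A, config = analysis_config()) {
  validate_config(config)
  results <- lapply(config$k_candidates, function(k)
    consensus_matrix(A, k, n_runs = config$n_nmf_runs,
                     base_seed = config$base_seed,
                     max_iter = config$max_iter, tol = config$tol))
  names(results) <- config$k_candidates
  k_sel <- select_k(results)
  structure(list(
    results = results,
    rho = vapply(results, `[[`, numeric(1), "rho"),
    k = k_sel,
    labels = results[[as.character(k_sel)]]$consensus_labels
  ), class = "consensus_selection")
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat("Consensus NMF model selection\n")
  for (kk in names(x$results))
    cat(sprintf("  k = %s: rho = %.4f%s\n", kk, x$rho[[kk]],
                if (as.integer(kk) == x$k) "  <- selected" else ""))
  invisible(x)
}
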