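#' Generalized Kullback-Leibler divergence of a factorization
#'
#' The divergence cost minimized by the multiplicative updates:
#' `D = sum_ij ( A_ij log(A_ij / (WH)_ij) - A_ij + (WH)_ij )`,
#' with the convention that a term with `A_ij = 0` contributes `(WH)_ij`,
#' and `(WH)_ij` clamped below at a tiny epsilon (1e-12 relative to the
#' matrix scale) before the log.
#'
#' @param A Nonnegative gene x sample matrix.
#' @param W,H Nonnegative factor matrices (n x k and k x m).
#' @return The divergence, a nonnegative scalar.
#' @export
#' @examples
#' kl_divergence(matrix(2), matrix(1), matrix(1))  # 2*log(2) - 1
kl_divergence <- function(A, W, H) {
  if (nrow(W) != nrow(A) || ncol(H) != ncol(A) || ncol(W) != nrow(H))
    stop("shape mismatch between A, W, H")
  if (any(A < 0) || any(W < 0) || any(H < 0))
    stop("A, W, H must be nonnegative")
  eps <- 1e-12 * max(mean(A), .Machine$double.xmin)
  WH <- pmax(W %*% H, eps)
  pos <- A > 0
  sum(WH) - sum(A) + sum(A[pos] * log(A[pos] / WH[pos]))
}

#' Fit divergence-based NMF by multiplicative updates
#'
#' Decomposes the nonnegative matrix `A` (n genes x m samples) as
#' `A ~ W H` with `W` (n x k) and `H` (k x m) nonnegative, by the
#' divergence-form multiplicative update rules: each iteration updates `H`
#' (using the current `W`), then `W` (using the freshly updated `H`).
#' Entries of `W` and `H` are initialized i.i.d. uniform(0, 1) scaled by
#' `mean(A)/k` from a seeded generator, so the fit is deterministic given
#' the seed. The divergence is recorded at initialization and after every
#' iteration and is non-increasing; the fit stops at `max_iter` or when the
#' relative decrease of the divergence over 10 consecutive iterations falls
#' below `tol`.
#'
#' @param A Nonnegative matrix with no all-zero column.
#' @param k Factorization rank (number of clusters), >= 1.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of iterations.
#' @param tol Relative-decrease convergence tolerance.
#' @return An object of class `nmf_fit`: list with `W`, `H`,
#'   `divergence_trace`, `seed`, `k`, `n_iter`, `converged`.
#' @export
nmf_fit <- function(A, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  stopifnot(k >= 1, max_iter >= 1, tol > 0)
  if (any(A < 0)) stop("A must be nonnegative")
  if (any(colSums(A) == 0)) stop("A has all-zero column(s)")
  n <- nrow(A); m <- ncol(A)
  scale <- mean(A) / k
  init <- withr::with_seed(seed, list(
    W = matrix(runif(n * k), n, k) * scale,
    H = matrix(runif(k * m), k, m) * scale
  ))
  eps <- 1e-12 * max(mean(A), .Machine$double.xmin)
  res <- nmf_kl_run(A, init$W, init$H, as.integer(max_iter), tol, 10L, eps)
  dimnames(res$W) <- list(rownames(A), NULL)
  dimnames(res$H) <- list(NULL, colnames(A))
  structure(list(W = res$W, H = res$H,
                 divergence_trace = res$divergence_trace,
                 seed = as.integer(seed), k = as.integer(k),
                 n_iter = res$n_iter, converged = res$converged),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: %d x %d, k = %d, %d iteration(s), %s (final D = %.6g)\n",
              nrow(x$W), ncol(x$H), x$k, x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$divergence_trace[length(x$divergence_trace)]))
  invisible(x)
}

#' Hard cluster assignment from the H matrix
#'
#' Each sample's cluster is the row index of the maximal entry in its column
#' of `H`; ties go to the smallest row index. Labels are 1-based.
#'
#' @param H Nonnegative k x m loading matrix (or an `nmf_fit`).
#' @return Integer labels in 1..k, named by sample when `H` has column names.
#' @export
assign_clusters <- function(H) {
  if (inherits(H, "nmf_fit")) H <- H$H
  if (any(H < 0)) stop("H must be nonnegative")
  zero <- colSums(H) == 0
  if (any(zero))
    stop("all-zero H column(s): cluster membership undefined for sample(s) ",
         paste(which(zero), collapse = ", "))
  labels <- max.col(t(H), ties.method = "first")
  names(labels) <- colnames(H)
  labels
}
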