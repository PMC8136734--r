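# shared fixtures: tiny planted-structure cohorts and hand-built matrices

# counts whose CPM equals the raw count: a "ballast" gene tops every column
# up to 1e6 so library sizes are exactly 1e6
counts_with_unit_cpm <- function(m) {
  ballast <- 1e6 - colSums(m)
  stopifnot(all(ballast >= 0))
  out <- rbind(m, ballast = ballast)
  rownames(out) <- c(rownames(m), "ballast")
  out
}

small_cohort <- function(seed = 7, log2fc = 2, n_genes = 300, n_samples = 60,
                         n_sig = 30) {
  spec <- simulation_spec(n_genes = n_genes, n_samples = n_samples,
                          n_signature_genes_per_subtype = n_sig,
                          signature_log2fc = log2fc, seed = seed)
  suppressMessages(simulate_counts(spec))
}

quick_config <- function(...) {
  analysis_config(n_nmf_runs = 8, k_candidates = 2:3, iqr_top_fraction = 0.5,
                  base_seed = 11, ...)
}

# brute-force silhouette oracle, straight from the defining formulas
silhouette_brute <- function(X, labels) {
  m <- ncol(X)
  d <- as.matrix(dist(t(X)))
  vapply(seq_len(m), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k)
      mean(d[i, labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}
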