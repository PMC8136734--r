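#' Exact test of independence for an r x c contingency table
#'
#' Freeman-Halton generalization of Fisher's exact test: conditioning on
#' both margins, the two-sided p-value is the total multivariate
#' hypergeometric probability of all tables whose probability does not
#' exceed that of the observed table (with the customary `1 + 1e-7`
#' relative float tolerance — the probability-ordering rule that reproduces
#' standard statistical-environment output). All-zero rows and columns are
#' dropped first (they cannot affect the exact test). Tables are enumerated
#' exactly by depth-first iteration over feasible row fills when the table
#' space is small enough; otherwise the p-value is estimated from
#' margin-preserving Monte-Carlo draws, with a reported standard error.
#'
#' @param tab Integer matrix of counts (r x c).
#' @param max_tables Enumerate exactly when an upper bound on the number of
#'   margin-compatible tables is below this (default 1e7).
#' @param mc_draws Monte-Carlo sample size for larger tables (default 1e6).
#' @param seed Seed for the Monte-Carlo branch (deterministic given seed).
#' @return List with `p_value`, `method` (`"enumeration"` or
#'   `"monte_carlo"`), `mc_se` (NA for enumeration), and the reduced
#'   `table`.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(12, 9, 5, 2, 46, 55), ncol = 2, byrow = TRUE))
fisher_exact_rxc <- function(tab, max_tables = 1e7, mc_draws = 1e6,
                             seed = 1L) {
  tab <- as.matrix(tab)
  if (any(abs(tab - round(tab)) > 1e-8)) stop("non-integer counts")
  if (any(tab < 0)) stop("negative counts")
  storage.mode(tab) <- "integer"
  if (sum(tab) == 0) stop("empty table")
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c))
    log_msg("fisher_exact_rxc: dropping %d all-zero row(s), %d all-zero column(s)",
            sum(!keep_r), sum(!keep_c))
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate table (single nonzero row or column); p = 1")
    return(list(p_value = 1, method = "degenerate", mc_se = NA_real_,
                table = tab))
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  # upper bound on the table space: independent fills of the first c-1 cells
  # of every row
  bound <- prod(vapply(rs, function(r)
    prod(pmin(r, cs[-length(cs)]) + 1), numeric(1)))
  if (is.finite(bound) && bound <= max_tables) {
    p <- fisher_rxc_enumerate(tab, 1e-7)
    return(list(p_value = p, method = "enumeration", mc_se = NA_real_,
                table = tab))
  }
  lp <- withr::with_seed(seed, table_log_prob(r2dtable(mc_draws, rs, cs)))
  lp_obs <- table_log_prob(list(tab))
  p <- mean(lp <= lp_obs + log1p(1e-7))
  list(p_value = p, method = "monte_carlo",
       mc_se = sqrt(p * (1 - p) / mc_draws), table = tab)
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-sided t-test with pooled variance; missing values are
#' excluded pairwise. Degenerate inputs (zero pooled variance) give p = 1
#' when the group means are equal and p = 0 (flagged) when they differ.
#'
#' @param values Numeric vector.
#' @param groups Vector with exactly two distinct non-missing levels
#'   aligned with `values`.
#' @return List with `p_value`, `t`, `df`, `means` (named group means),
#'   `n_used`, `degenerate`.
#' @export
two_sample_t <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required, got ", length(lev))
  x <- values[groups == lev[1]]; y <- values[groups == lev[2]]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 non-missing values per group")
  m1 <- mean(x); m2 <- mean(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  means <- setNames(c(m1, m2), lev)
  if (sp2 == 0) {
    return(list(p_value = if (m1 == m2) 1 else 0, t = NA_real_,
                df = n1 + n2 - 2, means = means, n_used = n1 + n2,
                degenerate = TRUE))
  }
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(p_value = 2 * pt(-abs(tstat), n1 + n2 - 2), t = tstat,
       df = n1 + n2 - 2, means = means, n_used = n1 + n2,
       degenerate = FALSE)
}

#' Subtype-covariate association report
#'
#' Tests every declared metadata column against the subtype label: exact
#' contingency-table test for categorical columns, pooled-variance t-test
#' for continuous columns (two subtypes). Missing metadata values are
#' excluded pairwise per test. Also reports, per categorical level, the
#' per-subtype counts and prevalence percentages (1 decimal).
#'
#' @param assign A `subtype_assignment` (or data.frame with `sample_id`,
#'   `label`, optionally `is_core`).
#' @param meta A `metadata_table` from [read_metadata()] or
#'   [simulate_metadata()].
#' @param core_only Restrict to core samples when the assignment carries an
#'   `is_core` flag (default TRUE; use FALSE in transfer mode).
#' @return Class `association_report`: list of per-variable results (each
#'   with `variable`, `test`, `p_value`, `n_used`, and the contingency
#'   table with prevalence percentages or group means), plus `n_samples`.
#' @export
association_report <- function(assign, meta, core_only = TRUE) {
  if (core_only && "is_core" %in% names(assign))
    assign <- assign[assign$is_core, , drop = FALSE]
  ids <- intersect(assign$sample_id, meta$sample_id)
  if (!length(ids)) stop("no overlapping samples between assignment and metadata")
  lab <- setNames(assign$label, assign$sample_id)[ids]
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  schema <- attr(meta, "schema")
  results <- list()
  for (col in names(schema)) {
    vals <- meta[[col]]
    ok <- !is.na(vals)
    res <- list(variable = col, n_used = sum(ok))
    if (schema[[col]] == "categorical") {
      v <- droplevels(factor(vals[ok]))
      tb <- table(level = v, subtype = lab[ok])
      prev <- round(100 * prop.table(tb, margin = 1), 1)
      res$table <- tb
      res$prevalence_pct <- prev
      if (nlevels(v) < 2 || length(unique(lab[ok])) < 2) {
        res$test <- "skipped"
        res$reason <- "fewer than 2 covariate levels or subtypes"
        res$p_value <- NA_real_
      } else {
        ft <- fisher_exact_rxc(unclass(tb))
        res$test <- "fisher_exact"
        res$p_value <- ft$p_value
        res$method <- ft$method
      }
    } else {
      groups <- lab[ok]
      if (length(unique(groups)) != 2) {
        res$test <- "skipped"
        res$reason <- "t-test requires exactly 2 subtypes"
        res$p_value <- NA_real_
      } else {
        tt <- two_sample_t(vals[ok], groups)
        res$test <- "t_test"
        res$p_value <- tt$p_value
        res$means <- tt$means
      }
    }
    results[[col]] <- res
  }
  structure(list(results = results, n_samples = length(ids)),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("Subtype-covariate associations over", x$n_samples, "samples\n")
  for (r in x$results)
    cat(sprintf("  %-12s %-12s p = %s (n = %d)\n", r$variable, r$test,
                ifelse(is.na(r$p_value), "NA", sprintf("%.3f", r$p_value)),
                r$n_used))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set (intersected with the universe first): with a universe
#' of size N containing K set members, and a query of size n overlapping the
#' set in k genes, the p-value is the upper hypergeometric tail P(X >= k)
#' and the fold enrichment is (k/n) / (K/N). P-values are Benjamini-Hochberg
#' adjusted across tested sets.
#'
#' @param query_genes Character vector, a subset of `universe_genes`.
#' @param universe_genes Character vector of background genes.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame with `set`, `set_size` (K), `overlap` (k),
#'   `fold_enrichment`, `p_value`, `fdr`, ordered by ascending p.
#' @export
hypergeometric_ora <- function(query_genes, universe_genes, gene_sets) {
  query_genes <- unique(query_genes)
  universe_genes <- unique(universe_genes)
  if (!length(universe_genes)) stop("empty universe")
  if (!length(query_genes)) stop("empty query")
  if (!all(query_genes %in% universe_genes))
    stop("query genes must be a subset of the universe")
  N <- length(universe_genes); n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe_genes)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(set, query_genes))
    data.frame(set = nm, set_size = K, overlap = k,
               fold_enrichment = (k / n) / (K / N),
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
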