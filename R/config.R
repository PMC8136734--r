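#' Analysis configuration
#'
#' Bundles the tunable constants of the subtyping pipeline: the CPM
#' expression filter, the IQR gene-selection fraction, the candidate cluster
#' numbers and number of consensus NMF runs, the NMF stopping rule, and the
#' fold-change/FDR gates for signature genes.
#'
#' @param cpm_threshold Expression floor in counts-per-million; a gene is
#'   "non-expressed" in a sample when its CPM falls below this (default 5).
#' @param nonexpressed_fraction Fraction of samples in which a gene must be
#'   below `cpm_threshold` to be filtered out (default 0.8).
#' @param iqr_top_fraction Fraction of filtered genes, ranked by
#'   interquartile range of log2(CPM+1), retained for factorization
#'   (default 0.2).
#' @param k_candidates Strictly increasing integer vector of candidate
#'   cluster numbers (default 2:4).
#' @param n_nmf_runs Number of randomly initialized NMF runs per candidate k
#'   used to build the consensus matrix (default 40).
#' @param max_iter Maximum multiplicative-update iterations per run
#'   (default 2000).
#' @param tol Convergence tolerance: relative decrease of the divergence over
#'   10 consecutive iterations (default 1e-6).
#' @param fc_cutoff Linear fold-change gate for signature genes (default 1.5).
#' @param fdr_cutoff Benjamini-Hochberg FDR gate for signature genes
#'   (default 0.05).
#' @param log_transform Feed log2(CPM+1) rather than CPM to the
#'   factorization (default FALSE).
#' @param base_seed Base random seed from which all per-run seeds derive.
#' @param simulation Optional named list of [simulation_spec()] arguments,
#'   carried inside the config so a simulated cohort is reproducible from
#'   the config file alone.
#'
#' @return An object of class `nmf_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config(k_candidates = c(2, 3), n_nmf_runs = 10)
#' cfg$fc_cutoff
analysis_config <- function(cpm_threshold = 5,
                            nonexpressed_fraction = 0.8,
                            iqr_top_fraction = 0.2,
                            k_candidates = c(2L, 3L, 4L),
                            n_nmf_runs = 40L,
                            max_iter = 2000L,
                            tol = 1e-6,
                            fc_cutoff = 1.5,
                            fdr_cutoff = 0.05,
                            log_transform = FALSE,
                            base_seed = 1L,
                            simulation = NULL) {
  if (length(simulation) == 0) simulation <- NULL
  cfg <- list(
    cpm_threshold = as.numeric(cpm_threshold),
    nonexpressed_fraction = as.numeric(nonexpressed_fraction),
    iqr_top_fraction = as.numeric(iqr_top_fraction),
    k_candidates = as.integer(k_candidates),
    n_nmf_runs = as.integer(n_nmf_runs),
    max_iter = as.integer(max_iter),
    tol = as.numeric(tol),
    fc_cutoff = as.numeric(fc_cutoff),
    fdr_cutoff = as.numeric(fdr_cutoff),
    log_transform = isTRUE(log_transform),
    base_seed = as.integer(base_seed),
    simulation = simulation
  )
  class(cfg) <- "nmf_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "nmf_config"))
  with(cfg, {
    if (!(cpm_threshold >= 0)) stop("cpm_threshold must be >= 0")
    if (!(nonexpressed_fraction > 0 && nonexpressed_fraction <= 1))
      stop("nonexpressed_fraction must be in (0, 1]")
    if (!(iqr_top_fraction > 0 && iqr_top_fraction <= 1))
      stop("iqr_top_fraction must be in (0, 1]")
    if (length(k_candidates) < 1 || any(k_candidates < 2))
      stop("k_candidates must be integers >= 2")
    if (is.unsorted(k_candidates, strictly = TRUE))
      stop("k_candidates must be strictly increasing")
    if (n_nmf_runs < 1) stop("n_nmf_runs must be >= 1")
    if (max_iter < 1) stop("max_iter must be >= 1")
    if (!(tol > 0)) stop("tol must be > 0")
    if (!(fc_cutoff > 1)) stop("fc_cutoff must be > 1")
    if (!(fdr_cutoff > 0 && fdr_cutoff < 1)) stop("fdr_cutoff must be in (0, 1)")
  })
  invisible(cfg)
}

#' Read / write an analysis configuration as JSON
#'
#' The JSON round trip is lossless: `read_config(write_config(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param path File path of the JSON configuration.
#' @return `read_config` returns an [analysis_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param cfg An [analysis_config()] object.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.nmf_config <- function(x, ...) {
  cat("Subtyping analysis configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
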