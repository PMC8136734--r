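#' Specification of a synthetic subtyped expression cohort
#'
#' Describes a negative-binomial count matrix with planted molecular
#' subtypes: every gene has a baseline mean drawn on a log2 grid, every
#' sample a lognormal library-size factor, and each subtype a disjoint block
#' of signature genes whose mean is multiplied by `2^signature_log2fc` in
#' samples of that subtype. Defaults give a two-subtype cohort of 2,000
#' genes by 200 samples with 100 signature genes per subtype at log2
#' fold-change 2 — a scaled-down caricature of a bulk brain RNA-seq cohort.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param n_subtypes Number of planted subtypes (>= 1).
#' @param subtype_proportions Probability simplex over subtypes (default
#'   uniform); must sum to 1 within 1e-12.
#' @param n_signature_genes_per_subtype Size of each subtype's up-regulated
#'   gene block; blocks are disjoint.
#' @param signature_log2fc Log2 fold-change applied to a signature gene's
#'   mean in samples of its subtype (>= 0; 0 plants no structure).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param baseline_mean_log2_range Range (log2 scale) from which per-gene
#'   baseline mean counts are drawn uniformly.
#' @param libsize_log_sd Standard deviation of the lognormal library-size
#'   factor (0 = equal libraries).
#' @param covariate_specs Optional list of covariate specifications for
#'   [simulate_metadata()]; each element is a list with `name`, `type`
#'   (`"categorical"` or `"continuous"`) and either `levels` + `probs`
#'   (one probability vector per subtype, rows of a matrix) or `mean` + `sd`
#'   (one value per subtype).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return An object of class `sim_spec`.
#' @export
simulation_spec <- function(n_genes = 2000L,
                            n_samples = 200L,
                            n_subtypes = 2L,
                            subtype_proportions = NULL,
                            n_signature_genes_per_subtype = 100L,
                            signature_log2fc = 2,
                            nb_dispersion = 0.2,
                            baseline_mean_log2_range = c(1, 8),
                            libsize_log_sd = 0.2,
                            covariate_specs = list(),
                            seed = 1L) {
  if (is.null(subtype_proportions))
    subtype_proportions <- rep(1 / n_subtypes, n_subtypes)
  spec <- list(
    n_genes = as.integer(n_genes),
    n_samples = as.integer(n_samples),
    n_subtypes = as.integer(n_subtypes),
    subtype_proportions = as.numeric(subtype_proportions),
    n_signature_genes_per_subtype = as.integer(n_signature_genes_per_subtype),
    signature_log2fc = as.numeric(signature_log2fc),
    nb_dispersion = as.numeric(nb_dispersion),
    baseline_mean_log2_range = as.numeric(baseline_mean_log2_range),
    libsize_log_sd = as.numeric(libsize_log_sd),
    covariate_specs = covariate_specs,
    seed = as.integer(seed)
  )
  stopifnot(spec$n_genes >= 1, spec$n_samples >= 1, spec$n_subtypes >= 1)
  if (length(spec$subtype_proportions) != spec$n_subtypes)
    stop("subtype_proportions length must equal n_subtypes")
  if (abs(sum(spec$subtype_proportions) - 1) > 1e-12)
    stop("subtype_proportions must sum to 1")
  if (spec$signature_log2fc < 0) stop("signature_log2fc must be >= 0")
  if (spec$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (spec$libsize_log_sd < 0) stop("libsize_log_sd must be >= 0")
  if (spec$n_signature_genes_per_subtype * spec$n_subtypes > spec$n_genes)
    stop("signature blocks exceed the number of genes")
  class(spec) <- "sim_spec"
  spec
}

#' Simulate a count matrix with planted subtypes
#'
#' Counts are drawn gene-wise from a negative binomial whose mean is the
#' gene's baseline mean times the sample's library-size factor, multiplied by
#' `2^signature_log2fc` when the gene belongs to the signature block of the
#' sample's subtype.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `counts` (gene x sample integer-valued matrix) and
#'   `truth` (class `sim_truth`: per-sample `label`, per-subtype
#'   `signature_genes`, realized `libsize_factor`, programmed
#'   `baseline_mean` per gene, and the `seed`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_genes; m <- spec$n_samples; K <- spec$n_subtypes
    genes <- sprintf("gene%05d", seq_len(n))
    samples <- sprintf("S%04d", seq_len(m))
    labels <- sample.int(K, m, replace = TRUE, prob = spec$subtype_proportions)
    nsig <- spec$n_signature_genes_per_subtype
    sig <- lapply(seq_len(K), function(t) genes[((t - 1) * nsig + 1):(t * nsig)])
    base_mu <- 2^runif(n, spec$baseline_mean_log2_range[1],
                       spec$baseline_mean_log2_range[2])
    libf <- rlnorm(m, meanlog = 0, sdlog = spec$libsize_log_sd)
    mu <- outer(base_mu, libf)
    fc <- 2^spec$signature_log2fc
    for (t in seq_len(K)) {
      rows <- ((t - 1) * nsig + 1):(t * nsig)
      cols <- which(labels == t)
      if (nsig > 0 && length(cols)) mu[rows, cols] <- mu[rows, cols] * fc
    }
    counts <- if (spec$nb_dispersion == 0) {
      matrix(rpois(n * m, lambda = mu), n, m)
    } else {
      matrix(rnbinom(n * m, mu = mu, size = 1 / spec$nb_dispersion), n, m)
    }
    dimnames(counts) <- list(genes, samples)
    truth <- structure(
      list(label = setNames(labels, samples),
           signature_genes = setNames(sig, paste0("subtype", seq_len(K))),
           libsize_factor = setNames(libf, samples),
           baseline_mean = setNames(base_mu, genes),
           seed = spec$seed),
      class = "sim_truth")
    log_msg("simulate_counts: %d x %d, %d subtypes, log2fc=%g, seed=%d",
            n, m, K, spec$signature_log2fc, spec$seed)
    list(counts = counts, truth = truth)
  })
}

#' Simulate per-sample metadata conditional on true subtype
#'
#' Each sample's covariate is drawn independently given its true subtype:
#' categorical covariates from per-subtype level probabilities, continuous
#' covariates from per-subtype normal distributions.
#'
#' @param truth A `sim_truth` object from [simulate_counts()].
#' @param covariate_specs List of covariate specifications (see
#'   [simulation_spec()]).
#' @param seed Integer seed (default: the truth's seed + 1).
#' @return A `metadata_table` data.frame with `sample_id` and one column per
#'   covariate; the declared schema is stored in `attr(, "schema")`.
#' @export
simulate_metadata <- function(truth, covariate_specs,
                              seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  labels <- truth$label
  df <- data.frame(sample_id = names(labels), stringsAsFactors = FALSE)
  schema <- character()
  withr::with_seed(seed, {
    for (cv in covariate_specs) {
      type <- match.arg(cv$type, c("categorical", "continuous"))
      if (type == "categorical") {
        probs <- cv$probs
        if (is.list(probs)) probs <- do.call(rbind, probs)
        probs <- as.matrix(probs)
        if (nrow(probs) < max(labels))
          stop("covariate '", cv$name, "': need one probability vector per subtype")
        if (any(abs(rowSums(probs) - 1) > 1e-8))
          stop("covariate '", cv$name, "': probability vectors must sum to 1")
        vals <- vapply(labels, function(l) {
          cv$levels[sample.int(length(cv$levels), 1, prob = probs[l, ])]
        }, character(1))
        df[[cv$name]] <- factor(vals, levels = cv$levels)
      } else {
        df[[cv$name]] <- rnorm(length(labels),
                               mean = cv$mean[labels],
                               sd = rep_len(cv$sd, max(labels))[labels])
      }
      schema[cv$name] <- type
    }
  })
  attr(df, "schema") <- schema
  class(df) <- c("metadata_table", "data.frame")
  df
}

#' Write a simulated cohort to a directory
#'
#' Writes `counts.tsv`, `truth.tsv` (sample, true label) and `metadata.tsv`
#' so downstream command-line stages can run on the files alone.
#'
#' @param sim Result of [simulate_counts()].
#' @param meta Optional `metadata_table` from [simulate_metadata()].
#' @param dir Output directory (created if absent).
#' @export
write_simulation <- function(sim, dir, meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(sim$counts, file.path(dir, "counts.tsv"))
  truth_df <- data.frame(sample_id = names(sim$truth$label),
                         true_label = as.integer(sim$truth$label))
  write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(meta))
    write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
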