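#' Read a gene-by-sample count matrix
#'
#' Reads nonnegative counts from TSV/CSV (gene identifiers in the first
#' column, sample identifiers in the header) or MatrixMarket triplet format
#' (with `<path>.genes` and `<path>.samples` identifier sidecar files, one
#' identifier per line).
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`; default guessed from the
#'   file extension.
#' @return A base numeric matrix (genes in rows, samples in columns) with
#'   gene/sample identifiers as dimnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".genes"))
    samples <- readLines(paste0(path, ".samples"))
    if (length(genes) != nrow(m) || length(samples) != ncol(m))
      stop("MTX sidecar identifier counts do not match matrix dimensions")
    dimnames(m) <- list(genes, samples)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing entries in count matrix")
  if (any(m < 0)) stop("negative entries in count matrix")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  log_msg("read_counts: %d genes x %d samples from %s", nrow(m), ncol(m), path)
  m
}

#' Write a gene-by-sample matrix as TSV
#'
#' Inverse of [read_counts()] for the TSV format: the first column (`gene`)
#' holds gene identifiers, the header holds sample identifiers.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Reads a TSV with a `sample_id` column and enforces declared column types.
#' Tokens in `na_strings` (and empty fields) are recorded as missing, never
#' dropped; a continuous column containing any other non-numeric token is an
#' error.
#'
#' @param path File path of the metadata TSV.
#' @param schema Named character vector mapping column names to
#'   `"categorical"` or `"continuous"`. Columns not named in the schema are
#'   kept as character.
#' @param na_strings Tokens treated as missing (default `c("", "NA")`).
#' @return A data.frame of class `metadata_table`; categorical columns are
#'   factors, continuous columns numeric, with the schema stored in
#'   `attr(, "schema")`.
#' @export
read_metadata <- function(path, schema = character(),
                          na_strings = c("", "NA")) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = na_strings,
                   colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(names(schema), names(df))
  if (length(bad)) stop("schema names absent from table: ",
                        paste(bad, collapse = ", "))
  for (col in names(schema)) {
    type <- match.arg(schema[[col]], c("categorical", "continuous"))
    if (type == "continuous") {
      vals <- df[[col]]
      num <- suppressWarnings(as.numeric(vals))
      bad_tok <- !is.na(vals) & is.na(num)
      if (any(bad_tok))
        stop(sprintf("continuous column '%s' has non-numeric value(s): %s",
                     col, paste(unique(vals[bad_tok]), collapse = ", ")))
      df[[col]] <- num
    } else {
      df[[col]] <- factor(df[[col]])
    }
  }
  attr(df, "schema") <- schema
  class(df) <- c("metadata_table", "data.frame")
  log_msg("read_metadata: %d samples, %d columns from %s",
          nrow(df), ncol(df) - 1L, path)
  df
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated GMT lines: set name, description, then member
#' genes. Set names must be unique and sets non-empty.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of character vectors of gene
#'   identifiers.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nfields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfields < 3))
    stop("malformed GMT line(s) with fewer than 3 fields: line ",
         paste(which(nfields < 3), collapse = ", "))
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0)) stop("empty gene set(s) in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled; default `"NA"`).
#' @export
write_gmt <- function(sets, path, descriptions = "NA") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
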