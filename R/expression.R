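#' Construct an expression matrix
#'
#' The package's central container: a numeric genes x samples matrix carrying
#' two provenance flags -- the measurement scale (`"linear"` or `"log2"`) and
#' whether the values have been globally standardised (pooled mean 0, sd 1).
#' Downstream stages consult these flags: deconvolution requires linear-scale
#' input, the co-expression network requires standardised log2 input.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene and sample identifiers unless `gene_ids` /
#'   `sample_ids` are given.
#' @param gene_ids,sample_ids Optional character vectors of identifiers.
#' @param scale `"linear"` or `"log2"`.
#' @param standardized Logical; has the matrix been globally z-scored?
#' @param log_offset Offset used by the log2 transform (so it can be undone).
#'
#' @return An object of class `expr_mat`: the numeric matrix with attributes
#'   `scale`, `standardized` and `log_offset`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              scale = c("linear", "log2"),
                              standardized = FALSE, log_offset = 1) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression values contain missing entries", call. = FALSE)
  }
  if (scale == "linear" && !standardized && min(values) < 0) {
    stop("linear-scale values must be non-negative prior to standardization",
         call. = FALSE)
  }
  structure(values, class = c("expr_mat", "matrix", "array"),
            scale = scale, standardized = standardized,
            log_offset = log_offset)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples [%s%s]\n",
              nrow(x), ncol(x), attr(x, "scale"),
              if (isTRUE(attr(x, "standardized"))) ", standardized" else ""))
  invisible(x)
}

expr_scale <- function(x) attr(x, "scale") %||% "linear"
expr_standardized <- function(x) isTRUE(attr(x, "standardized"))

# Rebuild an expr_mat from plain matrix `values`, inheriting flags from
# `template` unless overridden.
restamp <- function(values, template, scale = NULL, standardized = NULL,
                    log_offset = NULL) {
  expression_matrix(values,
                    scale = scale %||% expr_scale(template),
                    standardized = standardized %||% expr_standardized(template),
                    log_offset = log_offset %||% attr(template, "log_offset") %||% 1)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row whose first column is named
#' `gene`; remaining columns are sample identifiers and the body is numeric.
#' If a sidecar `<path>.json` written by [write_expression_tsv()] is present,
#' the scale/standardisation flags are restored from it.
#'
#' @param path File path.
#' @param scale,standardized Flags to stamp on the result when no sidecar is
#'   found.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = "linear", standardized = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          sep = "\t")
  if (ncol(df) < 2 || names(df)[1] != "gene") {
    stop("expected a TSV whose first column is named 'gene': ", path,
         call. = FALSE)
  }
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                    dimnames = list(genes, colnames(body))))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene row %d ('%s'), sample column '%s' in %s",
                 bad[1], genes[bad[1]], colnames(values)[bad[2]], path),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  log_offset <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- meta$scale %||% scale
    standardized <- isTRUE(meta$standardized)
    log_offset <- meta$log_offset %||% 1
  }
  expression_matrix(values, scale = scale, standardized = standardized,
                    log_offset = log_offset)
}

#' Write an expression matrix to TSV
#'
#' Emits a tab-separated table (first column `gene`) plus a sidecar
#' `<path>.json` recording the scale and standardisation flags so that a
#' later [read_expression_tsv()] restores an equivalent object. Values are
#' written at full double precision; the round-trip is lossless.
#'
#' @param m An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expr_mat"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- apply(unclass(m), 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  jsonlite::write_json(
    list(scale = expr_scale(m), standardized = expr_standardized(m),
         log_offset = attr(m, "log_offset") %||% 1),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects CSV columns `sample_id, study, location, grade, age, sex`.
#' `location` must be one of `convexity`/`skull_base` (it is the phenotype
#' under test and may never be missing), `grade` one of 1/2/3 and `sex`
#' `M`/`F`.
#'
#' @param path CSV file path.
#' @return A tibble with one validated row per sample.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(tibble::as_tibble(df))
}

validate_metadata <- function(df) {
  needed <- c("sample_id", "study", "location", "grade", "age", "sex")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_loc <- which(!df$location %in% c("convexity", "skull_base"))
  if (length(bad_loc) > 0) {
    stop(sprintf("unknown location '%s' for sample '%s' (row %d)",
                 df$location[bad_loc[1]], df$sample_id[bad_loc[1]], bad_loc[1]),
         call. = FALSE)
  }
  if (!all(df$grade %in% 1:3)) {
    stop("grade must be 1, 2 or 3", call. = FALSE)
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a gene panel from a plain-text list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of gene identifiers, in file order.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a gene panel to a plain-text list
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
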