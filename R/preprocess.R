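#' Quantile normalisation
#'
#' Forces every sample column onto a common reference distribution: the
#' across-sample mean of per-column sorted values. Ties within a column
#' receive the mean of their reference quantiles (midrank rule). Delegates
#' to [limma::normalizeQuantiles()].
#'
#' @param m An [expression_matrix()] or plain numeric matrix with at least
#'   two sample columns.
#' @return Object of the same kind with normalised columns.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) {
    stop("quantile normalisation needs at least 2 samples", call. = FALSE)
  }
  out <- limma::normalizeQuantiles(unclass(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (inherits(m, "expr_mat")) restamp(out, m) else out
}

#' Log2 transform with offset
#'
#' `value -> log2(value + offset)`. Records the offset so that downstream
#' stages (deconvolution needs linear input) can undo it exactly.
#'
#' @param m Linear-scale [expression_matrix()] (all values >= 0).
#' @param offset Pseudo-count added before the log (default 1, so 0 maps
#'   to 0).
#' @return Log2-scale expression matrix.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_mat"))
  if (expr_scale(m) != "linear") {
    stop("input is already on the log2 scale", call. = FALSE)
  }
  if (min(m) < 0) stop("negative values cannot be log-transformed", call. = FALSE)
  restamp(log2(unclass(m) + offset), m, scale = "log2", log_offset = offset)
}

#' Undo the log2 transform
#'
#' @param m Log2-scale expression matrix produced by [log2_transform()].
#' @return Linear-scale expression matrix (`2^x - offset`).
#' @export
unlog2_transform <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  if (expr_scale(m) != "log2") stop("input is not log2-scaled", call. = FALSE)
  offset <- attr(m, "log_offset") %||% 1
  vals <- 2^unclass(m) - offset
  if (!expr_standardized(m)) vals <- pmax(vals, 0)
  restamp(vals, m, scale = "linear")
}

#' Intersect gene sets and merge studies into one matrix
#'
#' Keeps exactly the genes common to every study (in canonical sorted
#' order) and concatenates sample columns in study order -- the step that
#' reduced the published cohort to its common-gene core before batch
#' correction.
#'
#' @param matrices Named list of >= 2 [expression_matrix()] objects with
#'   disjoint sample ids and identical scale flags.
#' @return A list with `matrix` (the merged expression matrix) and `report`
#'   (a `merge_report`: per-study gene counts, the intersected count and the
#'   per-study dropped-gene lists).
#' @export
intersect_and_merge <- function(matrices) {
  if (length(matrices) < 2) stop("need at least 2 studies to merge", call. = FALSE)
  if (is.null(names(matrices))) {
    names(matrices) <- paste0("study", seq_along(matrices))
  }
  all_samples <- unname(unlist(lapply(matrices, colnames)))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup) > 0) {
    stop("duplicate sample ids across studies: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  gene_sets <- lapply(matrices, rownames)
  common <- sort(Reduce(intersect, gene_sets))
  if (length(common) == 0) stop("empty gene intersection", call. = FALSE)
  merged <- do.call(cbind, lapply(matrices, function(m)
    unclass(m)[common, , drop = FALSE]))
  colnames(merged) <- all_samples
  report <- structure(list(
    per_study_genes = vapply(gene_sets, length, integer(1)),
    intersected_genes = length(common),
    dropped = lapply(gene_sets, function(g) setdiff(g, common))
  ), class = "merge_report")
  list(matrix = restamp(merged, matrices[[1]]), report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("Merge report:\n")
  for (s in names(x$per_study_genes)) {
    cat(sprintf("  %s: %d genes (%d dropped)\n", s, x$per_study_genes[[s]],
                length(x$dropped[[s]])))
  }
  cat(sprintf("  intersection: %d genes\n", x$intersected_genes))
  invisible(x)
}

#' Scale a matrix to a global mean of 0 and SD of 1
#'
#' All entries are pooled: the output matrix has overall mean 0 and overall
#' population standard deviation 1. Applied per study before batch
#' correction, and to the mixture before deconvolution.
#'
#' @param m Expression matrix or plain numeric matrix (non-constant).
#' @return Same kind of object, standardised; the `standardized` flag is set.
#' @export
global_scale <- function(m) {
  v <- as.vector(unclass(m))
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0) stop("constant matrix cannot be standardised", call. = FALSE)
  out <- (unclass(m) - mu) / sd_pop
  if (inherits(m, "expr_mat")) restamp(out, m, standardized = TRUE) else out
}

#' Empirical-Bayes batch correction
#'
#' Parametric ComBat adjustment: per-gene standardisation against the grand
#' mean and pooled variance, per-batch location/scale estimates shrunk by
#' empirical-Bayes priors (normal on the location effect, inverse-gamma on
#' the scale effect, hyperparameters by method of moments), then
#' back-transformation. No covariate design is used. Delegates to
#' [sva::ComBat()]. With a single batch the input is returned unchanged.
#'
#' @param m Expression matrix or plain numeric matrix (genes x samples).
#' @param batch Character/factor batch label per sample; every batch must
#'   contain at least 2 samples.
#' @param parametric Only the parametric adjustment is provided.
#' @return Batch-corrected matrix of the same kind.
#' @export
combat_correct <- function(m, batch, parametric = TRUE) {
  if (!parametric) {
    stop("non-parametric adjustment is not supported", call. = FALSE)
  }
  stopifnot(length(batch) == ncol(m))
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop("every batch needs at least 2 samples (offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")", call. = FALSE)
  }
  if (length(sizes) < 2) return(m)
  vals <- unclass(m)
  keep <- apply(vals, 1, stats::var) > 0
  out <- vals
  quiet <- function(expr) {
    utils::capture.output(res <- suppressMessages(expr))
    res
  }
  out[keep, ] <- quiet(sva::ComBat(dat = vals[keep, , drop = FALSE],
                                   batch = as.factor(batch), mod = NULL,
                                   par.prior = TRUE, prior.plots = FALSE))
  if (inherits(m, "expr_mat")) restamp(out, m) else out
}

#' Run the full multi-study preprocessing chain
#'
#' Per study: quantile normalisation then log2 transform; across studies:
#' gene intersection and merging, per-study global scaling, then
#' empirical-Bayes batch correction. Per-study (rather than pooled) scaling
#' is used so that scaling itself does not re-encode the batch structure the
#' correction step is meant to remove.
#'
#' @param studies Named list of linear-scale [expression_matrix()] objects.
#' @param metadata Sample metadata tibble (used for batch labels; `study`
#'   column).
#' @param log_offset Offset for the log2 transform.
#' @param skip_combat If `TRUE`, stop after scaling (ablation runs).
#' @param pooled_scale If `TRUE`, scale the merged matrix once instead of
#'   per study.
#' @return List with `matrix` (preprocessed, standardised log2 expression),
#'   `report` (the merge report) and `linear` (the merged linear-scale
#'   matrix, the input deconvolution expects).
#' @export
preprocess_studies <- function(studies, metadata, log_offset = 1,
                               skip_combat = FALSE, pooled_scale = FALSE) {
  metadata <- validate_metadata(metadata)
  per_study <- lapply(studies, function(m)
    log2_transform(quantile_normalize(m), offset = log_offset))
  merged <- intersect_and_merge(per_study)
  merged_linear <- intersect_and_merge(studies)$matrix

  missing_meta <- setdiff(colnames(merged$matrix), metadata$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  batch <- metadata$study[match(colnames(merged$matrix), metadata$sample_id)]

  if (pooled_scale) {
    scaled <- global_scale(merged$matrix)
  } else {
    pieces <- lapply(unique(batch), function(b)
      global_scale(merged$matrix[, batch == b, drop = FALSE]))
    scaled_vals <- do.call(cbind, lapply(pieces, unclass))
    scaled_vals <- scaled_vals[, colnames(merged$matrix), drop = FALSE]
    scaled <- restamp(scaled_vals, merged$matrix, standardized = TRUE)
  }

  out <- if (skip_combat) scaled else combat_correct(scaled, batch)
  list(matrix = out, report = merged$report, linear = merged_linear)
}
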