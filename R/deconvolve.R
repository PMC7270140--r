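#' Load a signature matrix from TSV
#'
#' Accepts LM22-format files: first column gene symbols, remaining columns
#' cell types, non-negative numeric body, full column rank.
#'
#' @param path TSV file path.
#' @return Numeric genes x K matrix with dimnames.
#' @export
load_signature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  genes <- df[[1]]
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- genes
  validate_signature(S)
}

validate_signature <- function(S) {
  if (!is.numeric(S)) stop("signature body must be numeric", call. = FALSE)
  if (anyDuplicated(colnames(S))) {
    stop("duplicate cell-type names in signature", call. = FALSE)
  }
  if (anyDuplicated(rownames(S))) {
    stop("duplicate gene ids in signature", call. = FALSE)
  }
  if (min(S) < 0) stop("signature entries must be non-negative", call. = FALSE)
  if (qr(S)$rank < ncol(S)) {
    stop("signature matrix is rank-deficient", call. = FALSE)
  }
  S
}

#' Prepare a bulk mixture for deconvolution
#'
#' Deconvolution consumes linear-scale data scaled to a global mean of 0
#' and SD of 1: a log2 matrix is first un-logged, then globally z-scored.
#' The global z-scoring (which produces negative "linear" values) can be
#' skipped via `scale = FALSE`.
#'
#' @param m Expression matrix with a known scale flag.
#' @param scale Apply the global z-scoring (default `TRUE`).
#' @return Expression matrix ready for [estimate_fractions()].
#' @export
prepare_mixture <- function(m, scale = TRUE) {
  stopifnot(inherits(m, "expr_mat"))
  if (!expr_scale(m) %in% c("linear", "log2")) {
    stop("unknown scale flag", call. = FALSE)
  }
  if (expr_scale(m) == "log2") m <- unlog2_transform(m)
  if (scale) global_scale(m) else m
}

#' Estimate immune cell fractions from bulk expression
#'
#' Reference-based deconvolution of each sample against a signature matrix.
#' Mixture and signature are intersected on shared genes (>= 50 required)
#' and each gene is standardised by the signature's per-gene mean and SD --
#' a shared affine transform, so exact mixtures remain exact. Engines:
#' `"nnls"` (non-negative least squares, the deterministic default) or
#' `"nusvr"` (linear nu-support-vector regression over nu in
#' {0.25, 0.5, 0.75}, keeping the lowest-RMSE fit and clamping negative
#' coefficients). Coefficients are normalised to the unit simplex.
#'
#' @param mixture Expression matrix (samples in columns).
#' @param signature Genes x K non-negative signature matrix.
#' @param engine `"nnls"` or `"nusvr"`.
#' @param nu_grid Candidate nu values for the SVR engine.
#' @return An object of class `cell_fractions`: list with `fractions`
#'   (samples x K simplex matrix) and `diagnostics` (tibble: `sample_id`,
#'   `rmse`, `nu`).
#' @export
estimate_fractions <- function(mixture, signature,
                               engine = c("nnls", "nusvr"),
                               nu_grid = c(0.25, 0.5, 0.75)) {
  engine <- match.arg(engine)
  signature <- validate_signature(signature)
  vals <- unclass(mixture)
  shared <- intersect(rownames(vals), rownames(signature))
  if (length(shared) < 50) {
    stop("only ", length(shared),
         " genes shared between mixture and signature (need >= 50)",
         call. = FALSE)
  }
  Y <- vals[shared, , drop = FALSE]
  S <- signature[shared, , drop = FALSE]
  # normalise each gene by the signature's per-gene SD, applied identically
  # to both sides: a shared diagonal scaling preserves convex mixtures
  # exactly and keeps the signature full rank. (Shared *centering* would
  # project out the simplex direction -- for signatures with balanced row
  # sums the fractions become unidentifiable -- so genes are
  # variance-normalised, not z-scored.)
  g_sd <- apply(S, 1, stats::sd)
  g_sd[g_sd == 0] <- 1
  Sz <- S / g_sd
  Yz <- Y / g_sd
  K <- ncol(S)
  fractions <- matrix(0, ncol(Y), K,
                      dimnames = list(colnames(Y), colnames(S)))
  diag_rows <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Yz[, j]
    if (engine == "nnls") {
      w <- pracma::lsqnonneg(Sz, y)$x
      nu_used <- NA_real_
    } else {
      best <- NULL
      for (nu in nu_grid) {
        fit <- e1071::svm(x = Sz, y = y, type = "nu-regression",
                          kernel = "linear", nu = nu, scale = FALSE)
        wc <- as.vector(t(fit$coefs) %*% fit$SV)
        wc[wc < 0] <- 0
        rmse <- sqrt(mean((y - Sz %*% wc)^2))
        if (is.null(best) || rmse < best$rmse) {
          best <- list(w = wc, rmse = rmse, nu = nu)
        }
      }
      w <- best$w
      nu_used <- best$nu
    }
    if (sum(w) == 0) {
      warning("all-zero coefficients for sample ", colnames(Y)[j],
              "; returning uniform fractions")
      w <- rep(1, K)
    }
    fractions[j, ] <- w / sum(w)
    diag_rows[[j]] <- tibble::tibble(
      sample_id = colnames(Y)[j],
      rmse = sqrt(mean((y - Sz %*% w)^2)),
      nu = nu_used)
  }
  structure(list(fractions = fractions,
                 diagnostics = dplyr::bind_rows(diag_rows),
                 engine = engine, n_shared_genes = length(shared)),
            class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat(sprintf("<cell_fractions> %d samples x %d cell types (engine: %s, %d shared genes)\n",
              nrow(x$fractions), ncol(x$fractions), x$engine,
              x$n_shared_genes))
  invisible(x)
}

#' Write cell fractions to TSV
#' @param cf A `cell_fractions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fractions_tsv <- function(cf, path) {
  df <- data.frame(sample_id = rownames(cf$fractions), cf$fractions,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
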