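#' Soft-thresholded co-expression adjacency
#'
#' Raises pairwise gene correlations to a power so that weak edges fade
#' while the network stays weighted. Unsigned: `|cor|^beta` (default, with
#' beta = 20); signed: `((1 + cor)/2)^beta`. The diagonal is set to 0, as
#' the topological overlap transform expects.
#'
#' @param m Expression matrix, genes in rows, samples in columns.
#' @param power Soft-thresholding exponent beta (>= 1).
#' @param type `"unsigned"` or `"signed"`.
#' @return Symmetric genes x genes adjacency matrix with entries in
#'   `[0, 1]` and zero diagonal.
#' @export
soft_adjacency <- function(m, power = 20, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  stopifnot(power >= 1)
  vals <- unclass(m)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene(s): ", paste(rownames(vals)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  C <- stats::cor(t(vals))
  A <- if (type == "unsigned") abs(C)^power else ((1 + C) / 2)^power
  diag(A) <- 0
  A
}

#' Scale-free topology fit across candidate powers
#'
#' For each candidate soft-thresholding power, computes the linear fit R^2
#' of `log10 p(k)` against `log10 k` over binned connectivities (the
#' scale-free criterion), signed negative when the slope is positive, plus
#' the mean connectivity.
#'
#' @param m Expression matrix (>= 50 genes for a meaningful fit).
#' @param powers Candidate powers.
#' @param type Network type, as in [soft_adjacency()].
#' @param n_bins Connectivity histogram bins.
#' @return Tibble with columns `power`, `sft_r_squared`, `slope`,
#'   `mean_connectivity`.
#' @export
pick_soft_threshold <- function(m, powers = c(1, 2, 4, 6, 8, 10, 12, 16, 20),
                                type = "unsigned", n_bins = 10) {
  if (nrow(m) < 50) {
    stop("need at least 50 genes for a scale-free fit", call. = FALSE)
  }
  purrr::map_dfr(powers, function(p) {
    A <- soft_adjacency(m, power = p, type = type)
    k <- rowSums(A)
    fit <- scale_free_fit(k, n_bins)
    tibble::tibble(power = p, sft_r_squared = fit$r2, slope = fit$slope,
                   mean_connectivity = mean(k))
  })
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  p_k <- tapply(k, bin, length) / length(k)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(p_k) & p_k > 0 & mean_k > 0
  if (sum(ok) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(p_k[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = if (slope > 0) -r2 else r2, slope = unname(slope))
}

#' Topological overlap matrix
#'
#' Transforms an adjacency matrix into pairwise similarity in terms of
#' shared network neighbourhood:
#' `TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
#' row connectivity `k_i = sum_u A_iu`; the diagonal is 1.
#'
#' @param A Symmetric adjacency with zero diagonal and entries in `[0, 1]`.
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-12)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  # enforce exact symmetry against accumulation-order rounding
  (tom + t(tom)) / 2
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut adaptively at
#' a fraction of the tallest merge height; clusters below the minimum size
#' are assigned to the background (grey) label 0 and the remainder are
#' renumbered 1..M by descending size (ties broken by smallest member gene
#' name, so labels are invariant to gene order).
#'
#' @param tom TOM matrix from [topological_overlap()] (with gene dimnames).
#' @param min_size Minimum module size (default 30).
#' @param cut_fraction Cut height as a fraction of the maximum merge height.
#' @return Named integer vector: gene -> module id (0 = unassigned).
#' @export
detect_modules <- function(tom, min_size = 30, cut_fraction = 0.99) {
  stopifnot(min_size >= 2, !is.null(rownames(tom)))
  d <- stats::as.dist(1 - tom)
  h <- stats::hclust(d, method = "average")
  raw <- stats::cutree(h, h = cut_fraction * max(h$height))
  names(raw) <- rownames(tom)
  renumber_modules(raw, min_size)
}

renumber_modules <- function(raw, min_size) {
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- stats::setNames(integer(length(raw)), names(raw))
  if (length(keep) > 0) {
    first_gene <- vapply(keep, function(k) min(names(raw)[raw == k]), "")
    ord <- keep[order(-sizes[keep], first_gene)]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  labels
}

#' Module eigengenes (meta-genes)
#'
#' Summarises each module as the first principal component of its
#' row-standardised gene profiles: the first right-singular vector over
#' samples, sign-aligned so that its correlation with the module's mean
#' profile is non-negative, with the fraction of variance explained.
#'
#' @param m Expression matrix.
#' @param labels Module labels from [detect_modules()] (0 is skipped).
#' @return List with `metagenes` (samples x modules matrix of unit-norm
#'   columns, named `ME1`, `ME2`, ...) and `variance_explained`.
#' @export
module_eigengene <- function(m, labels) {
  vals <- unclass(m)
  labels <- labels[rownames(vals)]
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no modules to summarise", call. = FALSE)
  me <- matrix(NA_real_, ncol(vals), length(mods),
               dimnames = list(colnames(vals), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    rows <- vals[labels == mods[i], , drop = FALSE]
    z <- t(scale(t(rows)))
    if (nrow(z) == 1) {
      warning("module ", mods[i], " has a single gene; using its profile")
      v <- as.vector(z) / sqrt(sum(z^2))
      ve[i] <- 1
    } else {
      sv <- svd(z)
      v <- sv$v[, 1]
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    me[, i] <- v
  }
  list(metagenes = me, variance_explained = ve)
}

#' Test module eigengenes against tumour location
#'
#' Per module: a Mann-Whitney comparison of meta-gene scores between skull
#' base and convexity samples, and a covariate-adjusted p-value -- the Wald
#' test of the meta-gene coefficient in a logistic regression of location
#' on meta-gene, WHO grade (ordinal numeric), age and sex.
#'
#' @param metagenes Samples x modules matrix from [module_eigengene()].
#' @param metadata Metadata tibble covering every sample row.
#' @return Tibble with `module`, `mann_whitney_p`, `adjusted_p`.
#' @export
test_module_location <- function(metagenes, metadata) {
  metadata <- validate_metadata(metadata)
  meta <- metadata[match(rownames(metagenes), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("metadata missing for some samples", call. = FALSE)
  }
  is_sb <- meta$location == "skull_base"
  if (all(is_sb) || !any(is_sb)) {
    stop("both locations must be represented", call. = FALSE)
  }
  purrr::map_dfr(colnames(metagenes), function(mod) {
    me <- metagenes[, mod]
    mw <- mann_whitney_u(me[is_sb], me[!is_sb])
    df <- data.frame(y = as.integer(is_sb), me = me,
                     grade = as.numeric(meta$grade), age = meta$age,
                     sex = as.integer(meta$sex == "M"))
    fit <- suppressWarnings(stats::glm(y ~ me + grade + age + sex,
                                       family = stats::binomial(), data = df))
    coefs <- summary(fit)$coefficients
    adj_p <- if ("me" %in% rownames(coefs)) coefs["me", 4] else NA_real_
    tibble::tibble(module = mod, mann_whitney_p = mw$p, adjusted_p = adj_p)
  })
}

#' Label modules with positively associated cytokines
#'
#' A cytokine labels a module when its expression is significantly and
#' positively correlated with the module meta-gene (Pearson r > 0.6,
#' p < 0.05). Panel genes absent from the matrix are reported and skipped.
#'
#' @param metagenes Samples x modules matrix.
#' @param m Expression matrix over the same samples.
#' @param panel Character vector of cytokine gene ids.
#' @param rho_min,alpha Association thresholds.
#' @return Tibble with `module`, `cytokine`, `rho`, `p` (one row per label).
#' @export
label_cytokines <- function(metagenes, m, panel, rho_min = 0.6, alpha = 0.05) {
  vals <- unclass(m)
  missing <- setdiff(panel, rownames(vals))
  if (length(missing) > 0) {
    message("panel genes absent from matrix (skipped): ",
            paste(missing, collapse = ", "))
  }
  present <- intersect(panel, rownames(vals))
  out <- purrr::map_dfr(colnames(metagenes), function(mod) {
    purrr::map_dfr(present, function(g) {
      r <- pearson_with_p(vals[g, ], metagenes[, mod])
      tibble::tibble(module = mod, cytokine = g, rho = r$rho, p = r$p)
    })
  })
  dplyr::filter(out, .data$rho > rho_min, .data$p < alpha)
}

#' Genes most correlated with a module eigengene
#'
#' Ranks module genes by kME (correlation with the meta-gene), descending,
#' with deterministic lexicographic tie-breaks.
#'
#' @param m Expression matrix.
#' @param metagene Meta-gene score vector over samples.
#' @param genes Module member gene ids.
#' @param n How many to return (<= module size).
#' @return Tibble with `gene`, `kme`, best first.
#' @export
top_module_genes <- function(m, metagene, genes, n = 10) {
  stopifnot(n <= length(genes))
  vals <- unclass(m)[genes, , drop = FALSE]
  kme <- apply(vals, 1, function(g) stats::cor(g, metagene))
  ord <- order(-kme, genes)
  tibble::tibble(gene = genes[ord], kme = unname(kme[ord]))[seq_len(n), ]
}

#' Logistic-regression location classifier
#'
#' Fits location ~ expression of a gene panel and scores discrimination by
#' the area under the ROC curve, computed with the rank (Mann-Whitney)
#' formula over predicted probabilities. In-sample evaluation is the
#' default; k-fold cross-validation is available. Perfect separation falls
#' back to an L2-ridge fit rather than failing.
#'
#' @param m Expression matrix containing the panel genes.
#' @param gene_panel Predictor gene ids.
#' @param metadata Metadata tibble (provides `location`).
#' @param scheme `"in_sample"` or `"kfold"`.
#' @param k Folds for `"kfold"`.
#' @param seed Seed for the fold assignment.
#' @return List with `auc`, `roc_points` (tibble `fpr`, `tpr`), `scores`,
#'   and `ridge` (logical: was the fallback used).
#' @export
location_classifier <- function(m, gene_panel, metadata,
                                scheme = c("in_sample", "kfold"), k = 5,
                                seed = 1L) {
  scheme <- match.arg(scheme)
  metadata <- validate_metadata(metadata)
  vals <- unclass(m)
  missing <- setdiff(gene_panel, rownames(vals))
  if (length(missing) > 0) {
    stop("panel genes absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- t(vals[gene_panel, , drop = FALSE])
  y <- as.integer(metadata$location[match(rownames(X), metadata$sample_id)] ==
                    "skull_base")
  if (anyNA(y)) stop("metadata missing for some samples", call. = FALSE)
  if (length(unique(y)) < 2) stop("both locations must be present", call. = FALSE)

  fit_score <- function(X_train, y_train, X_test) {
    ridge <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(cbind(1, X_train), y_train, family = stats::binomial()),
      warning = function(w) {
        ridge <<- TRUE
        invokeRestart("muffleWarning")
      })
    # numerically separated fits push probabilities to the boundary
    if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)) {
      ridge <- TRUE
    }
    if (ridge || !fit$converged) {
      rf <- glmnet::glmnet(X_train, y_train, family = "binomial", alpha = 0,
                           lambda = 1e-3)
      p <- as.vector(stats::predict(rf, newx = X_test, type = "response"))
      list(p = p, ridge = TRUE)
    } else {
      eta <- cbind(1, X_test) %*% fit$coefficients
      list(p = as.vector(1 / (1 + exp(-eta))), ridge = FALSE)
    }
  }

  if (scheme == "in_sample") {
    fs <- fit_score(X, y, X)
    scores <- fs$p
    ridge <- fs$ridge
  } else {
    folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = length(y))))
    scores <- numeric(length(y))
    ridge <- FALSE
    for (f in seq_len(k)) {
      te <- folds == f
      fs <- fit_score(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
      scores[te] <- fs$p
      ridge <- ridge || fs$ridge
    }
  }
  list(auc = auc_rank(scores, y), roc_points = roc_points(scores, y),
       scores = stats::setNames(scores, rownames(X)), ridge = ridge)
}

#' Area under the ROC curve via the rank formula
#'
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum of
#' positive-class scores (midranks for ties).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 class labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(fpr = sum(pred & labels == 0) / sum(labels == 0),
                   tpr = sum(pred & labels == 1) / sum(labels == 1))
  })
  dplyr::distinct(pts)
}

#' Fit the full co-expression module analysis
#'
#' Convenience wrapper chaining soft-thresholded adjacency, topological
#' overlap, module detection, eigengene extraction, location testing and
#' cytokine labelling into one fitted object with [tidy()]/[glance()]
#' methods.
#'
#' @param m Preprocessed (standardised, log2) expression matrix.
#' @param metadata Sample metadata tibble (optional; enables location tests).
#' @param power Soft-thresholding exponent.
#' @param min_size Minimum module size.
#' @param type Network type.
#' @param panel Optional cytokine panel for module labelling.
#' @param cut_fraction Dendrogram cut height fraction, see [detect_modules()].
#' @return An object of class `coexpress_fit`.
#' @export
coexpress_modules <- function(m, metadata = NULL, power = 20, min_size = 30,
                              type = "unsigned", panel = NULL,
                              cut_fraction = 0.99) {
  A <- soft_adjacency(m, power = power, type = type)
  tom <- topological_overlap(A)
  labels <- detect_modules(tom, min_size = min_size,
                           cut_fraction = cut_fraction)
  eg <- module_eigengene(m, labels)
  tests <- if (!is.null(metadata)) {
    test_module_location(eg$metagenes, metadata)
  } else NULL
  cyto <- if (!is.null(panel)) {
    label_cytokines(eg$metagenes, m, panel)
  } else NULL
  structure(list(labels = labels, metagenes = eg$metagenes,
                 variance_explained = eg$variance_explained,
                 tests = tests, cytokine_labels = cyto,
                 params = list(power = power, min_size = min_size,
                               type = type, cut_fraction = cut_fraction)),
            class = "coexpress_fit")
}

#' @export
print.coexpress_fit <- function(x, ...) {
  n_mod <- length(unique(x$labels[x$labels > 0]))
  cat(sprintf("<coexpress_fit> %d modules over %d genes (power %s, min size %s)\n",
              n_mod, length(x$labels), x$params$power, x$params$min_size))
  if (!is.null(x$tests)) {
    sig <- sum(x$tests$mann_whitney_p < 0.05)
    cat(sprintf("  %d module(s) location-associated at Mann-Whitney p < 0.05\n",
                sig))
  }
  invisible(x)
}
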