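# Shared builders for small deterministic fixtures.

tiny_expr <- function(values, genes = NULL, samples = NULL, scale = NULL) {
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  # signed fixtures are treated as log-scale data
  if (is.null(scale)) scale <- if (min(values) >= 0) "linear" else "log2"
  expression_matrix(values, gene_ids = genes, sample_ids = samples,
                    scale = scale)
}

tiny_metadata <- function(n, locations, studies = "ST1") {
  tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    study = rep_len(studies, n),
    location = rep_len(locations, n),
    grade = rep_len(c(1L, 2L), n),
    age = seq(40, 80, length.out = n),
    sex = rep_len(c("M", "F"), n)
  )
}

# small cohort config used by several integration-style tests
small_sim <- function(seed = 1L, ...) {
  sim_config(n_studies = 2, samples_per_study = c(30, 30),
             skull_base_fraction = c(0.5, 0.5), n_genes = 400,
             module_sizes = c(40, 35), markers_per_type = 3,
             seed = seed, ...)
}

no_couplings <- function() default_couplings()[0, ]

# adjusted Rand index between two label vectors (contingency form)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
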