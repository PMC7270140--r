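#' The 22 immune cell type labels
#'
#' Standard LM22-style leukocyte labels (naive/memory, resting/activated
#' variants) used as default cell-type names throughout the simulator and
#' deconvolution examples.
#'
#' @return Character vector of length 22.
#' @export
lm22_cell_types <- function() {
  c("B cells naive", "B cells memory", "Plasma cells",
    "T cells CD8", "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta",
    "NK cells resting", "NK cells activated", "Monocytes",
    "Macrophages M0", "Macrophages M1", "Macrophages M2",
    "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells resting", "Mast cells activated", "Eosinophils",
    "Neutrophils")
}

#' Default 35-gene cytokine panel
#'
#' A configurable stand-in for a literature-derived cytokine list. Includes
#' the interleukins, chemokines and growth factors most often profiled in
#' tumour-microenvironment studies (IL6, IL1R2, BTK and CCL3 among them).
#' Real-data analyses should supply their own panel via [read_gene_list()].
#'
#' @return Character vector of 35 gene symbols.
#' @export
default_cytokine_panel <- function() {
  c("IL6", "IL1R2", "BTK", "CCL3",
    "IL1A", "IL1B", "IL2", "IL4", "IL5", "IL7", "IL10", "IL12A", "IL13",
    "IL15", "IL17A", "IL18", "CXCL8", "TNF", "IFNG", "TGFB1",
    "CCL2", "CCL4", "CCL5", "CCL11", "CCL19", "CCL20", "CCL22",
    "CXCL1", "CXCL9", "CXCL10", "CXCL12", "CSF1", "CSF2", "CSF3", "VEGFA")
}

#' Simulation configuration
#'
#' Defines the synthetic multi-study cohort: its size and class balance
#' mirror the three-study, 107-tumour meningioma cohort (12, 84 and 11
#' samples; 71 skull base in total), the Dirichlet immune-fraction priors
#' differ by location (skull base enriched for gamma-delta T cells,
#' monocytes and plasma cells; convexity for activated mast cells and
#' neutrophils), and the planted cell-cytokine couplings reproduce the
#' location-specific correlation structure the network stage must detect.
#'
#' @param n_studies Number of studies (batches).
#' @param samples_per_study Integer vector of per-study sample counts.
#' @param skull_base_fraction Per-study fraction of skull-base samples;
#'   counts are assigned deterministically as `round(fraction * n)`.
#' @param n_genes Total genes before per-study dropping.
#' @param cell_types Cell-type names (length K).
#' @param markers_per_type Marker genes per cell type in the signature.
#' @param base_level,marker_fold Signature background level and marker
#'   fold-change.
#' @param module_sizes Sizes of planted co-expression modules.
#' @param location_module Index of the module whose latent factor is shifted
#'   between locations.
#' @param module_location_effect Shift (in latent-factor SD units) of the
#'   location module in skull-base samples.
#' @param dirichlet_alpha Named list with elements `convexity` and
#'   `skull_base`, each a length-K vector of Dirichlet concentrations.
#' @param couplings Tibble with columns `cell_type`, `cytokine`, `location`,
#'   `target_rho`: population correlations planted between a cell fraction
#'   and a cytokine gene within one location.
#' @param coupling_mean,coupling_sd Mean and total SD of coupled cytokine
#'   expression on the linear scale.
#' @param batch_shift,batch_scale Per-study additive shift and multiplicative
#'   scale applied to linear values.
#' @param gene_shift_sd SD of the per-gene batch shift around the study mean.
#' @param noise_sd SD (log scale) of multiplicative lognormal measurement
#'   noise.
#' @param gene_drop_rate Fraction of genes each study drops (disjoint across
#'   studies) so that cross-study intersection is exercised.
#' @param cytokine_panel Panel gene names (planted in the expression matrix).
#' @param seed Integer seed; identical configs and seeds give byte-identical
#'   cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 3,
                       samples_per_study = c(12, 84, 11),
                       skull_base_fraction = c(7 / 12, 53 / 84, 1),
                       n_genes = 1200,
                       cell_types = lm22_cell_types(),
                       markers_per_type = 5,
                       base_level = 1,
                       marker_fold = 10,
                       module_sizes = c(100, 60, 45, 30),
                       location_module = 1,
                       module_location_effect = 1.5,
                       dirichlet_alpha = NULL,
                       couplings = default_couplings(),
                       coupling_mean = 10,
                       coupling_sd = 1,
                       batch_shift = NULL,
                       batch_scale = NULL,
                       gene_shift_sd = 0.05,
                       noise_sd = 0.05,
                       gene_drop_rate = 0.05,
                       cytokine_panel = default_cytokine_panel(),
                       seed = 1L) {
  K <- length(cell_types)
  if (is.null(dirichlet_alpha)) dirichlet_alpha <- default_dirichlet_alpha(cell_types)
  if (is.null(batch_shift)) batch_shift <- seq(0, 1.5, length.out = n_studies)
  if (is.null(batch_scale)) batch_scale <- seq(1, 1.3, length.out = n_studies)
  cfg <- list(n_studies = n_studies, samples_per_study = samples_per_study,
              skull_base_fraction = skull_base_fraction, n_genes = n_genes,
              cell_types = cell_types, markers_per_type = markers_per_type,
              base_level = base_level, marker_fold = marker_fold,
              module_sizes = module_sizes, location_module = location_module,
              module_location_effect = module_location_effect,
              dirichlet_alpha = dirichlet_alpha, couplings = couplings,
              coupling_mean = coupling_mean, coupling_sd = coupling_sd,
              batch_shift = batch_shift, batch_scale = batch_scale,
              gene_shift_sd = gene_shift_sd, noise_sd = noise_sd,
              gene_drop_rate = gene_drop_rate, cytokine_panel = cytokine_panel,
              seed = as.integer(seed))
  stopifnot(length(samples_per_study) == n_studies,
            length(skull_base_fraction) == n_studies,
            all(samples_per_study > 0), K >= 2,
            all(skull_base_fraction >= 0 & skull_base_fraction <= 1),
            all(module_sizes >= 2),
            location_module >= 1, location_module <= length(module_sizes),
            length(dirichlet_alpha$convexity) == K,
            length(dirichlet_alpha$skull_base) == K,
            all(batch_scale > 0), noise_sd >= 0,
            gene_drop_rate >= 0, gene_drop_rate < 1 / n_studies)
  if (!all(abs(couplings$target_rho) < 1)) {
    stop("coupling target_rho must lie in (-1, 1)", call. = FALSE)
  }
  if (!all(couplings$cell_type %in% cell_types)) {
    stop("coupling cell types must appear in `cell_types`", call. = FALSE)
  }
  if (!all(couplings$cytokine %in% cytokine_panel)) {
    stop("coupled cytokines must appear in the cytokine panel", call. = FALSE)
  }
  if (anyDuplicated(couplings[, c("cytokine", "location")])) {
    stop("a cytokine can be coupled to at most one cell per location",
         call. = FALSE)
  }
  n_struct <- K * markers_per_type + sum(module_sizes) + length(cytokine_panel)
  if (n_genes < n_struct + 10) {
    stop("n_genes too small for the requested structure (need > ", n_struct,
         ")", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default planted cell-cytokine couplings
#'
#' Emulates the location-specific correlation structure of the real
#' networks: in convexity tumours, activated mast cells and neutrophils are
#' the cytokine-active fractions (marquee edges mast/IL6 rho 0.69 and
#' neutrophils/IL1R2 rho 0.74); in skull base, gamma-delta T cells, plasma
#' cells and monocytes (gamma-delta/CCL3 the strongest). Because the
#' connectivity statistic is a *sum* of significant correlations, an active
#' cell is coupled to a block of several cytokines -- a single strong edge
#' is statistically indistinguishable from the extreme of the null sum at
#' realistic per-location sample sizes, whereas a genuinely active cell
#' (one whose cytokine programme spans many genes) separates cleanly.
#'
#' @return A tibble with columns `cell_type`, `cytokine`, `location`,
#'   `target_rho`.
#' @export
default_couplings <- function() {
  tibble::tribble(
    ~cell_type,             ~cytokine, ~location,    ~target_rho,
    # convexity: mast cells dominate, neutrophils second
    "Mast cells activated", "IL6",     "convexity",  0.69,
    "Mast cells activated", "CCL2",    "convexity",  0.60,
    "Mast cells activated", "IL1B",    "convexity",  0.55,
    "Mast cells activated", "CXCL8",   "convexity",  0.55,
    "Mast cells activated", "TNF",     "convexity",  0.50,
    "Mast cells activated", "IL4",     "convexity",  0.50,
    "Mast cells activated", "IL5",     "convexity",  0.45,
    "Mast cells activated", "CCL20",   "convexity",  0.45,
    "Neutrophils",          "IL1R2",   "convexity",  0.74,
    "Neutrophils",          "CXCL1",   "convexity",  0.50,
    "Neutrophils",          "CSF3",    "convexity",  0.45,
    # skull base: gamma-delta T cells dominate, plasma cells and
    # monocytes weaker
    "T cells gamma delta",  "CCL3",    "skull_base", 0.70,
    "T cells gamma delta",  "IFNG",    "skull_base", 0.60,
    "T cells gamma delta",  "TNF",     "skull_base", 0.55,
    "T cells gamma delta",  "CCL4",    "skull_base", 0.55,
    "T cells gamma delta",  "IL17A",   "skull_base", 0.50,
    "T cells gamma delta",  "CCL5",    "skull_base", 0.50,
    "T cells gamma delta",  "IL2",     "skull_base", 0.45,
    "T cells gamma delta",  "CXCL9",   "skull_base", 0.45,
    "Plasma cells",         "BTK",     "skull_base", 0.57,
    "Plasma cells",         "IL10",    "skull_base", 0.45,
    "Monocytes",            "CSF1",    "skull_base", 0.54
  )
}

default_dirichlet_alpha <- function(cell_types) {
  base <- stats::setNames(rep(1, length(cell_types)), cell_types)
  sb <- conv <- base
  boost <- function(a, cells) {
    hit <- intersect(cells, names(a)); a[hit] <- 3; a
  }
  sb <- boost(sb, c("T cells gamma delta", "Monocytes", "Plasma cells"))
  conv <- boost(conv, c("Mast cells activated", "Neutrophils"))
  list(convexity = conv, skull_base = sb)
}

#' Generate a synthetic immune signature matrix
#'
#' Builds a genes x K non-negative reference matrix with one disjoint marker
#' block per cell type: markers sit at `base_level * marker_fold`, all other
#' entries at `base_level` (plus optional lognormal jitter). Full column rank
#' by construction.
#'
#' @param K Number of cell types (>= 2).
#' @param markers_per_type Markers per type (>= 1).
#' @param base_level Background expression level.
#' @param marker_fold Fold-change of a marker over background (> 1).
#' @param cell_types Optional type names (defaults to the LM22 labels).
#' @param jitter_sd Log-scale SD of multiplicative jitter (0 = exact blocks).
#' @param seed Optional seed (used only when `jitter_sd > 0`).
#' @return Numeric matrix (K * markers_per_type) x K with gene row names and
#'   cell-type column names.
#' @export
generate_signature <- function(K, markers_per_type, base_level = 1,
                               marker_fold = 10, cell_types = NULL,
                               jitter_sd = 0, seed = NULL) {
  stopifnot(K >= 2, markers_per_type >= 1, base_level > 0)
  if (marker_fold <= 1) {
    stop("marker_fold must exceed 1 (markers must distinguish cell types)",
         call. = FALSE)
  }
  if (is.null(cell_types)) {
    cell_types <- if (K <= 22) lm22_cell_types()[seq_len(K)]
                  else paste0("cell_type_", seq_len(K))
  }
  stopifnot(length(cell_types) == K, !anyDuplicated(cell_types))
  G <- K * markers_per_type
  S <- matrix(base_level, G, K,
              dimnames = list(paste0("SIG", rep(seq_len(K), each = markers_per_type),
                                     "_", rep(seq_len(markers_per_type), K)),
                              cell_types))
  for (k in seq_len(K)) {
    rows <- (k - 1) * markers_per_type + seq_len(markers_per_type)
    S[rows, k] <- base_level * marker_fold
  }
  if (jitter_sd > 0) {
    jit <- function() matrix(exp(stats::rnorm(G * K, 0, jitter_sd)), G, K)
    J <- if (is.null(seed)) jit() else withr::with_seed(seed, jit())
    S <- S * J
  }
  S
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  x / rowSums(x)
}

# Population SD of a Dirichlet marginal for component i
dirichlet_marginal_sd <- function(alpha, i) {
  a0 <- sum(alpha)
  sqrt(alpha[i] * (a0 - alpha[i]) / (a0^2 * (a0 + 1)))
}

#' Apply additive/multiplicative batch effects
#'
#' For every sample in study `b`, each gene value becomes
#' `scale_b * value + shift_{b,g}` where the gene-specific shift is drawn
#' around the study's mean shift with SD `gene_shift_sd`. This is the
#' distortion the batch-correction stage is expected to remove.
#'
#' @param m Numeric matrix (genes x samples).
#' @param study_labels Character/factor of length `ncol(m)`.
#' @param shifts,scales Named or ordered per-study parameters (one per
#'   distinct study, in `unique(study_labels)` order when unnamed).
#' @param gene_shift_sd SD of per-gene shifts around the study mean (0 gives
#'   a uniform shift).
#' @return Matrix of the same shape.
#' @export
apply_batch_effects <- function(m, study_labels, shifts, scales,
                                gene_shift_sd = 0) {
  studies <- unique(study_labels)
  stopifnot(length(study_labels) == ncol(m),
            length(shifts) == length(studies),
            length(scales) == length(studies))
  if (any(scales <= 0)) stop("batch scales must be positive", call. = FALSE)
  if (is.null(names(shifts))) names(shifts) <- studies
  if (is.null(names(scales))) names(scales) <- studies
  out <- m
  for (b in studies) {
    cols <- which(study_labels == b)
    g_shift <- if (gene_shift_sd > 0) {
      stats::rnorm(nrow(m), shifts[[b]], gene_shift_sd)
    } else rep(shifts[[b]], nrow(m))
    out[, cols] <- scales[[b]] * m[, cols] + g_shift
  }
  out
}

#' Generate a multi-study cohort with planted ground truth
#'
#' Draws per-sample immune fractions from location-specific Dirichlet
#' distributions, builds linear-scale bulk expression as signature x
#' fractions for marker genes, multiplicative latent-factor modules (one
#' shifted between locations), location-coupled cytokine genes whose
#' population correlation with a chosen cell fraction equals the configured
#' target, and lognormal background; then applies lognormal measurement
#' noise, splits samples into studies, applies per-study batch effects and
#' drops a disjoint random gene subset per study.
#'
#' @param config A [sim_config()].
#' @return A list with elements `studies` (named list of linear-scale
#'   [expression_matrix()] objects), `metadata` (tibble), and `truth`
#'   (list: `fractions` samples x K matrix, `signature`, `module_labels`
#'   named integer vector with 0 = background, `location_module_id`,
#'   `couplings` as realised, `batch` parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  K <- length(cfg$cell_types)
  n_total <- sum(cfg$samples_per_study)
  study_ids <- paste0("STUDY", seq_len(cfg$n_studies))
  study_of <- rep(study_ids, cfg$samples_per_study)
  sample_ids <- sprintf("S%03d", seq_len(n_total))

  # deterministic skull-base counts per study: round(fraction * n)
  location <- unlist(lapply(seq_len(cfg$n_studies), function(s) {
    n <- cfg$samples_per_study[s]
    n_sb <- round(cfg$skull_base_fraction[s] * n)
    sample(c(rep("skull_base", n_sb), rep("convexity", n - n_sb)))
  }))

  grade2_prob <- ifelse(location == "skull_base", 0.02, 0.12)
  metadata <- tibble::tibble(
    sample_id = sample_ids,
    study = study_of,
    location = location,
    grade = ifelse(stats::runif(n_total) < grade2_prob, 2L, 1L),
    age = round(pmin(90, pmax(18, stats::rnorm(n_total, 56.4, 12.6)))),
    sex = ifelse(stats::runif(n_total) < 0.3, "M", "F")
  )

  # immune fractions: location-specific Dirichlet
  fractions <- matrix(NA_real_, n_total, K,
                      dimnames = list(sample_ids, cfg$cell_types))
  for (loc in c("convexity", "skull_base")) {
    idx <- which(location == loc)
    if (length(idx) > 0) {
      fractions[idx, ] <- rdirichlet(length(idx), cfg$dirichlet_alpha[[loc]])
    }
  }

  sig <- generate_signature(K, cfg$markers_per_type, cfg$base_level,
                            cfg$marker_fold, cell_types = cfg$cell_types)
  marker_genes <- rownames(sig)

  n_mod <- length(cfg$module_sizes)
  module_genes <- unlist(lapply(seq_len(n_mod), function(m)
    sprintf("MOD%d_G%03d", m, seq_len(cfg$module_sizes[m]))))
  module_of <- rep(seq_len(n_mod), cfg$module_sizes)

  panel <- cfg$cytokine_panel
  n_bg <- cfg$n_genes - length(marker_genes) - length(module_genes) - length(panel)
  bg_genes <- sprintf("BG_G%04d", seq_len(n_bg))
  genes <- c(marker_genes, module_genes, panel, bg_genes)

  expr <- matrix(0, length(genes), n_total, dimnames = list(genes, sample_ids))

  # marker genes: mixture of the signature by the true fractions
  expr[marker_genes, ] <- sig %*% t(fractions)

  # module genes: multiplicative latent factor (additive on the log2 scale);
  # the location module's factor is shifted in skull-base samples
  factors <- matrix(stats::rnorm(n_mod * n_total), n_mod, n_total)
  factors[cfg$location_module, location == "skull_base"] <-
    factors[cfg$location_module, location == "skull_base"] +
    cfg$module_location_effect
  base_log2 <- stats::rnorm(length(module_genes), 3, 0.5)
  loading <- stats::runif(length(module_genes), 0.7, 1)
  expr[module_genes, ] <- 2^(base_log2 + loading * factors[module_of, , drop = FALSE])

  # cytokines: background behaviour unless coupled within a location
  expr[panel, ] <- 2^(stats::rnorm(length(panel), 3, 0.5) +
                        matrix(stats::rnorm(length(panel) * n_total, 0, 0.5),
                               length(panel), n_total))
  realized <- cfg$couplings
  realized$a <- NA_real_
  realized$noise_sd <- NA_real_
  # coupled cytokines start as independent noise at the coupling scale in
  # both locations; each coupling then overwrites its own location only,
  # so a cytokine may be coupled to different cells in the two locations
  coupled_genes <- unique(cfg$couplings$cytokine)
  expr[coupled_genes, ] <- cfg$coupling_mean +
    matrix(stats::rnorm(length(coupled_genes) * n_total, 0, cfg$coupling_sd),
           length(coupled_genes), n_total)
  for (i in seq_len(nrow(cfg$couplings))) {
    cp <- cfg$couplings[i, ]
    loc_idx <- which(location == cp$location)
    alpha <- cfg$dirichlet_alpha[[cp$location]]
    k <- match(cp$cell_type, cfg$cell_types)
    sd_f <- dirichlet_marginal_sd(alpha, k)
    if (!is.finite(sd_f) || sd_f == 0) {
      stop("infeasible coupling: cell fraction '", cp$cell_type,
           "' has zero variance in ", cp$location, call. = FALSE)
    }
    a <- cp$target_rho * cfg$coupling_sd / sd_f
    # budget the coupling's own noise so that the *emitted* values (which
    # still receive multiplicative lognormal measurement noise) carry the
    # target population correlation
    meas_var <- (cfg$noise_sd * cfg$coupling_mean)^2
    e_var <- (1 - cp$target_rho^2) * cfg$coupling_sd^2 - meas_var
    if (e_var < 0) {
      stop("infeasible coupling: target_rho ", cp$target_rho, " for '",
           cp$cytokine, "' cannot be reached under noise_sd ", cfg$noise_sd,
           call. = FALSE)
    }
    e_sd <- sqrt(e_var)
    mean_f <- alpha[k] / sum(alpha)
    expr[cp$cytokine, loc_idx] <- cfg$coupling_mean +
      a * (fractions[loc_idx, k] - mean_f) +
      stats::rnorm(length(loc_idx), 0, e_sd)
    realized$a[i] <- a
    realized$noise_sd[i] <- e_sd
  }

  # background genes
  expr[bg_genes, ] <- 2^(stats::rnorm(n_bg, 3, 0.5) +
                           matrix(stats::rnorm(n_bg * n_total, 0, 0.5),
                                  n_bg, n_total))

  # multiplicative lognormal measurement noise
  if (cfg$noise_sd > 0) {
    expr <- expr * exp(matrix(stats::rnorm(length(expr), 0, cfg$noise_sd),
                              nrow(expr)))
  }

  # per-study batch effects on the linear scale
  expr <- apply_batch_effects(expr, study_of, cfg$batch_shift,
                              cfg$batch_scale, cfg$gene_shift_sd)
  expr <- pmax(expr, 0)

  # disjoint per-study gene drops
  n_drop <- floor(cfg$gene_drop_rate * cfg$n_genes)
  protected <- c(marker_genes, panel)
  droppable <- setdiff(genes, protected)
  drop_pool <- sample(droppable, min(n_drop * cfg$n_studies, length(droppable)))
  dropped <- lapply(seq_len(cfg$n_studies), function(s) {
    if (length(drop_pool) == 0) character() else
      drop_pool[rep(seq_len(cfg$n_studies),
                    length.out = length(drop_pool)) == s]
  })

  studies <- stats::setNames(lapply(seq_len(cfg$n_studies), function(s) {
    cols <- which(study_of == study_ids[s])
    keep <- setdiff(genes, dropped[[s]])
    expression_matrix(expr[keep, cols, drop = FALSE], scale = "linear")
  }), study_ids)

  module_labels <- stats::setNames(integer(length(genes)), genes)
  module_labels[module_genes] <- module_of

  list(
    studies = studies,
    metadata = metadata,
    panel = panel,
    truth = list(
      fractions = fractions,
      signature = sig,
      module_labels = module_labels,
      location_module_id = cfg$location_module,
      couplings = realized,
      batch = list(shift = cfg$batch_shift, scale = cfg$batch_scale,
                   gene_shift_sd = cfg$gene_shift_sd),
      dropped_genes = dropped
    )
  )
}

#' Write a simulated cohort to disk
#'
#' Emits one expression TSV per study (linear scale, with sidecar flags), a
#' metadata CSV, the true signature TSV, the cytokine panel as a plain-text
#' list, and the ground truth (fractions embedded) as JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$studies)) {
    write_expression_tsv(cohort$studies[[s]],
                         file.path(dir, paste0(s, "_expression.tsv")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  sig <- cohort$truth$signature
  sig_df <- data.frame(gene = rownames(sig), sig, check.names = FALSE)
  utils::write.table(sig_df, file.path(dir, "signature.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_gene_list(cohort$panel, file.path(dir, "cytokine_panel.txt"))
  truth <- cohort$truth
  truth$fractions <- as.data.frame(truth$fractions)
  truth$signature <- as.data.frame(truth$signature)
  truth$module_labels <- as.list(truth$module_labels)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
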