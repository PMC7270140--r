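#' Pipeline run configuration
#'
#' Collects every stage parameter plus a single global seed into one
#' serialisable object. Unknown keys are rejected. Per-stage seeds are
#' derived from the global seed by a fixed counter offset, so individual
#' stages can be rerun in isolation with identical results.
#'
#' @param sim A [sim_config()] describing the synthetic cohort (set to
#'   `NULL` to supply `studies`/`metadata` directly to [run_pipeline()]).
#' @param power,min_size Co-expression parameters.
#' @param engine Deconvolution engine.
#' @param scale_mixture Apply the global z-scoring of the mixture before
#'   deconvolution. Off by default: global centring shifts the mixture
#'   along the simplex direction, which an intercept-free non-negative fit
#'   against a balanced signature cannot absorb (see the methods vignette).
#' @param rho_min,alpha Network thresholds.
#' @param connectivity_mode `"signed"` or `"absolute"`.
#' @param n_top_genes Classifier panel size per significant module.
#' @param skip_combat Ablation flag: omit batch correction.
#' @param gmt Optional named list of gene sets for enrichment.
#' @param seed Global integer seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), power = 20, min_size = 30,
                       engine = "nnls", rho_min = 0.6, alpha = 0.05,
                       connectivity_mode = "signed", n_top_genes = 10,
                       scale_mixture = FALSE, skip_combat = FALSE,
                       gmt = NULL, seed = 1L) {
  cfg <- list(sim = sim, power = power, min_size = min_size, engine = engine,
              rho_min = rho_min, alpha = alpha,
              connectivity_mode = connectivity_mode,
              n_top_genes = n_top_genes, scale_mixture = scale_mixture,
              skip_combat = skip_combat,
              gmt = gmt, seed = as.integer(seed))
  stopifnot(power >= 1, min_size >= 2, rho_min >= 0, rho_min <= 1,
            alpha > 0, alpha < 1, n_top_genes >= 1,
            engine %in% c("nnls", "nusvr"),
              connectivity_mode %in% c("signed", "absolute"))
  structure(cfg, class = "run_config")
}

stage_seed <- function(config, stage_index) {
  (config$seed + 1000L * stage_index) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> co-expression modules ->
#' deconvolution -> immune network -> enrichment (optional) in fixed order,
#' with deconvolution consuming the merged linear-scale (pre-log) matrix.
#' Any stage error aborts with the stage name attached; re-running with the
#' same configuration and seed reproduces every non-timing field of the
#' report.
#'
#' @param config A [run_config()].
#' @param studies,metadata Supply a real cohort instead of simulating
#'   (`config$sim` is then ignored).
#' @return A list of class `run_report`: per-stage timings and key results
#'   (module count, significant modules, classifier AUC, per-location
#'   top-3 cells by connectivity and centrality), the fitted objects, the
#'   parameter echo, package version and seed.
#' @export
run_pipeline <- function(config = run_config(), studies = NULL,
                         metadata = NULL) {
  stopifnot(inherits(config, "run_config"))
  timings <- list()
  stage <- function(name, index, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(withr::with_seed(stage_seed(config, index), expr),
               error = function(e) {
                 stop("stage '", name, "' failed: ", conditionMessage(e),
                      call. = FALSE)
               }),
      warning = function(w) invokeRestart("muffleWarning"))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  truth <- NULL
  panel <- default_cytokine_panel()
  if (is.null(studies)) {
    if (is.null(config$sim)) {
      stop("either supply studies/metadata or a sim config", call. = FALSE)
    }
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config, 1L)
    class(sim_cfg) <- "sim_config"
    cohort <- stage("simulate", 1L, generate_cohort(sim_cfg))
    studies <- cohort$studies
    metadata <- cohort$metadata
    truth <- cohort$truth
    panel <- cohort$panel
  }
  metadata <- validate_metadata(metadata)

  prep <- stage("preprocess", 2L,
                preprocess_studies(studies, metadata,
                                   skip_combat = config$skip_combat))

  fit <- stage("coexpress", 3L,
               coexpress_modules(prep$matrix, metadata,
                                 power = config$power,
                                 min_size = config$min_size,
                                 panel = panel))

  signature <- if (!is.null(truth)) truth$signature else NULL
  fractions <- if (!is.null(signature)) {
    stage("deconvolve", 4L, {
      mix <- prepare_mixture(prep$linear, scale = config$scale_mixture)
      estimate_fractions(mix, signature, engine = config$engine)
    })
  } else NULL

  network <- if (!is.null(fractions)) {
    stage("immune_network", 5L,
          immune_network_analysis(fractions, prep$matrix, panel, metadata,
                                  rho_min = config$rho_min,
                                  alpha = config$alpha,
                                  mode = config$connectivity_mode))
  } else NULL

  # classifier over the top genes of location-significant modules
  classifier <- NULL
  sig_mods <- fit$tests$module[fit$tests$mann_whitney_p < 0.05]
  if (length(sig_mods) > 0) {
    classifier <- stage("classifier", 6L, {
      panel_genes <- unlist(lapply(sig_mods, function(mod) {
        id <- as.integer(sub("ME", "", mod))
        genes <- names(fit$labels)[fit$labels == id]
        n <- min(config$n_top_genes, length(genes))
        top_module_genes(prep$matrix, fit$metagenes[, mod], genes, n)$gene
      }))
      location_classifier(prep$matrix, unique(panel_genes), metadata,
                          seed = stage_seed(config, 6L))
    })
  }

  enrich <- if (!is.null(config$gmt)) {
    stage("enrichment", 7L, {
      universe <- rownames(prep$matrix)
      mods <- sort(unique(fit$labels[fit$labels > 0]))
      purrr::map_dfr(mods, function(mid) {
        res <- overrepresentation(
          intersect(names(fit$labels)[fit$labels == mid], universe),
          universe, config$gmt)
        dplyr::mutate(res, module = paste0("ME", mid), .before = 1)
      })
    })
  } else NULL

  top3 <- function(s, col) {
    d <- if (col == "connectivity") s$connectivity else
      dplyr::rename(s$centrality[s$centrality$node_kind == "cell", ],
                    cell_type = "node")
    metric <- if (col == "connectivity") d$connectivity else d$centrality
    d$cell_type[order(-metric)][1:3]
  }
  key_results <- list(
    n_genes = nrow(prep$matrix),
    n_modules = length(unique(fit$labels[fit$labels > 0])),
    n_significant_modules = sum(fit$tests$mann_whitney_p < 0.05),
    auc = if (!is.null(classifier)) classifier$auc else NA_real_,
    top_connectivity = if (!is.null(network)) list(
      convexity = top3(network$convexity, "connectivity"),
      skull_base = top3(network$skull_base, "connectivity")) else NULL,
    top_centrality = if (!is.null(network)) list(
      convexity = top3(network$convexity, "centrality"),
      skull_base = top3(network$skull_base, "centrality")) else NULL
  )

  structure(list(
    key_results = key_results,
    merge_report = prep$report,
    coexpress = fit,
    fractions = fractions,
    network = network,
    classifier = classifier,
    enrichment = enrich,
    truth = truth,
    params = unclass(config)[setdiff(names(config), c("sim", "gmt"))],
    timings = timings,
    seed = config$seed,
    version = as.character(utils::packageVersion("menimm"))
  ), class = "run_report")
}

#' Write a run report
#'
#' Emits the machine-readable JSON report plus a human-readable text
#' summary with one cell-ranking block per location and the significant
#' modules table. Skipped stages are marked as such.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path Output path stem; writes `<path>.json` and `<path>.txt`.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  payload <- list(
    version = report$version,
    seed = report$seed,
    params = report$params,
    key_results = report$key_results,
    timings_sec = report$timings,
    module_tests = if (!is.null(report$coexpress$tests))
      report$coexpress$tests else "skipped",
    differences = if (!is.null(report$network))
      report$network$differences else "skipped",
    enrichment = if (!is.null(report$enrichment))
      report$enrichment else "skipped"
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)

  lines <- c(
    sprintf("menimm run report (version %s, seed %d)", report$version,
            report$seed),
    sprintf("genes: %d  modules: %d  location-significant: %d",
            report$key_results$n_genes, report$key_results$n_modules,
            report$key_results$n_significant_modules),
    sprintf("classifier AUC: %s",
            ifelse(is.na(report$key_results$auc), "skipped",
                   sprintf("%.3f", report$key_results$auc))))
  if (!is.null(report$network)) {
    for (loc in c("convexity", "skull_base")) {
      lines <- c(lines, sprintf("top cells by connectivity [%s]: %s", loc,
                                paste(report$key_results$top_connectivity[[loc]],
                                      collapse = ", ")))
      lines <- c(lines, sprintf("top cells by centrality   [%s]: %s", loc,
                                paste(report$key_results$top_centrality[[loc]],
                                      collapse = ", ")))
    }
  } else {
    lines <- c(lines, "immune network: skipped")
  }
  lines <- c(lines, if (is.null(report$enrichment)) "enrichment: skipped"
             else sprintf("enrichment: %d set-module tests",
                          nrow(report$enrichment)))
  writeLines(lines, txt_path)
  invisible(c(json_path, txt_path))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d | %d modules (%d significant) | AUC %s\n",
              x$seed, x$key_results$n_modules,
              x$key_results$n_significant_modules,
              ifelse(is.na(x$key_results$auc), "-",
                     sprintf("%.3f", x$key_results$auc))))
  invisible(x)
}
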