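#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a co-expression fit
#'
#' One row per detected module: size, variance explained by the meta-gene,
#' the location tests (when metadata was supplied) and the number of
#' cytokine labels.
#'
#' @param x A `coexpress_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy coexpress_fit
#' @export
tidy.coexpress_fit <- function(x, ...) {
  mods <- sort(unique(x$labels[x$labels > 0]))
  out <- tibble::tibble(
    module = paste0("ME", mods),
    n_genes = vapply(mods, function(m) sum(x$labels == m), integer(1)),
    variance_explained = unname(x$variance_explained[paste0("ME", mods)])
  )
  if (!is.null(x$tests)) out <- dplyr::left_join(out, x$tests, by = "module")
  if (!is.null(x$cytokine_labels)) {
    counts <- dplyr::count(x$cytokine_labels, .data$module,
                           name = "n_cytokine_labels")
    out <- dplyr::left_join(out, counts, by = "module")
    out$n_cytokine_labels[is.na(out$n_cytokine_labels)] <- 0L
  }
  out
}

#' @rdname tidy.coexpress_fit
#' @method glance coexpress_fit
#' @export
glance.coexpress_fit <- function(x, ...) {
  mods <- unique(x$labels[x$labels > 0])
  tibble::tibble(
    n_genes = length(x$labels),
    n_modules = length(mods),
    n_grey = sum(x$labels == 0),
    n_significant = if (is.null(x$tests)) NA_integer_
                    else sum(x$tests$mann_whitney_p < 0.05),
    power = x$params$power,
    min_size = x$params$min_size
  )
}

#' Tidy estimated cell fractions
#'
#' @param x A `cell_fractions` object.
#' @param ... Unused.
#' @return Long tibble: `sample_id`, `cell_type`, `fraction`.
#' @method tidy cell_fractions
#' @export
tidy.cell_fractions <- function(x, ...) {
  tibble::as_tibble(x$fractions, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "fraction")
}

#' @rdname tidy.cell_fractions
#' @method glance cell_fractions
#' @export
glance.cell_fractions <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$fractions),
                 n_cell_types = ncol(x$fractions),
                 engine = x$engine,
                 n_shared_genes = x$n_shared_genes,
                 mean_rmse = mean(x$diagnostics$rmse))
}

#' Tidy an immune network fit
#'
#' @param x An `immune_network_fit`.
#' @param ... Unused.
#' @return Long tibble of per-location cell connectivity and centrality
#'   plus the between-location differences.
#' @method tidy immune_network_fit
#' @export
tidy.immune_network_fit <- function(x, ...) {
  per_loc <- purrr::map_dfr(list(x$convexity, x$skull_base), function(s) {
    cent <- s$centrality[s$centrality$node_kind == "cell", ]
    dplyr::left_join(s$connectivity,
                     tibble::tibble(cell_type = cent$node,
                                    centrality = cent$centrality),
                     by = "cell_type") |>
      dplyr::mutate(location = s$location, .before = 1)
  })
  per_loc
}

#' @rdname tidy.immune_network_fit
#' @method glance immune_network_fit
#' @export
glance.immune_network_fit <- function(x, ...) {
  d <- x$differences
  tibble::tibble(
    n_cells = nrow(d),
    n_edges_convexity = igraph::ecount(x$convexity$graph),
    n_edges_skull_base = igraph::ecount(x$skull_base$graph),
    top_convexity_cell = d$cell_type[which.max(d$delta_connectivity)],
    top_skull_base_cell = d$cell_type[which.min(d$delta_connectivity)],
    rho_min = x$params$rho_min,
    alpha = x$params$alpha,
    mode = x$params$mode
  )
}
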