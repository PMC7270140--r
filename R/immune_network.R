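#' Cell-cytokine correlation edge table for one location
#'
#' For every (immune cell type, cytokine gene) pair, the Pearson correlation
#' (with t-based p-value) between the cell's estimated fraction and the
#' cytokine's expression across the samples of one anatomical location.
#' Cell fractions that are constant across those samples yield a degenerate
#' row (`rho = 0`, `p = 1`) rather than an error, so one flat cell type
#' cannot abort the analysis.
#'
#' @param fractions Samples x cell-types matrix, or a `cell_fractions`
#'   object.
#' @param m Expression matrix over (at least) the same samples.
#' @param panel Cytokine gene ids; panel genes absent from the matrix are
#'   reported and skipped.
#' @param metadata Metadata tibble providing `location` per sample.
#' @param location `"convexity"` or `"skull_base"`.
#' @return Tibble with one row per (cell_type, cytokine): `cell_type`,
#'   `cytokine`, `rho`, `p`, `n`, `location`, `degenerate`.
#' @export
cell_cytokine_edges <- function(fractions, m, panel, metadata, location) {
  if (inherits(fractions, "cell_fractions")) fractions <- fractions$fractions
  metadata <- validate_metadata(metadata)
  stopifnot(location %in% c("convexity", "skull_base"))
  samples <- metadata$sample_id[metadata$location == location]
  samples <- intersect(samples, intersect(rownames(fractions), colnames(m)))
  if (length(samples) < 3) {
    stop("need at least 3 samples in location '", location, "'",
         call. = FALSE)
  }
  vals <- unclass(m)
  missing <- setdiff(panel, rownames(vals))
  if (length(missing) > 0) {
    message("panel genes absent from matrix (skipped): ",
            paste(missing, collapse = ", "))
  }
  present <- intersect(panel, rownames(vals))
  fr <- fractions[samples, , drop = FALSE]
  ex <- vals[present, samples, drop = FALSE]
  n <- length(samples)
  f_sd <- apply(fr, 2, stats::sd)
  g_sd <- apply(ex, 1, stats::sd)
  # one correlation-matrix call (cells x cytokines), then the same t-based
  # two-sided p-value pearson_with_p applies per pair
  C <- suppressWarnings(stats::cor(fr, t(ex)))
  C[f_sd == 0, ] <- 0
  C[, g_sd == 0] <- 0
  C <- pmin(pmax(C, -1), 1)
  tstat <- C * sqrt((n - 2) / pmax(1 - C^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  P[abs(C) == 1] <- 0
  degenerate <- outer(f_sd == 0, g_sd == 0, `|`)
  P[degenerate] <- 1
  grid <- tidyr::expand_grid(cell_type = colnames(fr), cytokine = present)
  idx <- cbind(match(grid$cell_type, colnames(fr)),
               match(grid$cytokine, present))
  tibble::tibble(cell_type = grid$cell_type, cytokine = grid$cytokine,
                 rho = C[idx], p = P[idx], n = n, location = location,
                 degenerate = degenerate[idx])
}

#' Build the thresholded bipartite cell-cytokine network
#'
#' Nodes are all cell types plus all panel cytokines in the edge table; an
#' edge is kept when `rho > rho_min` and `p < alpha` (one-sided on positive
#' correlations, as the effect-size cut-off is stated; `two_sided = TRUE`
#' uses `|rho| > rho_min`). Edge weight is the correlation.
#'
#' @param edges Edge table from [cell_cytokine_edges()] (one location).
#' @param rho_min Effect-size cut-off (default 0.6).
#' @param alpha Significance cut-off (default 0.05).
#' @param two_sided Keep strong negative correlations too?
#' @return An [igraph][igraph::graph_from_data_frame] bipartite graph with a
#'   logical vertex attribute `type` (`TRUE` = cytokine) and edge attribute
#'   `weight`.
#' @export
build_network <- function(edges, rho_min = 0.6, alpha = 0.05,
                          two_sided = FALSE) {
  eff <- if (two_sided) abs(edges$rho) else edges$rho
  keep <- edges[eff > rho_min & edges$p < alpha & !edges$degenerate, ]
  cells <- sort(unique(edges$cell_type))
  cyts <- sort(unique(edges$cytokine))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(cells), name = cells, type = FALSE)
  g <- igraph::add_vertices(g, length(cyts), name = cyts, type = TRUE)
  if (nrow(keep) > 0) {
    g <- igraph::add_edges(g,
      rbind(match(keep$cell_type, c(cells, cyts)),
            match(keep$cytokine, c(cells, cyts))),
      weight = keep$rho)
  }
  g
}

#' Export a network as GraphML
#'
#' @param graph igraph object from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Per-cell connectivity
#'
#' A cell type's "biological activity": the sum of its significant
#' (p < alpha) Pearson correlations with the cytokine panel. No effect-size
#' threshold is applied. `mode = "signed"` sums raw correlations (the
#' statistic as defined); `mode = "absolute"` sums their magnitudes.
#'
#' @param edges Edge table for one location.
#' @param alpha Significance cut-off.
#' @param mode `"signed"` or `"absolute"`.
#' @return Tibble `cell_type`, `connectivity` covering every cell type in
#'   the table (cells with no significant edge get 0).
#' @export
connectivity <- function(edges, alpha = 0.05, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  sig <- edges[edges$p < alpha & !edges$degenerate, ]
  contrib <- if (mode == "signed") sig$rho else abs(sig$rho)
  sums <- tapply(contrib, factor(sig$cell_type,
                                 levels = sort(unique(edges$cell_type))),
                 sum, default = 0)
  tibble::tibble(cell_type = names(sums), connectivity = as.numeric(sums))
}

#' Unweighted eigenvector centrality
#'
#' Builds the binary adjacency over all cell and cytokine nodes (1 iff the
#' pair's correlation is significant at `alpha`), then scores each node by
#' the principal eigenvector of that 0/1 matrix, computed by power
#' iteration to a 1e-12 tolerance. The vector is non-negative and scaled to
#' unit Euclidean norm; nodes outside the dominant connected component (and
#' isolated nodes) score 0. An empty graph returns all zeros.
#'
#' @param edges Edge table for one location.
#' @param alpha Significance cut-off defining adjacency.
#' @return Tibble `node`, `node_kind` (`"cell"`/`"cytokine"`), `centrality`.
#' @export
eigenvector_centrality <- function(edges, alpha = 0.05) {
  cells <- sort(unique(edges$cell_type))
  cyts <- sort(unique(edges$cytokine))
  nodes <- c(cells, cyts)
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  sig <- edges[edges$p < alpha & !edges$degenerate, ]
  if (nrow(sig) > 0) {
    i <- match(sig$cell_type, nodes)
    j <- match(sig$cytokine, nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  cent <- principal_eigenvector(A)
  tibble::tibble(node = nodes,
                 node_kind = ifelse(nodes %in% cells, "cell", "cytokine"),
                 centrality = unname(cent))
}

# Principal eigenvector of a symmetric non-negative matrix by per-component
# power iteration; returns the unit-norm eigenvector of the component with
# the largest dominant eigenvalue, zeros elsewhere.
principal_eigenvector <- function(A, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  deg <- rowSums(A)
  if (all(deg == 0)) return(out)
  comp <- connected_components(A)
  best <- NULL
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < 2 || all(A[idx, idx] == 0)) next
    # iterate on A + I: same eigenvectors, but a strictly dominant
    # eigenvalue even on bipartite components (whose spectrum is symmetric)
    sub <- A[idx, idx, drop = FALSE]
    diag(sub) <- diag(sub) + 1
    v <- rep(1 / sqrt(length(idx)), length(idx))
    lambda <- 0
    for (it in seq_len(max_iter)) {
      w <- as.vector(sub %*% v)
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      w <- w / nw
      if (sqrt(sum((w - v)^2)) < tol) {
        v <- w
        lambda <- nw - 1
        break
      }
      v <- w
      lambda <- nw - 1
    }
    if (is.null(best) || lambda > best$lambda + 1e-12) {
      best <- list(lambda = lambda, idx = idx, v = abs(v))
    }
  }
  if (!is.null(best)) out[best$idx] <- best$v
  out
}

connected_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(A[u, ] > 0 & comp == 0)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Summarise one location's immune network
#'
#' Bundles the edge table, thresholded graph, per-cell connectivity and
#' per-node eigenvector centrality for a single location.
#'
#' @inheritParams cell_cytokine_edges
#' @param rho_min,alpha Network thresholds.
#' @param mode Connectivity mode.
#' @return List of class `network_summary`.
#' @export
location_network_summary <- function(fractions, m, panel, metadata, location,
                                     rho_min = 0.6, alpha = 0.05,
                                     mode = "signed") {
  edges <- cell_cytokine_edges(fractions, m, panel, metadata, location)
  structure(list(
    location = location,
    edges = edges,
    graph = build_network(edges, rho_min = rho_min, alpha = alpha),
    connectivity = connectivity(edges, alpha = alpha, mode = mode),
    centrality = eigenvector_centrality(edges, alpha = alpha),
    params = list(rho_min = rho_min, alpha = alpha, mode = mode)
  ), class = "network_summary")
}

#' Compare the two location networks
#'
#' Per cell type: the convexity-minus-skull-base difference in connectivity
#' and in eigenvector centrality -- positive values mean the cell is more
#' active in convexity tumours, negative in skull base.
#'
#' @param conv,sb `network_summary` objects for convexity and skull base,
#'   built over identical cell-type sets.
#' @return Tibble `cell_type`, `delta_connectivity`, `delta_centrality`,
#'   sorted by descending `delta_connectivity`.
#' @export
compare_locations <- function(conv, sb) {
  stopifnot(inherits(conv, "network_summary"), inherits(sb, "network_summary"))
  if (!setequal(conv$connectivity$cell_type, sb$connectivity$cell_type)) {
    stop("the two summaries cover different cell-type sets", call. = FALSE)
  }
  cells <- sort(conv$connectivity$cell_type)
  cc <- conv$connectivity$connectivity[match(cells, conv$connectivity$cell_type)]
  sc <- sb$connectivity$connectivity[match(cells, sb$connectivity$cell_type)]
  conv_cent <- conv$centrality[conv$centrality$node_kind == "cell", ]
  sb_cent <- sb$centrality[sb$centrality$node_kind == "cell", ]
  ce <- conv_cent$centrality[match(cells, conv_cent$node)]
  se <- sb_cent$centrality[match(cells, sb_cent$node)]
  out <- tibble::tibble(cell_type = cells,
                        delta_connectivity = cc - sc,
                        delta_centrality = ce - se)
  dplyr::arrange(out, dplyr::desc(.data$delta_connectivity))
}

#' Fit both location networks and their comparison
#'
#' The package's headline analysis: builds the convexity and skull-base
#' cell-cytokine networks and the between-location difference table.
#'
#' @inheritParams location_network_summary
#' @return Object of class `immune_network_fit` with elements `convexity`,
#'   `skull_base` (both `network_summary`) and `differences`.
#' @export
immune_network_analysis <- function(fractions, m, panel, metadata,
                                    rho_min = 0.6, alpha = 0.05,
                                    mode = "signed") {
  conv <- location_network_summary(fractions, m, panel, metadata,
                                   "convexity", rho_min, alpha, mode)
  sb <- location_network_summary(fractions, m, panel, metadata,
                                 "skull_base", rho_min, alpha, mode)
  structure(list(convexity = conv, skull_base = sb,
                 differences = compare_locations(conv, sb),
                 params = list(rho_min = rho_min, alpha = alpha, mode = mode)),
            class = "immune_network_fit")
}

#' @export
print.immune_network_fit <- function(x, ...) {
  top <- x$differences
  cat("<immune_network_fit>\n")
  cat("  most convexity-active: ", top$cell_type[1], "\n")
  cat("  most skull-base-active:", top$cell_type[nrow(top)], "\n")
  invisible(x)
}
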