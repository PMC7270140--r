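make_edge_table <- function(df, location = "convexity") {
  tibble::tibble(cell_type = df$cell, cytokine = df$cyt, rho = df$rho,
                 p = df$p, n = 30L, location = location,
                 degenerate = df$degenerate %||% rep(FALSE, nrow(df)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("edge tables cover every cell-cytokine pair and flag degenerate cells", {
  md <- tiny_metadata(20, locations = rep(c("convexity", "skull_base"), 10))
  set.seed(40)
  fr <- matrix(runif(20 * 3), 20, 3,
               dimnames = list(md$sample_id, c("cellA", "cellB", "cellC")))
  fr[, "cellC"] <- 0.2  # constant fraction
  fr <- fr / rowSums(fr)
  fr[, "cellC"] <- 0.2
  vals <- matrix(rnorm(4 * 20), 4, 20,
                 dimnames = list(c("IL6", "TNF", "CCL3", "IL10"),
                                 md$sample_id))
  m <- expression_matrix(abs(vals), scale = "linear")
  edges <- cell_cytokine_edges(fr, m, c("IL6", "TNF", "CCL3", "IL10"),
                               md, "convexity")
  expect_equal(nrow(edges), 3L * 4L)
  expect_true(all(edges$n == 10))
  deg <- edges[edges$cell_type == "cellC", ]
  expect_true(all(deg$degenerate))
  expect_true(all(deg$rho == 0 & deg$p == 1))
  expect_true(all(abs(edges$rho) <= 1))

  expect_message(
    cell_cytokine_edges(fr, m, c("IL6", "NOPE"), md, "convexity"), "NOPE")
  expect_error(cell_cytokine_edges(fr, m, "IL6", md[1:4, ], "convexity"),
               "at least 3")
})

test_that("edge correlations agree with pearson_with_p per pair", {
  md <- tiny_metadata(15, locations = "convexity")
  set.seed(41)
  fr <- matrix(runif(15 * 2), 15, 2,
               dimnames = list(md$sample_id, c("cellA", "cellB")))
  vals <- matrix(rexp(3 * 15), 3, 15,
                 dimnames = list(c("IL6", "TNF", "CCL3"), md$sample_id))
  m <- expression_matrix(vals, scale = "linear")
  edges <- cell_cytokine_edges(fr, m, rownames(vals), md, "convexity")
  for (i in seq_len(nrow(edges))) {
    ref <- pearson_with_p(fr[, edges$cell_type[i]],
                          vals[edges$cytokine[i], ])
    expect_equal(edges$rho[i], ref$rho, tolerance = 1e-12)
    expect_equal(edges$p[i], ref$p, tolerance = 1e-12)
  }
})

test_that("build_network applies the positive-rho and significance gates", {
  df <- data.frame(cell = c("mast", "mast", "neut", "neut"),
                   cyt = c("IL6", "TNF", "IL1R2", "CCL3"),
                   rho = c(0.74, 0.59, 0.9, -0.8),
                   p = c(2e-7, 0.001, 0.2, 1e-5))
  g <- build_network(make_edge_table(df))
  kept <- igraph::as_edgelist(g)
  expect_equal(nrow(kept), 1L)
  expect_equal(sort(kept[1, ]), c("IL6", "mast"))
  # all nodes present even when isolated
  expect_equal(igraph::vcount(g), 6L)

  g2 <- build_network(make_edge_table(df), two_sided = TRUE)
  expect_equal(igraph::ecount(g2), 2L)  # -0.8 now kept, 0.9 still blocked by p

  # edge set invariant to row order
  df_shuffled <- df[c(3, 1, 4, 2), ]
  g3 <- build_network(make_edge_table(df_shuffled))
  expect_true(igraph::identical_graphs(
    igraph::permute(g3, match(igraph::V(g3)$name, igraph::V(g)$name)), g,
    attrs = FALSE))
})

test_that("GraphML export writes a readable graph", {
  df <- data.frame(cell = "mast", cyt = "IL6", rho = 0.7, p = 1e-4)
  g <- build_network(make_edge_table(df))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 2L)
  expect_equal(igraph::ecount(back), 1L)
})

test_that("connectivity sums significant correlations under both modes", {
  df <- data.frame(cell = c("A", "A", "A", "B"),
                   cyt = c("IL6", "TNF", "CCL3", "IL6"),
                   rho = c(0.7, -0.5, 0.9, 0.2),
                   p = c(0.01, 0.02, 0.5, 0.9))
  et <- make_edge_table(df)
  signed <- connectivity(et)
  expect_equal(signed$connectivity[signed$cell_type == "A"], 0.2,
               tolerance = 1e-12)
  expect_equal(signed$connectivity[signed$cell_type == "B"], 0)
  absolute <- connectivity(et, mode = "absolute")
  expect_equal(absolute$connectivity[absolute$cell_type == "A"], 1.2,
               tolerance = 1e-12)
})

test_that("connectivity matches a filter-and-sum oracle on random tables", {
  set.seed(43)
  for (i in 1:100) {
    n_cells <- sample(2:6, 1)
    n_cyt <- sample(2:8, 1)
    grid <- expand.grid(cell = paste0("c", seq_len(n_cells)),
                        cyt = paste0("g", seq_len(n_cyt)),
                        stringsAsFactors = FALSE)
    grid$rho <- runif(nrow(grid), -1, 1)
    grid$p <- runif(nrow(grid))
    et <- make_edge_table(grid)
    got <- connectivity(et, alpha = 0.05)
    for (cell in unique(grid$cell)) {
      sub <- grid[grid$cell == cell & grid$p < 0.05, ]
      expect_equal(got$connectivity[got$cell_type == cell],
                   sum(sub$rho), tolerance = 1e-12)
    }
  }
})

test_that("eigenvector centrality matches closed forms on known graphs", {
  # path graph cell - cytokine - cell: eigenvector (1, sqrt(2), 1)/2
  df <- data.frame(cell = c("A", "B"), cyt = c("IL6", "IL6"),
                   rho = c(0.5, 0.5), p = c(0.01, 0.01))
  cent <- eigenvector_centrality(make_edge_table(df))
  expect_equal(cent$centrality[cent$node == "IL6"], sqrt(2) / 2,
               tolerance = 1e-10)
  expect_equal(cent$centrality[cent$node == "A"], 0.5, tolerance = 1e-10)
  expect_equal(cent$centrality[cent$node == "B"], 0.5, tolerance = 1e-10)

  # isolated nodes score zero
  df2 <- data.frame(cell = c("A", "B"), cyt = c("IL6", "TNF"),
                    rho = c(0.5, 0.1), p = c(0.01, 0.9))
  cent2 <- eigenvector_centrality(make_edge_table(df2))
  expect_equal(cent2$centrality[cent2$node == "B"], 0)
  expect_equal(cent2$centrality[cent2$node == "TNF"], 0)

  # empty graph: all zeros
  df3 <- data.frame(cell = "A", cyt = "IL6", rho = 0.2, p = 0.8)
  expect_true(all(eigenvector_centrality(make_edge_table(df3))$centrality == 0))
})

test_that("eigenvector centrality matches dense eigendecomposition on random graphs", {
  set.seed(44)
  for (i in 1:25) {
    n_cells <- sample(3:12, 1)
    n_cyt <- sample(3:12, 1)
    grid <- expand.grid(cell = paste0("c", seq_len(n_cells)),
                        cyt = paste0("g", seq_len(n_cyt)),
                        stringsAsFactors = FALSE)
    grid$rho <- runif(nrow(grid), -1, 1)
    grid$p <- runif(nrow(grid), 0, 0.3)
    et <- make_edge_table(grid)
    got <- eigenvector_centrality(et, alpha = 0.05)

    nodes <- c(sort(unique(grid$cell)), sort(unique(grid$cyt)))
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    sig <- grid[grid$p < 0.05, ]
    A[cbind(match(sig$cell, nodes), match(sig$cyt, nodes))] <- 1
    A[cbind(match(sig$cyt, nodes), match(sig$cell, nodes))] <- 1
    if (all(A == 0)) next
    eig <- eigen(A, symmetric = TRUE)
    # degenerate top eigenvalue (tied components): principal eigenvector
    # is not unique, no meaningful comparison
    if (eig$values[1] - eig$values[2] < 1e-6) next
    v <- abs(eig$vectors[, 1])
    # zero out entries outside the dominant component (numerically tiny)
    v[v < 1e-8] <- 0
    v <- v / sqrt(sum(v^2))
    expect_equal(got$centrality[match(nodes, got$node)], v,
                 tolerance = 1e-8)
  }
})

test_that("compare_locations differences are antisymmetric and validated", {
  md <- tiny_metadata(24, locations = rep(c("convexity", "skull_base"),
                                          each = 12))
  set.seed(45)
  fr <- matrix(runif(24 * 4), 24, 4,
               dimnames = list(md$sample_id, paste0("cell", 1:4)))
  fr <- fr / rowSums(fr)
  vals <- matrix(rexp(5 * 24), 5, 24,
                 dimnames = list(c("IL6", "TNF", "CCL3", "IL10", "IL2"),
                                 md$sample_id))
  m <- expression_matrix(vals, scale = "linear")
  conv <- location_network_summary(fr, m, rownames(vals), md, "convexity")
  sb <- location_network_summary(fr, m, rownames(vals), md, "skull_base")

  d <- compare_locations(conv, sb)
  d_swapped <- compare_locations(sb, conv)
  expect_equal(d$delta_connectivity[match(d_swapped$cell_type, d$cell_type)],
               -d_swapped$delta_connectivity, tolerance = 1e-12)
  same <- compare_locations(conv, conv)
  expect_true(all(same$delta_connectivity == 0))
  expect_true(all(same$delta_centrality == 0))

  sb_bad <- sb
  sb_bad$connectivity <- sb_bad$connectivity[-1, ]
  expect_error(compare_locations(conv, sb_bad), "different cell-type sets")
})

test_that("planted location couplings surface in the edge tables", {
  plants <- tibble::tibble(
    cell_type = c("Mast cells activated", "T cells gamma delta"),
    cytokine = c("IL6", "CCL3"),
    location = c("convexity", "skull_base"),
    target_rho = c(0.7, 0.7))
  cfg <- sim_config(n_studies = 1, samples_per_study = 400,
                    skull_base_fraction = 0.5, n_genes = 400,
                    module_sizes = c(40, 35), markers_per_type = 3,
                    couplings = plants, batch_shift = 0, batch_scale = 1,
                    seed = 47)
  co <- generate_cohort(cfg)
  edges_c <- cell_cytokine_edges(co$truth$fractions, co$studies[[1]],
                                 co$panel, co$metadata, "convexity")
  edges_s <- cell_cytokine_edges(co$truth$fractions, co$studies[[1]],
                                 co$panel, co$metadata, "skull_base")
  planted_c <- edges_c[edges_c$cell_type == "Mast cells activated" &
                         edges_c$cytokine == "IL6", ]
  expect_equal(planted_c$rho, 0.7, tolerance = 0.1)
  cross <- edges_s[edges_s$cell_type == "Mast cells activated" &
                     edges_s$cytokine == "IL6", ]
  expect_lt(abs(cross$rho), 0.2)
  planted_s <- edges_s[edges_s$cell_type == "T cells gamma delta" &
                         edges_s$cytokine == "CCL3", ]
  expect_equal(planted_s$rho, 0.7, tolerance = 0.1)
})
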