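test_that("soft adjacency exponentiates correlations as configured", {
  # two perfectly correlated genes and one anti-correlated
  base <- c(1, 2, 3, 4, 5)
  m <- tiny_expr(rbind(base, base * 2 + 1, -base, c(2, 1, 3, 5, 4)))
  A <- soft_adjacency(m, power = 20)
  expect_equal(A["G1", "G2"], 1)
  expect_equal(A["G1", "G3"], 1)  # |-1|^20
  expect_equal(diag(A), rep(0, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(A))

  # cor 0.9 at power 20
  x <- c(1, 2, 3, 4, 5)
  y <- x + c(0.9, -0.9, 0, 0.9, -0.9)
  rho <- cor(x, y)
  A2 <- soft_adjacency(tiny_expr(rbind(x, y)), power = 20)
  expect_equal(A2[1, 2], abs(rho)^20, tolerance = 1e-12)

  # signed network maps cor -1 to 0
  As <- soft_adjacency(m, power = 2, type = "signed")
  expect_equal(As["G1", "G3"], 0, tolerance = 1e-12)

  m_const <- tiny_expr(rbind(base, rep(1, 5)), genes = c("OK", "FLAT"))
  expect_error(soft_adjacency(m_const), "FLAT")
})

test_that("topological overlap matches hand computations and brute force", {
  # 3 nodes: A12 = A13 = 0.5, A23 = 0
  A <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- 0.5
  tom <- topological_overlap(A)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(diag(tom), c(a = 1, b = 1, c = 1))

  # complete graph of ones
  A1 <- matrix(1, 3, 3) - diag(3)
  expect_equal(topological_overlap(A1)[1, 2], 1)

  # empty graph
  expect_equal(topological_overlap(matrix(0, 4, 4)),
               diag(4), ignore_attr = TRUE)

  # brute-force triple-loop oracle on a random 50-gene instance
  set.seed(12)
  m <- matrix(rnorm(50 * 20), 50, 20)
  Ar <- abs(cor(t(m)))^6
  diag(Ar) <- 0
  tom_fast <- topological_overlap(Ar)
  k <- rowSums(Ar)
  tom_slow <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    if (i == j) { tom_slow[i, j] <- 1; next }
    shared <- sum(Ar[i, ] * Ar[, j]) - Ar[i, i] * Ar[i, j] -
      Ar[i, j] * Ar[j, j]
    tom_slow[i, j] <- (sum(sapply(seq_len(50), function(u)
      Ar[i, u] * Ar[u, j])) + Ar[i, j]) / (min(k[i], k[j]) + 1 - Ar[i, j])
  }
  expect_equal(unname(tom_fast), tom_slow, tolerance = 1e-12)

  expect_error(topological_overlap(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("detect_modules recovers planted correlation blocks", {
  set.seed(8)
  n_samp <- 40
  make_block <- function(n_genes, rho = 0.9) {
    f <- rnorm(n_samp)
    t(sapply(seq_len(n_genes), function(i)
      sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samp)))
  }
  m <- rbind(make_block(50), make_block(50))
  rownames(m) <- sprintf("g%03d", seq_len(100))
  A <- soft_adjacency(tiny_expr(m, genes = rownames(m)), power = 6)
  labels <- detect_modules(topological_overlap(A), min_size = 30)
  expect_equal(length(unique(labels[labels > 0])), 2L)
  # block purity
  expect_equal(length(unique(labels[1:50])), 1L)
  expect_equal(length(unique(labels[51:100])), 1L)
  expect_true(all(labels > 0))
})

test_that("clusters below the minimum size are assigned to grey", {
  set.seed(9)
  n_samp <- 40
  f <- rnorm(n_samp)
  small_block <- t(sapply(1:10, function(i) f + rnorm(n_samp, 0, 0.2)))
  noise <- matrix(rnorm(60 * n_samp), 60, n_samp)
  m <- rbind(small_block, noise)
  rownames(m) <- sprintf("g%02d", 1:70)
  A <- soft_adjacency(tiny_expr(m, genes = rownames(m)), power = 6)
  labels <- detect_modules(topological_overlap(A), min_size = 30)
  expect_true(all(labels[1:10] == 0))
})

test_that("module labels are equivariant under gene permutation", {
  set.seed(10)
  n_samp <- 30
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  m <- rbind(t(sapply(1:35, function(i) f1 + rnorm(n_samp, 0, 0.3))),
             t(sapply(1:32, function(i) f2 + rnorm(n_samp, 0, 0.3))))
  rownames(m) <- sprintf("g%02d", 1:67)
  tom <- topological_overlap(soft_adjacency(tiny_expr(m, genes = rownames(m)),
                                            power = 6))
  labels <- detect_modules(tom, min_size = 30)
  perm <- sample(67)
  labels_perm <- detect_modules(tom[perm, perm], min_size = 30)
  expect_equal(labels_perm[names(labels)], labels)
})

test_that("module eigengenes summarise module variance with aligned sign", {
  # identical profiles: first PC explains everything
  prof <- c(1, 3, 2, 5, 4, 6)
  m <- tiny_expr(rbind(prof, prof * 2, prof + 1, rnorm(6)),
                 samples = paste0("S", 1:6))
  labels <- c(G1 = 1L, G2 = 1L, G3 = 1L, G4 = 0L)
  eg <- module_eigengene(m, labels)
  expect_equal(unname(eg$variance_explained["ME1"]), 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$metagenes[, "ME1"], prof)), 1, tolerance = 1e-12)
  expect_gt(cor(eg$metagenes[, "ME1"], prof), 0)  # sign alignment
  expect_equal(sum(eg$metagenes[, "ME1"]^2), 1, tolerance = 1e-12)

  # flipping all module genes leaves the aligned metagene invariant up to
  # the alignment rule (correlation with the mean profile >= 0)
  m_flip <- tiny_expr(rbind(-prof, -prof * 2, -(prof + 1), rnorm(6)),
                      samples = paste0("S", 1:6))
  eg_flip <- module_eigengene(m_flip, labels)
  expect_gt(cor(eg_flip$metagenes[, "ME1"],
                colMeans(t(scale(t(unclass(m_flip)[1:3, ]))))), 0)
})

test_that("orthogonal half-modules split variance evenly", {
  set.seed(14)
  a <- rnorm(40)
  b <- rnorm(40)
  b <- residuals(lm(b ~ a))  # exactly orthogonal halves
  m <- rbind(t(sapply(1:10, function(i) a + rnorm(40, 0, 1e-4))),
             t(sapply(1:10, function(i) b + rnorm(40, 0, 1e-4))))
  rownames(m) <- sprintf("g%02d", 1:20)
  eg <- module_eigengene(tiny_expr(m, genes = rownames(m)),
                         setNames(rep(1L, 20), rownames(m)))
  expect_equal(unname(eg$variance_explained["ME1"]), 0.5, tolerance = 0.05)
})

test_that("module location tests detect separation and absorb confounding", {
  md <- tiny_metadata(40, locations = rep(c("skull_base", "convexity"),
                                          each = 20))
  me <- matrix(c(rep(1, 20), rep(-1, 20)) + rnorm(40, 0, 0.05), ncol = 1,
               dimnames = list(md$sample_id, "ME1"))
  res <- test_module_location(me, md)
  expect_lt(res$mann_whitney_p, 1e-6)

  # metagene equal to grade, grade correlated with location: the
  # covariate-adjusted p-value should be much weaker than the marginal one
  set.seed(15)
  md2 <- tiny_metadata(60, locations = "convexity")
  md2$location[sample(60, 30)] <- "skull_base"
  md2$grade <- ifelse(md2$location == "skull_base", 1L, 2L)
  flip <- sample(60, 12)
  md2$grade[flip] <- 3L - md2$grade[flip]
  me2 <- matrix(as.numeric(md2$grade) + rnorm(60, 0, 0.01), ncol = 1,
                dimnames = list(md2$sample_id, "ME1"))
  res2 <- test_module_location(me2, md2)
  expect_gt(res2$adjusted_p, res2$mann_whitney_p)

  expect_error(test_module_location(me[, , drop = FALSE],
                                    dplyr::mutate(md, location = "convexity")),
               "both locations")
})

test_that("null metagenes give approximately uniform location p-values", {
  set.seed(16)
  md <- tiny_metadata(40, locations = rep(c("skull_base", "convexity"), 20))
  me <- matrix(rnorm(40 * 500), 40, 500,
               dimnames = list(md$sample_id, paste0("ME", 1:500)))
  res <- test_module_location(me, md)
  frac_sig <- mean(res$mann_whitney_p < 0.05)
  expect_gt(frac_sig, 0.02)
  expect_lt(frac_sig, 0.09)
})

test_that("cytokine labelling enforces positive rho and p thresholds", {
  set.seed(17)
  me <- matrix(rnorm(30), 30, 1, dimnames = list(paste0("S", 1:30), "ME1"))
  vals <- rbind(
    POS = me[, 1],                          # rho = 1 -> labelled
    NEG = -me[, 1],                         # rho = -1 -> excluded
    WEAK = 0.57 * me[, 1] + rnorm(30, 0, 0.9),  # below 0.6 -> excluded
    OFF = rnorm(30)
  )
  m <- tiny_expr(vals, genes = rownames(vals), samples = paste0("S", 1:30))
  labs <- label_cytokines(me, m, c("POS", "NEG", "WEAK", "OFF"))
  expect_true("POS" %in% labs$cytokine)
  expect_false("NEG" %in% labs$cytokine)
  wk <- abs(cor(vals["WEAK", ], me[, 1]))
  if (wk <= 0.6) expect_false("WEAK" %in% labs$cytokine)
  expect_message(label_cytokines(me, m, c("POS", "MISSING")), "MISSING")
})

test_that("top_module_genes ranks by kME with deterministic ties", {
  me <- c(1, 2, 3, 4, 5, 6)
  m <- tiny_expr(rbind(A = me, B = me * 2, C = -me, D = c(2, 1, 4, 3, 6, 5)),
                 genes = c("A", "B", "C", "D"), samples = paste0("S", 1:6))
  top <- top_module_genes(m, me, c("A", "B", "C", "D"), n = 4)
  # A and B tie at kME 1 -> lexicographic; C is most anti-correlated, last
  expect_equal(top$gene[1:2], c("A", "B"))
  expect_equal(top$gene[4], "C")
  # agrees with brute-force sort
  kme <- sapply(c("A", "B", "C", "D"), function(g)
    cor(unclass(m)[g, ], me))
  expect_equal(top$kme, unname(sort(kme, decreasing = TRUE)))
})

test_that("AUC follows the rank formula, trapezoid integration and known cases", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(0.8, 0.6, 0.4), c(1, 0, 1)), 0.5)

  trapezoid_auc <- function(scores, labels) {
    pts <- unique(rbind(c(0, 0),
      do.call(rbind, lapply(c(Inf, sort(unique(scores), decreasing = TRUE)),
        function(t) c(sum(scores >= t & labels == 0) / sum(labels == 0),
                      sum(scores >= t & labels == 1) / sum(labels == 1))))))
    sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) + utils::tail(pts[, 2], -1)) / 2)
  }
  set.seed(18)
  for (i in 1:20) {
    n <- 30
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels
    expect_equal(auc_rank(scores, labels), trapezoid_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("location classifier separates a planted signal and handles separation", {
  set.seed(19)
  md <- tiny_metadata(60, locations = rep(c("skull_base", "convexity"), 30))
  sig_gene <- ifelse(md$location == "skull_base", 1, -1) + rnorm(60, 0, 0.6)
  vals <- rbind(SIG = sig_gene,
                N1 = rnorm(60), N2 = rnorm(60), N3 = rnorm(60))
  m <- tiny_expr(vals, genes = rownames(vals), samples = md$sample_id)
  res <- location_classifier(m, c("SIG", "N1", "N2"), md)
  expect_gt(res$auc, 0.8)
  expect_equal(res$roc_points$fpr[1], 0)
  expect_equal(res$roc_points$tpr[nrow(res$roc_points)], 1)

  # perfectly separable input must not crash (ridge fallback)
  vals2 <- rbind(PERF = ifelse(md$location == "skull_base", 2, -2),
                 N1 = rnorm(60))
  m2 <- tiny_expr(vals2, genes = rownames(vals2), samples = md$sample_id)
  res2 <- location_classifier(m2, c("PERF", "N1"), md)
  expect_true(res2$ridge)
  expect_equal(res2$auc, 1)

  # k-fold scheme returns a sane AUC as well
  res3 <- location_classifier(m, c("SIG", "N1"), md, scheme = "kfold", k = 5)
  expect_gt(res3$auc, 0.7)
})

test_that("pick_soft_threshold returns one row per candidate power", {
  co <- generate_cohort(small_sim(seed = 23))
  prep <- preprocess_studies(co$studies, co$metadata)
  sub <- prep$matrix[1:80, ]
  m <- expression_matrix(sub, scale = "log2", standardized = TRUE)
  tab <- pick_soft_threshold(m, powers = c(1, 6, 12))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$power, c(1, 6, 12))
  expect_true(all(tab$mean_connectivity > 0))
  expect_true(all(diff(tab$mean_connectivity) < 0))
})

test_that("coexpress_modules bundles detection, tests and labels", {
  co <- generate_cohort(small_sim(seed = 29))
  prep <- preprocess_studies(co$studies, co$metadata)
  fit <- coexpress_modules(prep$matrix, co$metadata, power = 6,
                           panel = co$panel)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_true(all(td$n_genes >= 30))
  expect_equal(gl$n_modules, nrow(td))
  expect_true(all(fit$labels[fit$labels > 0] %in% seq_len(gl$n_modules)))
  # the location-shifted module must be detected and significant
  mod_genes <- names(co$truth$module_labels)[co$truth$module_labels == 1]
  mod_genes <- intersect(mod_genes, names(fit$labels))
  found <- names(which.max(table(fit$labels[mod_genes])))
  expect_true(found != "0")
  expect_lt(fit$tests$mann_whitney_p[fit$tests$module == paste0("ME", found)],
            0.05)
})
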