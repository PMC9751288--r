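test_that("log CP10K normalization does the documented arithmetic", {
  m <- matrix(c(1, 0, 9), 1, 3, dimnames = list("c", c("a", "b", "d")))
  y <- normalize_log_cp10k(m)
  expect_equal(as.numeric(y), c(log(1001), 0, log(9001)), tolerance = 1e-12)
  # scale invariance within a cell
  y2 <- normalize_log_cp10k(2 * m)
  expect_equal(as.matrix(y), as.matrix(y2))
  # monotone within a cell
  expect_true(y[1, "d"] > y[1, "a"])
  expect_warning(normalize_log_cp10k(matrix(0, 1, 2)), "all-zero")
})

test_that("HVG selection excludes constant genes and respects n_hvg", {
  set.seed(2)
  m <- cbind(const = rep(3, 100), matrix(rpois(100 * 9, 3), 100, 9))
  colnames(m)[-1] <- paste0("g", 1:9)
  hv <- suppressWarnings(select_hvgs(m, 9))
  expect_false("const" %in% hv)
  hv_all <- suppressWarnings(select_hvgs(m, 20))
  expect_setequal(hv_all, paste0("g", 1:9))
})

test_that("planted markers and opsins dominate the HVG ranking", {
  d <- acc_dataset()
  gt <- d$truth$genes
  hv <- suppressWarnings(select_hvgs(d$counts$counts, 500))
  planted <- gt$id[!is.na(gt$marker_of)]
  expect_gte(mean(planted %in% hv), 0.95)
  expect_true(all(c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6") %in% hv))
})

test_that("PCA concentrates single-axis variance and reconstructs monotonically", {
  set.seed(3)
  x <- cbind(v = rnorm(40), matrix(1, 40, 3))
  colnames(x)[-1] <- paste0("k", 1:3)
  p <- suppressWarnings(compute_pca(x, colnames(x), n_dims = 2))
  expect_equal(p$var_explained[1], 1, tolerance = 1e-9)

  y <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("g", 1:8)))
  # captured variance grows monotonically with n_dims (residual error shrinks)
  capt <- vapply(1:6, function(k) {
    p <- suppressWarnings(compute_pca(y, colnames(y), n_dims = k))
    sum(p$var_explained)
  }, 1)
  expect_true(all(diff(capt) > 0))
  expect_warning(compute_pca(y, colnames(y), n_dims = 50), "reduced")
})

test_that("same-type cells are closer than different-type cells in PC space", {
  d <- acc_dataset()
  truth <- d$truth$cells
  e <- acc_expr()
  hv <- suppressWarnings(select_hvgs(d$counts$counts, 500))
  pca <- suppressWarnings(compute_pca(e$expr, hv, 50))
  set.seed(11)
  idx <- sample(nrow(pca$scores), 600)
  dmat <- as.matrix(dist(pca$scores[idx, ]))
  same <- outer(truth$type[idx], truth$type[idx], "==")
  diag(same) <- NA
  expect_lt(mean(dmat[same & !is.na(same)]), mean(dmat[!same & !is.na(same)]))
})

test_that("SNN graph has the documented local structure", {
  pts <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  g <- build_snn_graph(pts, k = 1, prune = 0)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "b", "c"))
  # identical rows that are mutually nearest share full neighbor sets
  dup <- matrix(c(0, 0, 5, 5.1), 4, 1,
                dimnames = list(c("a", "b", "c", "d"), "x"))
  g2 <- build_snn_graph(dup, k = 1, prune = 0)
  e <- igraph::E(g2)[igraph::`%--%`("a", "b")]
  expect_equal(igraph::edge_attr(g2, "weight", e), 1)
  expect_error(build_snn_graph(pts, k = 1, prune = 1), "no edges")
})

test_that("community detection separates components and is deterministic", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("v", 1:10)
  igraph::E(g)$weight <- 1
  lab <- detect_communities(g, resolution = 1, seed = 1)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:5])), 1L)
  expect_identical(lab, detect_communities(g, resolution = 1, seed = 1))
})

test_that("2-D embedding is seeded, shaped, and neighborhood-preserving", {
  d <- acc_dataset()
  e <- acc_expr()
  hv <- suppressWarnings(select_hvgs(d$counts$counts, 500))
  pca <- suppressWarnings(compute_pca(e$expr, hv, 50))
  set.seed(5)
  idx <- sample(nrow(pca$scores), 500)
  emb1 <- embed_2d(pca$scores[idx, ], seed = 4)
  emb2 <- embed_2d(pca$scores[idx, ], seed = 4)
  expect_equal(emb1, emb2)
  expect_equal(dim(emb1), c(500L, 2L))

  tiny <- embed_2d(matrix(rnorm(6), 3, 2), seed = 1)
  expect_equal(dim(tiny), c(3L, 2L))

  # trustworthiness at k = 15, computed from its definition
  k <- 15
  dx <- as.matrix(dist(pca$scores[idx, ])); dy <- as.matrix(dist(emb1))
  n <- length(idx); s <- 0
  for (i in seq_len(n)) {
    rx <- rank(dx[i, -i]); ry <- rank(dy[i, -i])
    nnY <- which(ry <= k)
    viol <- nnY[rx[nnY] > k]
    s <- s + sum(rx[viol] - k)
  }
  trust <- 1 - 2 / (n * k * (2 * n - 3 * k - 1)) * s
  expect_gte(trust, 0.85)
})

test_that("marker-panel annotation applies the scoring and subtype rules", {
  # three clusters with hand-built panel expression
  set.seed(8)
  n <- 90
  genes <- c("Rh5", "Rh6", "sens", "ninaE", "ct", "Crys")
  m <- matrix(rpois(n * 6, 0.05), n, 6, dimnames = list(paste0("c", 1:n), genes))
  lab <- rep(c("k1", "k2", "k3"), each = 30)
  m[lab == "k1", "Rh5"] <- 30; m[lab == "k1", "sens"] <- 2   # pale R8
  m[lab == "k2", "ninaE"] <- 60                               # R1-6
  m[lab == "k3", "ct"] <- 5; m[lab == "k3", "Crys"] <- 8      # cone
  expr <- normalize_log_cp10k(m)
  panels <- list(R8 = c("Rh5", "Rh6", "sens"), `R1-6` = "ninaE",
                 cone = c("ct", "Crys"))
  ann <- annotate_clusters(expr, lab, panels)
  expect_identical(ann$label[ann$cluster == "k1"], "R8-pale")
  expect_identical(ann$type[ann$cluster == "k2"], "R1-6")
  expect_identical(ann$type[ann$cluster == "k3"], "cone")
  expect_warning(annotate_clusters(expr, lab, c(panels, list(pig = "wrapper"))),
                 "wrapper")
})

test_that("tied annotation scores are reported as ambiguous", {
  m <- matrix(5, 4, 2, dimnames = list(paste0("c", 1:4), c("a", "b")))
  m[1:2, 1] <- 9; m[3:4, 2] <- 9
  expr <- normalize_log_cp10k(m)
  ann <- annotate_clusters(expr, rep(c("k1", "k2"), each = 2),
                           panels = list(t1 = c("a", "b"), t2 = c("a", "b")))
  expect_true(all(ann$type == "ambiguous"))
})

test_that("clusters are annotated to the majority true type of their cells", {
  d <- acc_dataset()
  pipe <- acc_pipeline()
  truth <- d$truth$cells
  ct <- pipe$cluster$cell_types
  comm <- pipe$cluster$communities
  idx <- match(names(comm), truth$barcode)
  ann_type <- unname(sub("-(pale|yellow|dorsal3|DRA)$", "", ct))
  per_cluster <- tapply(seq_along(comm), comm, function(i) {
    majority <- names(which.max(table(truth$type[idx[i]])))
    identical(ann_type[i][1], majority)
  })
  expect_gte(mean(unlist(per_cluster)), 0.95)
})
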