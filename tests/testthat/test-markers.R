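test_that("rank-sum p-values match exact enumeration for small groups", {
  # spec worked example: complete separation at 3 vs 3 with a tie in one group
  expect_equal(wilcox_rank_p(c(5, 6, 7), c(0, 0, 1)), 0.1)
  set.seed(14)
  for (i in 1:60) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- round(rnorm(nx), 1); y <- round(rnorm(ny, 0.5), 1)
    r <- rank(c(x, y)); n <- nx + ny
    combs <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    mu <- nx * (n + 1) / 2
    p_oracle <- mean(abs(sums - mu) >= abs(sum(r[1:nx]) - mu) - 1e-9)
    expect_equal(wilcox_rank_p(x, y), p_oracle)
    if (!any(duplicated(c(x, y))))
      expect_equal(wilcox_rank_p(x, y),
                   stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("large-sample rank test is calibrated under the null", {
  set.seed(15)
  n_genes <- 10000
  p <- vapply(seq_len(n_genes), function(i)
    wilcox_rank_p(rpois(50, 2), rpois(50, 2)), 1)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("marker calling applies gates, fold changes, and Bonferroni", {
  set.seed(16)
  n <- 120
  m <- matrix(rpois(n * 4, 1), n, 4,
              dimnames = list(paste0("c", 1:n), c("up", "flat", "down", "rare")))
  lab <- rep(c("A", "B"), each = 60)
  m[lab == "A", "up"] <- rpois(60, 8)
  m[lab == "B", "down"] <- rpois(60, 8)
  m[, "rare"] <- 0; m[1:3, "rare"] <- 1  # fails min.pct everywhere
  expr <- normalize_log_cp10k(m)
  tab <- rank_markers_wilcoxon(expr, lab)
  expect_true("up" %in% tab$gene[tab$cluster == "A"])
  expect_false("rare" %in% tab$gene)
  # only_pos: "down" appears for B, not for A
  expect_false("down" %in% tab$gene[tab$cluster == "A"])
  expect_true("down" %in% tab$gene[tab$cluster == "B"])
  expect_true(all(tab$log2fc > 0))
  expect_true(all(tab$p_adj >= tab$p))
  # log2fc arithmetic on the CP10K scale
  cp <- expm1(expr)
  g <- tab[tab$cluster == "A" & tab$gene == "up", ]
  mi <- mean(cp[lab == "A", "up"]); mo <- mean(cp[lab == "B", "up"])
  expect_equal(g$log2fc, log2((mi + 1) / (mo + 1)))
  expect_warning(rank_markers_wilcoxon(expr, c("solo", "solo", lab[-(1:2)])),
                 "skipped")
})

test_that("log2 fold change follows the documented pseudocount formula", {
  # mean CP10K 300 in vs 30 out
  expect_equal(log2((300 + 1) / (30 + 1)), 3.279, tolerance = 1e-3)
})

test_that("marker intersection across datasets keeps common genes only", {
  t1 <- data.frame(gene = c("a", "b", "c"), cluster = "R8", p = c(1e-5, 1e-3, 1e-2))
  t2 <- data.frame(gene = c("b", "c", "d"), cluster = "R8", p = c(1e-4, 1e-6, 1e-2))
  out <- intersect_markers(list(t1, t2))
  expect_setequal(out$gene, c("b", "c"))
  expect_equal(out$gene[1], "b")  # ordered by worst p: b (1e-3) < c (1e-2)
  expect_identical(intersect_markers(list(t1, t1))$gene, t1$gene)
  t3 <- data.frame(gene = "z", cluster = "R8", p = 0.01)
  expect_equal(nrow(intersect_markers(list(t1, t3))), 0L)
  t4 <- data.frame(gene = "a", cluster = "R7", p = 0.01)
  ws <- testthat::capture_warnings(intersect_markers(list(t1, t4)))
  expect_match(ws, "absent", all = TRUE)  # R7 and R8 each missing from a table
})

test_that("planted markers survive intersection across replicate datasets", {
  tabs <- lapply(1:3, function(s) {
    d <- generate_retina_dataset(sim_config(n_cells = 3000), seed = 300 + s)
    expr <- normalize_log_cp10k(d$counts$counts)
    suppressWarnings(rank_markers_wilcoxon(expr, d$truth$cells$type))
  })
  inter <- suppressWarnings(intersect_markers(tabs))
  gt <- generate_retina_dataset(sim_config(n_cells = 10), seed = 1)$truth$genes
  found <- 0; total <- 0
  for (grp in c("cone", "pigment23")) {
    ids <- gt$id[!is.na(gt$marker_of) & gt$marker_of == grp]
    total <- total + length(ids)
    found <- found + sum(ids %in% inter$gene[inter$cluster == grp])
  }
  expect_gte(found / total, 0.9)
})

test_that("specificity classes follow the detection-threshold rules", {
  # detection patterns built directly: 4 clusters x 5 genes
  n <- 40
  lab <- rep(c("A", "B", "C", "D"), each = 10)
  m <- matrix(0, n, 5, dimnames = list(paste0("c", 1:n),
                                       c("only_a", "a_and_b", "a_b_c", "ubiq", "nohome")))
  m[lab == "A", "only_a"] <- 5
  m[lab %in% c("A", "B"), "a_and_b"] <- 5
  m[lab %in% c("A", "B", "C"), "a_b_c"] <- 5
  m[, "ubiq"] <- 5
  m[lab == "B", "nohome"] <- 5
  expr <- normalize_log_cp10k(m)
  cand <- data.frame(gene = colnames(m), cluster = "A")
  out <- classify_specificity(expr, lab, cand, tau = 0.10)
  expect_identical(out$class,
                   c("1", "2", "3", "ubiquitous", "not_expressed"))
  expect_error(classify_specificity(expr, lab, cand, exclude_clusters = "A"),
               "exclude")
  # excluding D: a gene in A+B+C over evaluated clusters becomes ubiquitous
  out2 <- classify_specificity(expr, lab, cand[3, , drop = FALSE],
                               tau = 0.10, exclude_clusters = "D")
  expect_identical(out2$class, "ubiquitous")
})

test_that("class assignment is invariant to cell order and label names", {
  e <- acc_expr()
  truth <- e$truth
  mk <- suppressWarnings(rank_markers_wilcoxon(e$expr, truth$type,
                                               min_pct = 0.25, logfc_thr = 1))
  cand <- mk[mk$cluster == "cone", ][1:10, c("gene", "cluster")]
  c1 <- classify_specificity(e$expr, truth$type, cand)
  perm <- sample(nrow(e$expr))
  c2 <- classify_specificity(e$expr[perm, ], truth$type[perm], cand)
  expect_identical(c1$class, c2$class)
})

test_that("shared-pair markers are exactly the genes confined to the pair", {
  e <- acc_expr()
  truth <- e$truth
  shared <- find_shared_pair_markers(e$expr, truth$type, c("R7", "R8"), tau = 0.10)
  planted <- e$genes$id[!is.na(e$genes$marker_of) & e$genes$marker_of == "R78"]
  expect_gte(mean(planted %in% shared), 0.9)
  # an R8-only gene (Rh5, detected in R8 but not R7) is not a pair marker
  expect_false("Rh5" %in% shared)
  expect_error(find_shared_pair_markers(e$expr, truth$type, c("R7", "nope")),
               "missing")
  m <- matrix(1, 4, 2, dimnames = list(paste0("c", 1:4), c("a", "b")))
  expect_warning(find_shared_pair_markers(normalize_log_cp10k(m),
                                          c("x", "x", "y", "y"), c("x", "y"),
                                          tau = 0), "tau")
})

test_that("hypergeometric enrichment matches direct tail summation", {
  universe <- paste0("g", 1:100)
  sets <- list(hit = paste0("g", c(1:5, 95:99)), none = paste0("g", 50:59))
  res <- hypergeom_enrichment(paste0("g", 1:10), sets, universe)
  p_oracle <- sum(stats::dhyper(5:10, 10, 90, 10))
  expect_equal(res$p[res$set == "hit"], p_oracle)
  expect_gt(res$p[res$set == "hit"], 1e-4)
  expect_lt(res$p[res$set == "hit"], 1e-3)
  expect_equal(res$p[res$set == "none"], 1)  # zero overlap, upper tail at 0
  # set identical to the list: maximal fold enrichment, minimal p
  res2 <- hypergeom_enrichment(paste0("g", 1:10),
                               c(sets, list(self = paste0("g", 1:10))), universe)
  expect_equal(res2$fold_enrichment[res2$set == "self"], 100 / 10)
  expect_equal(res2$set[which.min(res2$p)], "self")
  expect_equal(res2$q, stats::p.adjust(res2$p, "BH"))
  expect_error(hypergeom_enrichment("g1", sets, character()), "empty universe")
})
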