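test_that("batch merging joins genes and keeps barcodes unique", {
  cm <- toy_counts()
  self <- merge_batches(list(cm, cm), c("b1", "b2"))
  expect_equal(nrow(self$counts$counts), 6L)
  expect_equal(sum(self$counts$counts), 2 * sum(cm$counts))
  expect_false(any(duplicated(rownames(self$counts$counts))))

  other <- count_matrix(matrix(1:4, 2, 2, dimnames = list(c("X", "Y"), c("g3", "g4"))))
  ws <- testthat::capture_warnings(mg <- merge_batches(list(cm, other), c("b1", "b2")))
  expect_length(ws, 2)  # each batch is missing the other's genes
  expect_match(ws, "zero-filled", all = TRUE)
  expect_setequal(colnames(mg$counts$counts), c("g1", "g2", "g3", "g4"))
  expect_equal(sum(mg$counts$counts[mg$batch == "b1", c("g3", "g4")]), 0)
})

test_that("centroid correction removes a planted batch offset", {
  set.seed(51)
  sc <- matrix(rnorm(600 * 10), 600, 10) + rep(1:3, each = 200)
  batch <- rep(c("A", "B"), 300)
  off <- sc
  off[batch == "B", ] <- off[batch == "B", ] + 2
  rownames(off) <- paste0("c", 1:600)
  corr <- correct_batch_centroids(off, batch, seed = 5)
  offset_norm <- sqrt(10 * 4)
  blob <- rep(1:3, each = 200)
  gaps <- vapply(1:3, function(k)
    sqrt(sum((colMeans(corr[blob == k & batch == "A", ]) -
              colMeans(corr[blob == k & batch == "B", ]))^2)), 1)
  expect_true(all(gaps < 0.1 * offset_norm))
  # single batch: identity
  expect_identical(correct_batch_centroids(off, rep("A", 600)), off)
})

test_that("male/female integration restores joint type structure", {
  # the sex comparison merges the two 1-day datasets, so both batches are
  # generated at the single 1D timepoint (no depth-decline mixture)
  mk1d <- function(seed, sex) generate_retina_dataset(
    sim_config(n_cells = 900, sex = sex, depth_decline = c(`1D` = 1)), seed = seed)
  d_m <- mk1d(61, "M")
  d_f <- mk1d(62, "F")
  mg <- merge_batches(list(d_m$counts, d_f$counts), c("M", "F"))
  truth <- c(d_m$truth$cells$type, d_f$truth$cells$type)
  m <- mg$counts$counts
  expr <- normalize_log_cp10k(m)
  hv <- suppressWarnings(select_hvgs(m, 500))
  pca <- suppressWarnings(compute_pca(expr, hv, 50))
  # plant a constant batch offset in PC space, then correct it away
  sc <- pca$scores
  sc[mg$batch == "F", ] <- sc[mg$batch == "F", ] + 3
  corr <- correct_batch_centroids(sc, mg$batch, seed = 6)
  g <- build_snn_graph(corr, k = 20)
  comm <- detect_communities(g, 0.8, seed = 6)
  ari <- adjusted_rand_index(truth, comm[rownames(corr)])
  expect_gte(ari, 0.9)
  # per-cluster batch proportions near the global mix
  global <- mean(mg$batch == "M")
  props <- tapply(mg$batch == "M", comm[rownames(corr)], mean)
  big <- props[table(comm)[names(props)] >= 100]
  expect_true(all(abs(big - global) <= 0.10))
})

test_that("sex screen applies verdict rules and is symmetric under label swap", {
  set.seed(52)
  n <- 240
  sex <- rep(c("M", "F"), each = n / 2)
  m <- matrix(rpois(n * 4, 2), n, 4,
              dimnames = list(paste0("c", 1:n),
                              c("male_only", "f_higher", "flat", "weak")))
  # balanced library sizes by sex: M gains male_only (4), F gains f_higher (+4),
  # so CP10K of untouched genes stays comparable between sexes
  m[sex == "F", "male_only"] <- 0
  m[sex == "M", "male_only"] <- rpois(n / 2, 4)
  m[sex == "F", "f_higher"] <- rpois(n / 2, 6)  # 3-fold higher in F, detected in both
  expr <- normalize_log_cp10k(m)
  scr <- sex_specific_screen(expr, rep("k", n), sex)
  expect_identical(scr$verdict[scr$gene == "male_only"], "sex_specific")
  expect_identical(scr$verdict[scr$gene == "f_higher"], "fold_different")
  expect_false("flat" %in% scr$gene)
  swapped <- sex_specific_screen(expr, rep("k", n),
                                 ifelse(sex == "M", "F", "M"))
  expect_identical(sort(swapped$gene), sort(scr$gene))
  expect_equal(swapped$log2_mf[order(swapped$gene)],
               -scr$log2_mf[order(scr$gene)])
  expect_identical(swapped$verdict[order(swapped$gene)],
                   scr$verdict[order(scr$gene)])
  expect_warning(sex_specific_screen(expr, rep(c("k", "solo"), c(n - 2, 2)),
                                     sex), "skipped")
})

test_that("timepoint mixing scores composition homogeneity", {
  lab <- rep(c("A", "B"), each = 300)
  tp <- c(rep(c("1D", "3D", "7D"), 100), rep("1D", 300))
  out <- timepoint_mixing(lab, tp)
  expect_equal(out$H_norm[out$cluster == "B"], 0)
  # a cluster matching the global composition exactly scores 1
  lab2 <- rep(c("A", "B"), 300)
  tp2 <- rep(c("1D", "1D", "3D", "3D", "7D", "7D"), 100)
  out2 <- timepoint_mixing(lab2, tp2)
  expect_equal(out2$H_norm, c(1, 1))
  expect_error(timepoint_mixing(lab, rep("1D", 600)), "2 timepoints")
})

test_that("aging trend reports per-timepoint medians and direction", {
  metrics <- data.frame(barcode = paste0("c", 1:60), total_counts = rep(c(100, 100, 60), each = 20),
                        n_genes = rep(c(50, 50, 30), each = 20), mito_fraction = 0)
  tp <- rep(c("1D", "3D", "7D"), each = 20)
  out <- aging_trend(metrics, tp, order = c("1D", "3D", "7D"))
  expect_true(out$decreasing)
  expect_equal(out$table$median_counts, c(100, 100, 60))
  flat <- aging_trend(transform(metrics, total_counts = 80), tp)
  expect_false(flat$decreasing)
  single <- aging_trend(metrics[tp == "1D", ], tp[tp == "1D"])
  expect_true(is.na(single$decreasing))
  expect_equal(nrow(single$table), 1L)
})

test_that("exact binomial ratio test matches brute-force enumeration", {
  r <- ratio_test_binomial(3, 7, 0.3)
  expect_equal(r$p, 1.0)
  expect_lt(ratio_test_binomial(58, 441, 0.3)$p, 1e-15)
  expect_error(ratio_test_binomial(0, 0), "at least one")
  expect_error(ratio_test_binomial(-1, 5), "non-negative")
  set.seed(53)
  for (i in 1:50) {
    n <- sample(1:500, 1); x <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    out <- ratio_test_binomial(x, n - x, p0)
    bt <- stats::binom.test(x, n, p0)
    expect_equal(out$p, bt$p.value, tolerance = 1e-9)
    expect_equal(c(out$conf_low, out$conf_high), as.numeric(bt$conf.int),
                 tolerance = 1e-9)
    expect_gte(out$estimate, out$conf_low)
    expect_lte(out$estimate, out$conf_high)
  }
})
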