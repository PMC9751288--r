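#' Merge count matrices across batches
#'
#' Gene lists are reconciled by id (outer join; genes absent from a batch
#' are zero-filled with a warning) and barcodes are suffixed with the batch
#' label so they stay unique even on collision.
#'
#' @param matrices list of [count_matrix()] / cells x genes matrices.
#' @param batches character vector of batch labels, one per matrix.
#' @return list: `counts` (merged [count_matrix()]), `batch` (per-cell label).
#' @export
merge_batches <- function(matrices, batches) {
  stopifnot(length(matrices) == length(batches), length(matrices) >= 1)
  ms <- lapply(matrices, as_counts)
  gene_union <- Reduce(union, lapply(ms, colnames))
  filled <- mapply(function(m, b) {
    missing <- setdiff(gene_union, colnames(m))
    if (length(missing)) {
      warning("batch ", b, ": ", length(missing), " gene(s) zero-filled")
      m <- cbind(m, Matrix::sparseMatrix(
        i = integer(), j = integer(), x = numeric(),
        dims = c(nrow(m), length(missing)),
        dimnames = list(rownames(m), missing)))
    }
    m <- m[, gene_union, drop = FALSE]
    rownames(m) <- paste(rownames(m), b, sep = "_")
    m
  }, ms, batches, SIMPLIFY = FALSE)
  merged <- do.call(rbind, filled)
  batch <- rep(batches, vapply(ms, nrow, 1L))
  list(counts = count_matrix(merged), batch = batch)
}

#' Iterative centroid batch correction in PC space
#'
#' A deliberately transparent stand-in for mixture-model integration:
#' iterate { cluster all cells jointly on the current scores; within each
#' cluster, translate each batch's cells so batch centroids coincide with
#' the cluster centroid (only for batches with >= 10 cells in the cluster) }
#' until the largest translation is below `tol` or `max_iter` is reached.
#' Exact for batches differing by a constant offset with shared composition.
#'
#' @param scores cells x dims PC score matrix.
#' @param batch per-cell batch labels (>= 2 batches).
#' @param max_iter maximum iterations (default 10).
#' @param tol convergence threshold on the largest centroid translation.
#' @param k neighbors for the joint SNN clustering.
#' @param resolution community resolution for the joint clustering.
#' @param seed integer seed.
#' @param min_cells minimum batch cells in a cluster for translation.
#' @return corrected score matrix.
#' @export
correct_batch_centroids <- function(scores, batch, max_iter = 10, tol = 1e-3,
                                    k = 20, resolution = 0.8, seed = 1L,
                                    min_cells = 10) {
  batch <- as.character(batch)
  stopifnot(nrow(scores) == length(batch))
  if (length(unique(batch)) < 2) return(scores)
  cur <- scores
  # global alignment first (the single-cluster case of the iteration): a pure
  # between-batch offset is removed here, so batch-pure clusters downstream
  # cannot freeze the correction
  centroid <- colMeans(cur)
  for (b in unique(batch)) {
    bi <- which(batch == b)
    cur[bi, ] <- sweep(cur[bi, , drop = FALSE], 2,
                       centroid - colMeans(cur[bi, , drop = FALSE]), "+")
  }
  for (it in seq_len(max_iter)) {
    graph <- build_snn_graph(cur, k = min(k, nrow(cur) - 1))
    comm <- detect_communities(graph, resolution, derive_seed(seed, paste0("bc", it)))
    max_shift <- 0
    for (cl in unique(comm)) {
      idx <- which(comm == cl)
      centroid <- colMeans(cur[idx, , drop = FALSE])
      for (b in unique(batch[idx])) {
        bi <- idx[batch[idx] == b]
        if (length(bi) < min_cells) next
        shift <- centroid - colMeans(cur[bi, , drop = FALSE])
        cur[bi, ] <- sweep(cur[bi, , drop = FALSE], 2, shift, "+")
        max_shift <- max(max_shift, sqrt(sum(shift^2)))
      }
    }
    if (max_shift < tol) break
  }
  cur
}

#' Male/female sex-specific marker screen
#'
#' Per evaluated cluster, each gene is rank-tested male vs female on
#' normalized expression, Bonferroni-adjusted over the cluster's tested
#' genes. Candidates (p_adj < `alpha`) get a verdict: `sex_specific` if
#' detection is >= `tau_hi` in one sex and <= `tau_lo` in the other;
#' otherwise `fold_different` if the mean-CP10K ratio is >= `fold_thr` (or
#' <= 1/`fold_thr`); otherwise `pattern_equivalent`. Clusters missing a sex
#' are skipped with a warning.
#'
#' @param expr normalized cells x genes matrix.
#' @param labels per-cell cluster labels.
#' @param sex per-cell sex labels (two levels, e.g. "M"/"F").
#' @param alpha adjusted-p cutoff for candidates.
#' @param fold_thr fold-change threshold (default 2).
#' @param tau_hi,tau_lo detection thresholds for the sex-specific call.
#' @param exclude_clusters clusters skipped (e.g. cone / primary pigment
#'   when one sex has too few cells).
#' @param min_pct,logfc_thr test gates as in [rank_markers_wilcoxon()]
#'   (two-sided: enrichment in either sex).
#' @return data.frame: gene, cluster, p, p_adj, log2_mf, det_m, det_f, verdict.
#' @export
sex_specific_screen <- function(expr, labels, sex, alpha = 0.05, fold_thr = 2,
                                tau_hi = 0.25, tau_lo = 0.05,
                                exclude_clusters = character(),
                                min_pct = 0.1, logfc_thr = 0.25) {
  labels <- as.character(labels); sex <- as.character(sex)
  stopifnot(nrow(expr) == length(labels), nrow(expr) == length(sex))
  sexes <- sort(unique(sex))
  stopifnot(length(sexes) == 2)
  cp10k <- expm1(expr)
  out <- lapply(setdiff(sort(unique(labels)), exclude_clusters), function(k) {
    idx <- which(labels == k)
    male_level <- if ("M" %in% sexes) "M" else sexes[1]
    im <- idx[sex[idx] == male_level]
    if_ <- setdiff(idx, im)
    if (length(im) < 3 || length(if_) < 3) {
      warning("cluster ", k, " skipped: a sex has fewer than 3 cells")
      return(NULL)
    }
    det_m <- Matrix::colSums(detection_counts(cp10k, im)) / length(im)
    det_f <- Matrix::colSums(detection_counts(cp10k, if_)) / length(if_)
    mean_m <- Matrix::colMeans(cp10k[im, , drop = FALSE])
    mean_f <- Matrix::colMeans(cp10k[if_, , drop = FALSE])
    log2_mf <- log2((mean_m + 1) / (mean_f + 1))
    gate <- pmax(det_m, det_f) >= min_pct & abs(log2_mf) >= logfc_thr
    genes <- which(gate)
    if (!length(genes)) return(NULL)
    p <- vapply(genes, function(g) {
      v <- expr[, g]
      wilcox_rank_p(as.numeric(v[im]), as.numeric(v[if_]))
    }, 1)
    p_adj <- pmin(1, p * length(genes))
    keep <- which(p_adj < alpha)
    if (!length(keep)) return(NULL)
    g <- genes[keep]
    verdict <- mapply(function(dm, df, l2) {
      if ((dm >= tau_hi && df <= tau_lo) || (df >= tau_hi && dm <= tau_lo))
        "sex_specific"
      else if (l2 >= log2(fold_thr) || l2 <= -log2(fold_thr)) "fold_different"
      else "pattern_equivalent"
    }, det_m[g], det_f[g], log2_mf[g])
    data.frame(gene = colnames(expr)[g], cluster = k,
               p = p[keep], p_adj = p_adj[keep],
               log2_mf = as.numeric(log2_mf[g]),
               det_m = as.numeric(det_m[g]), det_f = as.numeric(det_f[g]),
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(gene = character(), cluster = character(),
                                      p = numeric(), p_adj = numeric(),
                                      log2_mf = numeric(), det_m = numeric(),
                                      det_f = numeric(), verdict = character())
  rownames(out) <- NULL
  out
}

#' Timepoint composition mixing per cluster
#'
#' For each cluster, the Shannon entropy of its timepoint composition
#' normalized by the entropy of the global composition (`H_norm` = 1 when
#' the cluster mirrors the dataset, 0 for a single-timepoint cluster), plus
#' a chi-square test of composition homogeneity.
#'
#' @param labels per-cell cluster labels.
#' @param timepoint per-cell timepoint labels (>= 2 timepoints overall).
#' @return data.frame: cluster, n, H_norm, chisq_p.
#' @export
timepoint_mixing <- function(labels, timepoint) {
  labels <- as.character(labels); timepoint <- as.character(timepoint)
  stopifnot(length(labels) == length(timepoint))
  tps <- sort(unique(timepoint))
  if (length(tps) < 2) stop("need at least 2 timepoints")
  global <- table(factor(timepoint, levels = tps))
  h_global <- shannon_entropy(as.numeric(global))
  out <- lapply(sort(unique(labels)), function(k) {
    cnt <- table(factor(timepoint[labels == k], levels = tps))
    h <- shannon_entropy(as.numeric(cnt))
    exp_cnt <- sum(cnt) * as.numeric(global) / sum(global)
    chisq_p <- tryCatch(
      suppressWarnings(stats::chisq.test(as.numeric(cnt), p = as.numeric(global) / sum(global))$p.value),
      error = function(e) NA_real_)
    data.frame(cluster = k, n = sum(cnt),
               H_norm = if (h_global > 0) h / h_global else NA_real_,
               chisq_p = chisq_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-timepoint depth medians and aging trend
#'
#' Median detected genes and molecules per cell for each timepoint (in the
#' given order), with a flag indicating a monotone decrease of the molecule
#' median across the ordered timepoints (NA for a single timepoint).
#'
#' @param metrics data.frame from [compute_qc_metrics()].
#' @param timepoint per-cell timepoint labels.
#' @param order timepoint order (default: sorted unique labels).
#' @return list: `table` (timepoint, n_cells, median_genes, median_counts),
#'   `decreasing` flag.
#' @export
aging_trend <- function(metrics, timepoint, order = sort(unique(timepoint))) {
  stopifnot(nrow(metrics) == length(timepoint))
  tab <- do.call(rbind, lapply(order, function(tp) {
    sel <- timepoint == tp
    data.frame(timepoint = tp, n_cells = sum(sel),
               median_genes = stats::median(metrics$n_genes[sel]),
               median_counts = stats::median(metrics$total_counts[sel]),
               stringsAsFactors = FALSE)
  }))
  decreasing <- if (nrow(tab) < 2) NA else
    all(diff(tab$median_counts) <= 0) && any(diff(tab$median_counts) < 0)
  list(table = tab, decreasing = decreasing)
}

#' Exact binomial test of a pale:yellow ratio
#'
#' Two-sided exact binomial p for observing `n_pale` pale cells out of
#' `n_pale + n_yellow` against the expected pale fraction `p0` (minimum-
#' likelihood method: the p-value sums the probabilities of all outcomes no
#' more likely than the observed count), with the Clopper-Pearson 95% CI
#' for the pale fraction.
#'
#' @param n_pale,n_yellow non-negative counts, at least one positive.
#' @param p0 expected pale fraction (default 0.3, the canonical 30:70).
#' @return list: n_pale, n_yellow, estimate, p0, p, conf_low, conf_high.
#' @export
ratio_test_binomial <- function(n_pale, n_yellow, p0 = 0.3) {
  if (n_pale < 0 || n_yellow < 0) stop("counts must be non-negative")
  n <- n_pale + n_yellow
  if (n < 1) stop("need at least one observed cell")
  stopifnot(p0 >= 0, p0 <= 1)
  d <- stats::dbinom(0:n, n, p0)
  p <- sum(d[d <= d[n_pale + 1] * (1 + 1e-7)])
  p <- min(1, p)
  conf_low <- if (n_pale == 0) 0 else stats::qbeta(0.025, n_pale, n_yellow + 1)
  conf_high <- if (n_pale == n) 1 else stats::qbeta(0.975, n_pale + 1, n_yellow)
  list(n_pale = n_pale, n_yellow = n_yellow, estimate = n_pale / n, p0 = p0,
       p = p, conf_low = conf_low, conf_high = conf_high)
}
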