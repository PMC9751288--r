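#' Log CP10K normalization
#'
#' `y_cg = ln(1 + 1e4 * x_cg / N_c)` with `N_c` the cell's library size.
#' Scale-invariant within a cell and monotone in the counts. All-zero cells
#' yield all-zero rows with a warning.
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @return sparse cells x genes matrix of normalized expression.
#' @export
normalize_log_cp10k <- function(x) {
  m <- as_counts(x)
  N <- Matrix::rowSums(m)
  if (any(N == 0)) warning(sum(N == 0), " all-zero cell(s) left as zero rows")
  inv <- ifelse(N > 0, 1e4 / N, 0)
  trip <- Matrix::summary(m)
  y <- log1p(trip$x * inv[trip$i])
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = y, dims = dim(m),
                       dimnames = dimnames(m))
}

#' Pearson-residual normalization (optional alternative)
#'
#' Residuals of an NB model with per-gene means proportional to library size
#' and fixed overdispersion `theta`; provided for sensitivity analysis next
#' to the default log CP10K. Residuals are clipped at `+/- sqrt(n)`.
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @param theta fixed NB overdispersion (default 0.1).
#' @return dense cells x genes matrix of residuals.
#' @export
normalize_pearson_residuals <- function(x, theta = 0.1) {
  m <- as_counts(x)
  N <- Matrix::rowSums(m)
  pg <- Matrix::colSums(m) / max(sum(m), 1)
  mu <- outer(as.numeric(N), as.numeric(pg))     # expected counts
  r <- (as.matrix(m) - mu) / sqrt(mu + theta * mu^2)
  r[!is.finite(r)] <- 0
  clip <- sqrt(nrow(m))
  pmin(pmax(r, -clip), clip)
}

#' Select highly variable genes by standardized variance
#'
#' Per-gene standardized variance against a mean-variance trend: a degree-2
#' polynomial of log10 variance on log10 mean is fit across genes with
#' positive variance, giving an expected sd per gene; counts are clipped at
#' `mean + clip_mult * sd_trend` and the variance of the clipped counts,
#' divided by the trend variance, is the ranking statistic. The default
#' `clip_mult = sqrt(n)` only tames extreme outlier cells, so rare but
#' strongly expressed genes (such as the Rhodopsins, each confined to a
#' small photoreceptor class) keep their full variance signal. Constant
#' genes are never selected. Ties break by gene id.
#'
#' @param x a [count_matrix()] or cells x genes raw count matrix.
#' @param n_hvg number of genes to return.
#' @param clip_mult clip counts at `mean + clip_mult * sd_trend`
#'   (default `sqrt(n)` cells).
#' @return character vector of gene ids, ranked by decreasing standardized
#'   variance; shorter than `n_hvg` (with a warning) if fewer genes vary.
#' @export
select_hvgs <- function(x, n_hvg, clip_mult = NULL) {
  m <- as_counts(x)
  n <- nrow(m)
  stopifnot(n >= 2)
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colSums(m^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  informative <- which(v > 0 & mu > 0)
  if (!length(informative)) stop("no gene has positive variance")
  lm_fit <- stats::lm(lv ~ stats::poly(lmu, 2),
                      data = data.frame(lmu = log10(mu[informative]),
                                        lv = log10(v[informative])))
  sd_trend <- rep(NA_real_, ncol(m))
  sd_trend[informative] <- sqrt(10^stats::fitted(lm_fit))
  if (is.null(clip_mult)) clip_mult <- sqrt(n)
  clip <- mu + clip_mult * sd_trend
  std_var <- rep(-Inf, ncol(m))
  cm <- methods::as(m, "CsparseMatrix")
  trip <- Matrix::summary(cm)
  xc <- pmin(trip$x, clip[trip$j])
  sum_c <- rep(0, ncol(m)); sum_c2 <- rep(0, ncol(m))
  agg <- rowsum(cbind(xc, xc^2), trip$j)
  jidx <- as.integer(rownames(agg))
  sum_c[jidx] <- agg[, 1]; sum_c2[jidx] <- agg[, 2]
  var_c <- (sum_c2 - sum_c^2 / n) / (n - 1)
  std_var[informative] <- var_c[informative] / sd_trend[informative]^2
  ids <- colnames(m)
  if (is.null(ids)) ids <- sprintf("G%05d", seq_len(ncol(m)))
  ord <- order(-std_var, ids)
  ord <- ord[std_var[ord] > -Inf]
  if (length(ord) < n_hvg) {
    warning("only ", length(ord), " informative genes available (< n_hvg = ", n_hvg, ")")
    return(ids[ord])
  }
  ids[ord[seq_len(n_hvg)]]
}

#' Principal component analysis on scaled HVG expression
#'
#' HVG columns of the normalized expression are centered and standardized,
#' clipped at `+/- 10`, and decomposed by truncated SVD. With
#' `scale = "trend"` (the default) each gene is divided by the sd *expected
#' from its mean* (a degree-2 log-log polynomial trend of variance on mean,
#' fit across all genes), so genes whose variance exceeds the trend -- e.g.
#' a Rhodopsin confined to one photoreceptor subtype -- keep standardized
#' variance above 1 and can dominate the decomposition, as they do under
#' variance-stabilizing (SCTransform-style) workflows. `scale = "unit"`
#' z-scores every gene to variance 1. The trend scaling falls back to unit
#' scaling when too few genes inform the fit. The sign of each component is
#' fixed so its largest-magnitude gene loading is positive, making scores
#' deterministic.
#'
#' @param expr normalized cells x genes matrix.
#' @param hvgs gene ids to use (non-empty).
#' @param n_dims number of components (reduced with a warning if it exceeds
#'   what the data support).
#' @param scale `"trend"` (variance-preserving standardization against the
#'   mean-variance trend) or `"unit"` (classical z-scoring).
#' @return list: `scores` (cells x dims), `loadings` (genes x dims), `sdev`,
#'   `var_explained` (fraction per component).
#' @export
compute_pca <- function(expr, hvgs, n_dims = 50, scale = c("trend", "unit")) {
  scale <- match.arg(scale)
  stopifnot(length(hvgs) >= 1)
  hvgs <- intersect(hvgs, colnames(expr))
  z <- as.matrix(expr[, hvgs, drop = FALSE])
  mu <- colMeans(z)
  sd_emp <- apply(z, 2, stats::sd)
  sd_use <- sd_emp
  if (scale == "trend") {
    all_mu <- Matrix::colMeans(expr)
    all_v <- Matrix::colMeans(expr^2) - all_mu^2
    ok <- which(all_mu > 0 & all_v > 0)
    if (length(ok) >= 10) {
      fit <- stats::lm(lv ~ stats::poly(lmu, 2),
                       data = data.frame(lmu = log10(all_mu[ok]), lv = log10(all_v[ok])))
      pred <- stats::predict(fit, newdata = data.frame(lmu = log10(pmax(mu, min(all_mu[ok])))))
      sd_use <- sqrt(10^pred)
    }
  }
  sd_use[sd_emp == 0] <- Inf  # constant genes contribute nothing
  z <- sweep(sweep(z, 2, mu, "-"), 2, sd_use, "/")
  z <- pmin(pmax(z, -10), 10)
  max_dims <- min(nrow(z) - 1L, ncol(z))
  if (n_dims > max_dims) {
    warning("n_dims reduced from ", n_dims, " to ", max_dims)
    n_dims <- max_dims
  }
  total_var <- sum(apply(z, 2, stats::var))
  sv <- if (n_dims >= 0.5 * min(dim(z)) || min(dim(z)) < 50) {
    s <- svd(z, nu = n_dims, nv = n_dims)
    list(u = s$u, d = s$d[seq_len(n_dims)], v = s$v)
  } else {
    s <- irlba::irlba(z, nv = n_dims)
    list(u = s$u, d = s$d, v = s$v)
  }
  flip <- vapply(seq_len(n_dims), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 1)
  scores <- sweep(sv$u %*% diag(sv$d, n_dims), 2, flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  rownames(scores) <- rownames(expr)
  rownames(loadings) <- hvgs
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_dims))
  sdev <- sv$d / sqrt(max(nrow(z) - 1, 1))
  list(scores = scores, loadings = loadings, sdev = sdev,
       var_explained = sdev^2 / total_var)
}

#' Shared-nearest-neighbor graph
#'
#' kNN by Euclidean distance in PC space (each cell's neighbor set includes
#' itself); edge weight between two cells is the Jaccard overlap of their
#' neighbor sets; edges with weight at or below `prune` are removed.
#'
#' @param scores cells x dims PC score matrix.
#' @param k number of neighbors (excluding self).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return an undirected weighted [igraph::graph] with one vertex per cell.
#' @export
build_snn_graph <- function(scores, k = 20, prune = 1 / 15) {
  n <- nrow(scores)
  stopifnot(k < n)
  nn <- RANN::nn2(scores, k = k + 1)$nn.idx  # includes self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                              j = as.integer(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  trip <- Matrix::summary(methods::as(shared, "CsparseMatrix"))
  jac <- trip$x / (2 * (k + 1) - trip$x)
  keep <- trip$i < trip$j & jac > prune
  if (!any(keep))
    stop("SNN graph has no edges after pruning; increase k or lower prune")
  vnames <- rownames(scores)
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = vnames[trip$i[keep]], to = vnames[trip$j[keep]],
               weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = vnames))
  g
}

#' Community detection on the SNN graph
#'
#' Multi-level modularity optimization (Louvain) at the given resolution,
#' seeded for determinism. Singleton components receive their own labels.
#'
#' @param graph weighted undirected graph from [build_snn_graph()].
#' @param resolution modularity resolution (default 0.8).
#' @param seed integer seed.
#' @return character vector of cluster labels named by cell.
#' @export
detect_communities <- function(graph, resolution = 0.8, seed = 1L) {
  set.seed(derive_seed(seed, "detect_communities"))
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  stats::setNames(as.character(igraph::membership(comm)),
                  igraph::V(graph)$name)
}

#' Seeded 2-D embedding for reporting
#'
#' UMAP on the PC scores. The embedding is for visual reporting only; no
#' downstream statistic in this package depends on it.
#'
#' @param scores cells x dims PC score matrix.
#' @param seed integer seed.
#' @param n_neighbors UMAP neighborhood size (capped at cells - 1).
#' @return cells x 2 coordinate matrix.
#' @export
embed_2d <- function(scores, seed = 1L, n_neighbors = 15) {
  set.seed(derive_seed(seed, "embed_2d"))
  nb <- max(2L, min(n_neighbors, nrow(scores) - 1L))
  init <- if (nrow(scores) < 20) "random" else "spectral"
  emb <- uwot::umap(scores, n_neighbors = nb, init = init,
                    n_threads = 1, n_sgd_threads = 0)
  rownames(emb) <- rownames(scores)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' Annotate clusters with cell types from marker panels
#'
#' Per cluster and candidate type, the score is the mean (over the type's
#' panel genes) of the cluster's mean expression z-scored across clusters;
#' the argmax type is assigned, with exact ties reported as `"ambiguous"`.
#' Inner-photoreceptor subtypes follow the opsin rules: an R7 cluster is pale
#' if its mean Rh3 exceeds its mean Rh4 (else yellow), an R8 cluster pale if
#' Rh5 exceeds Rh6; an R7 cluster with both Rh3 and Rh4 detected in >= 50%
#' of cells is flagged dorsal-third; a cluster with Rh3 and hth detection
#' >= 50% and Rh4-Rh6 detection < 10% is flagged DRA.
#'
#' @param expr normalized cells x genes matrix.
#' @param labels per-cell cluster labels.
#' @param panels named list: type -> panel gene ids (see
#'   [default_marker_panels()]); panel genes absent from the matrix warn and
#'   are skipped.
#' @return data.frame: cluster, type, subtype, dorsal3, dra, score, label.
#' @export
annotate_clusters <- function(expr, labels, panels = default_marker_panels()$panels) {
  labels <- as.character(labels)
  stopifnot(nrow(expr) == length(labels))
  mbc <- means_by_cluster(expr, labels)
  det <- detection_by_cluster(expr, labels)
  zc <- scale(mbc)            # z-score each gene across clusters
  zc[!is.finite(zc)] <- 0
  score_mat <- vapply(names(panels), function(ty) {
    genes <- panels[[ty]]
    miss <- setdiff(genes, colnames(zc))
    if (length(miss))
      warning("panel '", ty, "': gene(s) absent, skipped: ", paste(miss, collapse = ", "))
    genes <- intersect(genes, colnames(zc))
    if (!length(genes)) return(rep(NA_real_, nrow(zc)))
    rowMeans(zc[, genes, drop = FALSE])
  }, numeric(nrow(mbc)))
  score_mat <- matrix(score_mat, nrow = nrow(mbc),
                      dimnames = list(rownames(mbc), names(panels)))
  getm <- function(mat, k, g) if (g %in% colnames(mat)) mat[k, g] else 0
  out <- lapply(rownames(mbc), function(k) {
    sc <- score_mat[k, ]
    best <- max(sc, na.rm = TRUE)
    winners <- names(sc)[!is.na(sc) & sc == best]
    ty <- if (length(winners) == 1) winners else "ambiguous"
    subtype <- NA_character_; dorsal3 <- FALSE; dra <- FALSE
    if (ty %in% c("R7", "R8")) {
      a <- if (ty == "R7") "Rh3" else "Rh5"
      b <- if (ty == "R7") "Rh4" else "Rh6"
      subtype <- if (getm(mbc, k, a) > getm(mbc, k, b)) "pale" else "yellow"
      if (ty == "R7" && getm(det, k, "Rh3") >= 0.5 && getm(det, k, "Rh4") >= 0.5)
        dorsal3 <- TRUE
    }
    if (getm(det, k, "Rh3") >= 0.5 && getm(det, k, "hth") >= 0.5 &&
        getm(det, k, "Rh4") < 0.1 && getm(det, k, "Rh5") < 0.1 &&
        getm(det, k, "Rh6") < 0.1)
      dra <- TRUE
    label <- if (is.na(subtype)) ty else paste(ty, subtype, sep = "-")
    data.frame(cluster = k, type = ty, subtype = subtype, dorsal3 = dorsal3,
               dra = dra, score = best, label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
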