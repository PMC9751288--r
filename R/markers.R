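#' One-vs-rest rank-sum marker calling
#'
#' For each cluster, genes are gated before testing: a gene is tested only if
#' its detection fraction reaches `min_pct` in the cluster or in the rest,
#' and its log2 fold change of `(mean CP10K + 1)` clears `logfc_thr` (and is
#' positive when `only_pos`). Tested genes get a two-sided Wilcoxon rank-sum
#' p on the normalized expression (exact enumeration when both groups have
#' at most 10 cells, tie-corrected normal approximation otherwise) and a
#' Bonferroni-adjusted p over the cluster's tested set. Clusters with fewer
#' than 3 cells are skipped with a warning.
#'
#' @param expr normalized (log CP10K) cells x genes matrix.
#' @param labels per-cell cluster labels.
#' @param min_pct detection-fraction gate (default 0.25).
#' @param logfc_thr log2 fold-change gate (default 0.25).
#' @param only_pos keep only positively enriched genes (default TRUE).
#' @return data.frame: gene, cluster, log2fc, pct_in, pct_out, p, p_adj.
#' @export
rank_markers_wilcoxon <- function(expr, labels, min_pct = 0.25,
                                  logfc_thr = 0.25, only_pos = TRUE) {
  labels <- as.character(labels)
  stopifnot(nrow(expr) == length(labels))
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters")
  det <- detection_by_cluster(expr, labels)
  cp10k <- expm1(expr)  # back to CP10K scale for fold changes
  tabs <- lapply(cl, function(k) {
    in_idx <- which(labels == k)
    out_idx <- which(labels != k)
    if (length(in_idx) < 3 || length(out_idx) < 3) {
      warning("cluster ", k, " skipped: fewer than 3 cells in a compared group")
      return(NULL)
    }
    pct_in <- det[k, ]
    nz_out <- Matrix::colSums(detection_counts(cp10k, out_idx))
    pct_out <- nz_out / length(out_idx)
    mean_in <- Matrix::colMeans(cp10k[in_idx, , drop = FALSE])
    mean_out <- Matrix::colMeans(cp10k[out_idx, , drop = FALSE])
    log2fc <- log2((mean_in + 1) / (mean_out + 1))
    gate <- pmax(pct_in, pct_out) >= min_pct & abs(log2fc) >= logfc_thr
    if (only_pos) gate <- gate & log2fc > 0
    genes <- which(gate)
    if (!length(genes)) return(NULL)
    p <- vapply(genes, function(g) {
      v <- expr[, g]
      wilcox_rank_p(as.numeric(v[in_idx]), as.numeric(v[out_idx]))
    }, 1)
    data.frame(gene = colnames(expr)[genes], cluster = k,
               log2fc = as.numeric(log2fc[genes]),
               pct_in = as.numeric(pct_in[genes]),
               pct_out = as.numeric(pct_out[genes]),
               p = p, p_adj = pmin(1, p * length(genes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  if (is.null(out)) out <- data.frame(gene = character(), cluster = character(),
                                      log2fc = numeric(), pct_in = numeric(),
                                      pct_out = numeric(), p = numeric(),
                                      p_adj = numeric())
  rownames(out) <- NULL
  out[order(out$cluster, out$p, -out$log2fc), ]
}

# 0/1 indicator submatrix of rows `idx`.
detection_counts <- function(m, idx) {
  s <- m[idx, , drop = FALSE]
  s@x <- rep(1, length(s@x))
  s
}

#' Intersect marker tables across datasets
#'
#' Per cluster, the genes called in every table (e.g. one per timepoint),
#' ordered by worst (largest) p across tables. A cluster absent from any
#' table yields an empty intersection with a warning.
#'
#' @param tables list of marker data.frames from [rank_markers_wilcoxon()].
#' @return data.frame: cluster, gene, worst_p.
#' @export
intersect_markers <- function(tables) {
  stopifnot(length(tables) >= 2)
  cl <- sort(unique(unlist(lapply(tables, function(t) t$cluster))))
  out <- lapply(cl, function(k) {
    per <- lapply(tables, function(t) t[t$cluster == k, ])
    if (any(vapply(per, nrow, 1L) == 0)) {
      warning("cluster ", k, " absent from at least one table; empty intersection")
      return(NULL)
    }
    genes <- Reduce(intersect, lapply(per, function(t) t$gene))
    if (!length(genes)) return(NULL)
    worst <- vapply(genes, function(g)
      max(vapply(per, function(t) t$p[t$gene == g][1], 1)), 1)
    data.frame(cluster = k, gene = genes, worst_p = unname(worst),
               stringsAsFactors = FALSE)[order(worst), ]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(cluster = character(), gene = character(),
                                      worst_p = numeric())
  rownames(out) <- NULL
  out
}

#' Three-class specificity screen
#'
#' "Expressed in cluster j" means detection fraction >= `tau` in j; clusters
#' in `exclude_clusters` (e.g. tiny cone / primary pigment clusters) are not
#' evaluated. Class 1: expressed only in the home cluster; Class 2: home plus
#' exactly one other; Class 3: home plus two or more others but not all;
#' expressed in every evaluated cluster: `"ubiquitous"`; not expressed in
#' the home cluster: `"not_expressed"` (an anomaly worth inspecting).
#'
#' @param expr normalized cells x genes matrix.
#' @param labels per-cell cluster labels.
#' @param candidates data.frame with columns gene and cluster (e.g. from
#'   [rank_markers_wilcoxon()]).
#' @param tau detection threshold (default 0.10).
#' @param exclude_clusters cluster labels ignored in the screen.
#' @return `candidates` with an added `class` column.
#' @export
classify_specificity <- function(expr, labels, candidates, tau = 0.10,
                                 exclude_clusters = character()) {
  labels <- as.character(labels)
  if (any(candidates$cluster %in% exclude_clusters))
    stop("home cluster of a candidate is in exclude_clusters")
  det <- detection_by_cluster(expr, labels)
  eval_cl <- setdiff(rownames(det), exclude_clusters)
  det <- det[eval_cl, , drop = FALSE]
  cls <- vapply(seq_len(nrow(candidates)), function(r) {
    g <- candidates$gene[r]; home <- as.character(candidates$cluster[r])
    expressed <- rownames(det)[det[, g] >= tau]
    if (!(home %in% expressed)) return("not_expressed")
    n_other <- length(setdiff(expressed, home))
    if (length(expressed) == nrow(det) && n_other > 0) return("ubiquitous")
    if (n_other == 0) "1" else if (n_other == 1) "2" else "3"
  }, "")
  candidates$class <- cls
  candidates
}

#' Genes expressed in exactly one pair of clusters
#'
#' Genes detected at >= `tau` in both members of `pair` and below `tau` in
#' every other evaluated cluster -- e.g. the shared R7/R8 markers.
#'
#' @param expr normalized cells x genes matrix.
#' @param labels per-cell cluster labels.
#' @param pair length-2 vector of cluster labels (both must be present).
#' @param tau detection threshold.
#' @param exclude_clusters cluster labels ignored in the screen.
#' @return character vector of gene ids.
#' @export
find_shared_pair_markers <- function(expr, labels, pair, tau = 0.10,
                                     exclude_clusters = character()) {
  labels <- as.character(labels)
  det <- detection_by_cluster(expr, labels)
  missing <- setdiff(pair, rownames(det))
  if (length(missing)) stop("pair cluster(s) missing: ", paste(missing, collapse = ", "))
  if (tau <= 0)
    warning("tau = 0 returns every gene with any count in both pair members")
  others <- setdiff(rownames(det), c(pair, exclude_clusters))
  in_pair <- det[pair[1], ] >= tau & det[pair[2], ] >= tau
  out_ok <- if (length(others)) {
    apply(det[others, , drop = FALSE] < tau, 2, all)
  } else rep(TRUE, ncol(det))
  colnames(det)[in_pair & out_ok]
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test of each set's overlap with a marker list,
#' Benjamini-Hochberg q across sets, and fold enrichment
#' (observed / expected overlap).
#'
#' @param marker_list character vector of genes (subset of `universe`).
#' @param gene_sets named list of gene sets.
#' @param universe background gene ids (non-empty).
#' @return data.frame: set, set_size, overlap, expected, fold_enrichment, p, q.
#' @export
hypergeom_enrichment <- function(marker_list, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  marker_list <- intersect(marker_list, universe)
  out <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    ov <- length(intersect(set, marker_list))
    expected <- length(set) * length(marker_list) / length(universe)
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(marker_list), lower.tail = FALSE)
    data.frame(set = s, set_size = length(set), overlap = ov,
               expected = expected,
               fold_enrichment = if (expected > 0) ov / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[order(out$p), ]
}
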