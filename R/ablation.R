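#' Remove gene columns from a count matrix
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @param genes gene ids to delete; absent ids warn.
#' @return the matrix without those columns; barcodes unchanged.
#' @export
remove_genes <- function(x, genes) {
  m <- as_counts(x)
  missing <- setdiff(genes, colnames(m))
  if (length(missing))
    warning("gene(s) not present: ", paste(missing, collapse = ", "))
  keep <- setdiff(colnames(m), genes)
  out <- m[, keep, drop = FALSE]
  if (inherits(x, "count_matrix"))
    count_matrix(out, rownames(m), x$genes[x$genes$id %in% keep, , drop = FALSE])
  else out
}

#' Transfer reference labels onto an ablated dataset
#'
#' The ablated data contain the same cells, so reference annotations are
#' carried over by barcode -- never re-inferred. Any barcode mismatch is an
#' error listing the difference.
#'
#' @param reference_labels vector of labels named by barcode.
#' @param barcodes barcodes of the ablated dataset (same set, any order).
#' @return labels aligned to `barcodes`.
#' @export
transfer_reference_labels <- function(reference_labels, barcodes) {
  ref_bc <- names(reference_labels)
  stopifnot(!is.null(ref_bc))
  extra <- setdiff(barcodes, ref_bc)
  lost <- setdiff(ref_bc, barcodes)
  if (length(extra) || length(lost))
    stop("barcode mismatch; missing from reference: ",
         paste(utils::head(extra, 5), collapse = ", "),
         "; missing from query: ", paste(utils::head(lost, 5), collapse = ", "))
  reference_labels[barcodes]
}

#' kNN mixing index for a pair of cell classes
#'
#' Restricted to cells of classes A and B, each cell's same-label fraction
#' among its k nearest neighbors in PC space is averaged (`S_obs`) and
#' normalized against the chance level `S_null = p_A^2 + p_B^2`:
#' `M = (S_obs - S_null) / (1 - S_null)`. M is ~1 for fully separated
#' classes and ~0 for fully mixed ones.
#'
#' @param scores cells x dims PC score matrix.
#' @param labels per-cell class labels.
#' @param pair length-2 vector of class labels; both members need more than
#'   `k` cells.
#' @param k neighborhood size (default 20).
#' @return the mixing index M.
#' @export
mixing_index <- function(scores, labels, pair, k = 20) {
  labels <- as.character(labels)
  stopifnot(nrow(scores) == length(labels), length(pair) == 2)
  idx <- which(labels %in% pair)
  lab <- labels[idx]
  if (length(unique(lab)) < 2) stop("mixing index needs both classes present")
  sizes <- table(lab)
  if (any(sizes < k + 1))
    stop("pair member(s) with <= k cells: ",
         paste(names(sizes)[sizes < k + 1], collapse = ", "))
  sub <- scores[idx, , drop = FALSE]
  nn <- RANN::nn2(sub, k = k + 1)$nn.idx[, -1, drop = FALSE]  # drop self
  same <- matrix(lab[nn], nrow = nrow(nn)) == lab
  s_obs <- mean(rowMeans(same))
  p <- as.numeric(sizes) / length(lab)
  s_null <- sum(p^2)
  (s_obs - s_null) / (1 - s_null)
}

#' ARI between reference and de-novo labels, optionally restricted
#'
#' @param reference per-cell reference labels.
#' @param denovo per-cell de-novo labels (same cells).
#' @param restrict_to optional set of reference labels; the comparison is
#'   restricted to cells whose reference label is in this set.
#' @return adjusted Rand index.
#' @export
cluster_ari <- function(reference, denovo, restrict_to = NULL) {
  stopifnot(length(reference) == length(denovo))
  keep <- if (is.null(restrict_to)) seq_along(reference)
          else which(as.character(reference) %in% restrict_to)
  if (length(keep) < 2) stop("fewer than 2 cells after restriction")
  adjusted_rand_index(reference[keep], denovo[keep])
}

#' Rhodopsin-ablation clustering-contribution experiment
#'
#' For each gene set: delete the genes, re-run
#' normalize -> HVG -> PCA -> SNN -> communities with the reference
#' parameters and seed, transfer the reference per-cell annotations, and
#' quantify (i) subtype mixing in the ablated PC space for the pairs
#' (R7-pale, R7-yellow), (R8-pale, R8-yellow), (R7, R8), (inner
#' photoreceptors, R1-6) via [mixing_index()], and (ii) the stability of
#' pigment/cone clusters via [cluster_ari()] between reference and ablated
#' de-novo communities restricted to those cells. Baseline (no removal)
#' values are included for comparison.
#'
#' @param x a [count_matrix()] (typically ambient-corrected counts).
#' @param reference_labels per-cell type labels named by barcode (e.g.
#'   ground-truth or annotated types such as "R7-pale"; coarse types are
#'   derived by stripping the subtype suffix).
#' @param reference_communities per-cell de-novo community labels of the
#'   unablated run, named by barcode.
#' @param gene_sets named list of gene-id sets to remove; the default is the
#'   Rhodopsin series {Rh3,Rh4}, {Rh5,Rh6}, {Rh3..Rh6}, {ninaE},
#'   {ninaE,Rh3..Rh6}.
#' @param config a [pipeline_config()] (n_hvg, n_dims, neighbors_k,
#'   resolution, snn_prune).
#' @param seed master seed (stages derive their own).
#' @param mix_k neighborhood size for the mixing index.
#' @return data.frame: one row per (gene set x metric): set, metric, value,
#'   baseline.
#' @export
run_ablation_experiment <- function(x, reference_labels, reference_communities,
                                    gene_sets = list(
                                      Rh34 = c("Rh3", "Rh4"),
                                      Rh56 = c("Rh5", "Rh6"),
                                      Rh3456 = c("Rh3", "Rh4", "Rh5", "Rh6"),
                                      ninaE = "ninaE",
                                      ninaE_Rh3456 = c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6")),
                                    config = pipeline_config(), seed = 1L,
                                    mix_k = 20) {
  m <- as_counts(x)
  labels <- transfer_reference_labels(reference_labels, rownames(m))
  coarse <- subtype_to_type_label(labels)
  run_reduced <- function(counts) {
    expr <- normalize_log_cp10k(counts)
    hvgs <- suppressWarnings(select_hvgs(counts, config$n_hvg))
    pca <- suppressWarnings(compute_pca(expr, hvgs, config$n_dims))
    graph <- build_snn_graph(pca$scores, k = config$neighbors_k,
                             prune = config$snn_prune)
    comm <- detect_communities(graph, config$resolution, seed)
    list(pca = pca, comm = comm)
  }
  metrics_of <- function(scores) {
    inner <- ifelse(coarse %in% c("R7", "R8"), "innerPR", coarse)
    safe_mix <- function(lbl, pair) tryCatch(
      mixing_index(scores, lbl, pair, k = mix_k), error = function(e) NA_real_)
    c(M_R7pale_R7yellow = safe_mix(labels, c("R7-pale", "R7-yellow")),
      M_R8pale_R8yellow = safe_mix(labels, c("R8-pale", "R8-yellow")),
      M_R7_R8 = safe_mix(coarse, c("R7", "R8")),
      M_innerPR_R16 = safe_mix(inner, c("innerPR", "R1-6")),
      M_R16_rest = safe_mix(ifelse(coarse == "R1-6", "R1-6", "rest"),
                            c("R1-6", "rest")),
      ARI_pigment_cone = NA_real_)
  }
  pigment_cone <- which(coarse %in% c("pigment1", "pigment23", "cone"))
  ari_pc <- function(comm) {
    if (length(pigment_cone) < 2) return(NA_real_)
    adjusted_rand_index(reference_communities[rownames(m)][pigment_cone],
                        comm[pigment_cone])
  }
  base <- run_reduced(m)
  base_metrics <- metrics_of(base$pca$scores)
  base_metrics["ARI_pigment_cone"] <- ari_pc(base$comm)
  out <- lapply(names(gene_sets), function(gs) {
    reduced <- remove_genes(m, gene_sets[[gs]])
    res <- run_reduced(reduced)
    v <- metrics_of(res$pca$scores)
    v["ARI_pigment_cone"] <- ari_pc(res$comm)
    data.frame(set = gs, metric = names(v), value = as.numeric(v),
               baseline = as.numeric(base_metrics[names(v)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# "R7-pale" -> "R7", "R8-DRA" -> "R8"; labels without a dash pass through.
subtype_to_type_label <- function(labels) {
  out <- as.character(labels)
  out[startsWith(out, "R7-")] <- "R7"
  out[startsWith(out, "R8-")] <- "R8"
  out
}
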