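#' Per-cell QC metrics
#'
#' Total molecules, detected genes, and mitochondrial fraction per barcode.
#' An all-zero cell has mito_fraction defined as 0.
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @param mito_genes gene ids counted as mitochondrial; ids absent from the
#'   matrix produce a warning and are ignored; an empty set warns and yields
#'   mito_fraction 0.
#' @return data.frame: barcode, total_counts, n_genes, mito_fraction.
#' @export
compute_qc_metrics <- function(x, mito_genes = grep("^mt:", colnames(as_counts(x)), value = TRUE)) {
  m <- as_counts(x)
  total <- Matrix::rowSums(m)
  nz <- m
  nz@x <- rep(1, length(nz@x))
  n_genes <- Matrix::rowSums(nz)
  missing <- setdiff(mito_genes, colnames(m))
  if (length(missing))
    warning("mito genes absent from matrix: ", paste(missing, collapse = ", "))
  mito_genes <- intersect(mito_genes, colnames(m))
  if (!length(mito_genes)) {
    warning("empty mitochondrial gene set; mito_fraction set to 0")
    mito <- rep(0, nrow(m))
  } else {
    mito <- Matrix::rowSums(m[, mito_genes, drop = FALSE])
  }
  frac <- ifelse(total > 0, mito / total, 0)
  bc <- rownames(m)
  if (is.null(bc)) bc <- sprintf("CELL-%06d", seq_len(nrow(m)))
  data.frame(barcode = bc, total_counts = as.numeric(total),
             n_genes = as.numeric(n_genes), mito_fraction = as.numeric(frac),
             stringsAsFactors = FALSE)
}

#' Threshold cell filter
#'
#' Keeps a cell iff `gene_min <= n_genes <= gene_max` (inclusive, "between")
#' and `mito_fraction < mito_max` (strict). An empty result is allowed with a
#' warning.
#'
#' @param metrics data.frame from [compute_qc_metrics()].
#' @param mito_max strict upper bound on mitochondrial fraction.
#' @param gene_min,gene_max inclusive bounds on detected genes.
#' @return character vector of kept barcodes.
#' @export
filter_cells <- function(metrics, mito_max = 0.20, gene_min = 200, gene_max = 3500) {
  stopifnot(gene_min < gene_max, mito_max > 0, mito_max <= 1)
  keep <- metrics$n_genes >= gene_min & metrics$n_genes <= gene_max &
    metrics$mito_fraction < mito_max
  if (!any(keep)) warning("no cells pass the QC thresholds")
  metrics$barcode[keep]
}

#' Remove clusters of non-eye cells
#'
#' Drops every preliminary cluster in which the detection fraction of any
#' non-eye marker (brain neurons: fne; glia: moody, repo) reaches
#' `frac_threshold`, and returns the surviving barcodes.
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @param cluster_labels per-cell cluster labels (length = cells).
#' @param noneye_markers gene ids marking non-eye cells; markers absent from
#'   the gene list warn and are skipped.
#' @param frac_threshold detection-fraction threshold (default 0.5).
#' @return character vector of kept barcodes.
#' @export
drop_noneye_clusters <- function(x, cluster_labels,
                                 noneye_markers = c("fne", "moody", "repo"),
                                 frac_threshold = 0.5) {
  m <- as_counts(x)
  stopifnot(length(cluster_labels) == nrow(m))
  missing <- setdiff(noneye_markers, colnames(m))
  if (length(missing))
    warning("non-eye marker(s) absent, skipped: ", paste(missing, collapse = ", "))
  noneye_markers <- intersect(noneye_markers, colnames(m))
  bc <- rownames(m)
  if (is.null(bc)) bc <- sprintf("CELL-%06d", seq_len(nrow(m)))
  if (!length(noneye_markers)) return(bc)
  det <- detection_by_cluster(m[, noneye_markers, drop = FALSE], cluster_labels)
  bad <- rownames(det)[apply(det >= frac_threshold, 1, any)]
  bc[!(as.character(cluster_labels) %in% bad)]
}
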