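#' Run the clustering workflow on a count matrix
#'
#' Normalization (log CP10K, or Pearson residuals if configured), HVG
#' selection, PCA, SNN graph, community detection, optional 2-D embedding,
#' and marker-panel annotation. The embedding is reporting-only; no table
#' output depends on it.
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @param config a [pipeline_config()].
#' @param seed master seed (default `config$seed`).
#' @param panels marker panels as in [annotate_clusters()].
#' @param embed compute the 2-D embedding (default TRUE).
#' @return a `clustering_result` list: `expr`, `hvgs`, `pca`, `graph`,
#'   `labels` (per-cell community), `embedding` (or NULL), `annotation`
#'   (cluster table), `cell_types` (per-cell annotated label).
#' @export
run_clustering <- function(x, config = pipeline_config(), seed = config$seed,
                           panels = default_marker_panels(config$marker_panels)$panels,
                           embed = TRUE) {
  m <- as_counts(x)
  expr <- if (config$pearson_residuals)
    normalize_pearson_residuals(m) else normalize_log_cp10k(m)
  hvgs <- suppressWarnings(select_hvgs(m, config$n_hvg))
  pca <- suppressWarnings(compute_pca(expr, hvgs, config$n_dims))
  graph <- build_snn_graph(pca$scores, k = config$neighbors_k,
                           prune = config$snn_prune)
  labels <- detect_communities(graph, config$resolution, seed)
  embedding <- if (embed) embed_2d(pca$scores, seed) else NULL
  annotation <- suppressWarnings(annotate_clusters(expr, labels, panels))
  cell_types <- stats::setNames(
    annotation$label[match(labels, annotation$cluster)], names(labels))
  structure(list(expr = expr, hvgs = hvgs, pca = pca, graph = graph,
                 labels = labels, embedding = embedding,
                 annotation = annotation, cell_types = cell_types),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("clustering_result:", length(x$labels), "cells,",
      length(unique(x$labels)), "communities\n")
  print(x$annotation[, c("cluster", "label", "score")])
  invisible(x)
}

#' Run the full retina pipeline
#'
#' Orchestrates simulate -> QC -> ambient correction -> clustering ->
#' markers -> ablation -> comparisons and writes stage artifacts plus a
#' JSON report under `outdir`. Stages: `"simulate"`, `"qc"`, `"ambient"`,
#' `"cluster"`, `"markers"`, `"ablate"`, `"compare"`, or `"all"`.
#' Later stages reuse in-memory results of earlier ones; requesting a later
#' stage without its prerequisite is an error naming the missing stage.
#'
#' @param config a [pipeline_config()], or path to a JSON config.
#' @param sim a [sim_config()] for the synthetic dataset (or a dataset list
#'   from [generate_retina_dataset()]).
#' @param outdir output directory for artifacts (default: no files written).
#' @param stages character vector of stages (default "all").
#' @param seed master seed (default `config$seed`); per-stage seeds derive
#'   from it.
#' @return named list of stage results (invisibly includes the report).
#' @export
run_pipeline <- function(config = pipeline_config(), sim = sim_config(),
                         outdir = NULL, stages = "all", seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  validate_pipeline_config(config)
  if (is.null(seed)) seed <- config$seed
  all_stages <- c("simulate", "qc", "ambient", "cluster", "markers", "ablate", "compare")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  need <- function(stage, value) {
    if (is.null(value)) stop("stage requires output of the '", stage,
                             "' stage; run it first")
    value
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(params = list(config = unclass(config), seed = seed))

  dataset <- NULL
  if ("simulate" %in% stages) {
    dataset <- if (is.list(sim) && !inherits(sim, "sim_config")) sim
               else generate_retina_dataset(sim, derive_seed(seed, "simulate"))
    res$simulate <- list(n_cells = nrow(dataset$counts$counts),
                         n_genes = ncol(dataset$counts$counts))
    if (!is.null(outdir))
      write_retina_dataset(dataset, if (inherits(sim, "sim_config")) sim else sim_config(),
                           file.path(outdir, "simulated"))
  }

  kept <- NULL; counts_qc <- NULL
  if ("qc" %in% stages) {
    d <- need("simulate", dataset)
    metrics <- compute_qc_metrics(d$counts)
    kept <- filter_cells(metrics, config$mito_max, config$gene_min, config$gene_max)
    m1 <- as_counts(d$counts)[kept, , drop = FALSE]
    prelim <- run_clustering(m1, config, derive_seed(seed, "qc"), embed = FALSE)
    kept <- drop_noneye_clusters(m1, prelim$labels,
                                 frac_threshold = config$noneye_frac_threshold)
    counts_qc <- as_counts(d$counts)[kept, , drop = FALSE]
    res$qc <- list(metrics = metrics, n_kept = length(kept))
    if (!is.null(outdir))
      utils::write.table(metrics, file.path(outdir, "qc_metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  corrected <- NULL
  if ("ambient" %in% stages) {
    m <- need("qc", counts_qc)
    prelim <- run_clustering(m, config, derive_seed(seed, "ambient"), embed = FALSE)
    soup <- estimate_soup_profile(m)
    forb_map <- default_marker_panels(config$marker_panels)$forbidden
    forbidden <- lapply(stats::setNames(prelim$annotation$cluster,
                                        prelim$annotation$cluster), function(k) {
      ty <- prelim$annotation$type[prelim$annotation$cluster == k]
      forb_map[[ty]]
    })
    est <- estimate_contamination(m, prelim$labels, forbidden, soup)
    corrected <- correct_ambient(m, soup, est, prelim$labels,
                                 derive_seed(seed, "ambient_round"))
    res$ambient <- list(contamination = est)
  }

  clust <- NULL
  if ("cluster" %in% stages) {
    m <- need("ambient", corrected)
    clust <- run_clustering(m, config, derive_seed(seed, "cluster"))
    res$cluster <- list(annotation = clust$annotation,
                        sizes = as.list(table(clust$cell_types)),
                        communities = clust$labels,
                        cell_types = clust$cell_types)
    if (!is.null(outdir)) {
      utils::write.table(
        data.frame(barcode = names(clust$labels), cluster = clust$labels,
                   cell_type = clust$cell_types),
        file.path(outdir, "clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(barcode = rownames(clust$embedding), clust$embedding),
        file.path(outdir, "embedding.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("markers" %in% stages) {
    cl <- need("cluster", clust)
    mk <- rank_markers_wilcoxon(cl$expr, cl$cell_types)
    mk <- classify_specificity(cl$expr, cl$cell_types, mk, tau = config$tau)
    res$markers <- mk
    if (!is.null(outdir))
      utils::write.table(mk, file.path(outdir, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("ablate" %in% stages) {
    cl <- need("cluster", clust)
    m <- need("ambient", corrected)
    abl <- run_ablation_experiment(m, cl$cell_types, cl$labels,
                                   config = config, seed = derive_seed(seed, "ablate"))
    res$ablation <- abl
    if (!is.null(outdir))
      utils::write.table(abl, file.path(outdir, "ablation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("compare" %in% stages) {
    cl <- need("cluster", clust)
    d <- need("simulate", dataset)
    tp <- d$annotation$timepoint[match(names(cl$labels), d$annotation$barcode)]
    metrics_kept <- compute_qc_metrics(as_counts(d$counts)[names(cl$labels), , drop = FALSE])
    res$compare <- list(
      timepoint_mixing = timepoint_mixing(cl$labels, tp),
      aging = aging_trend(metrics_kept, tp,
                          order = names(sim_config()$depth_decline)))
    pale <- sum(cl$cell_types == "R8-pale")
    yellow <- sum(cl$cell_types == "R8-yellow")
    if (pale + yellow > 0)
      res$compare$r8_ratio <- ratio_test_binomial(pale, yellow)
  }

  if (!is.null(outdir)) write_report(res, file.path(outdir, "report.json"))
  invisible(res)
}
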