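#' Pipeline configuration
#'
#' Assemble and validate the analysis parameters consumed by the pipeline
#' stages. Defaults follow the conventions of the droplet scRNA-seq workflow
#' this package implements: cells kept with 200--3500 detected genes and a
#' mitochondrial fraction below 20%, 50 principal components for the
#' neighbor graph and embedding, 20 shared-nearest-neighbor neighbors,
#' community-detection resolution 0.8.
#'
#' @param mito_max keep cells with mitochondrial fraction strictly below this
#'   (in (0, 1]).
#' @param gene_min,gene_max inclusive bounds on detected genes per cell.
#' @param n_hvg number of highly variable genes.
#' @param n_dims number of principal components (>= 2).
#' @param neighbors_k kNN neighborhood size for the SNN graph.
#' @param resolution community-detection resolution.
#' @param snn_prune drop SNN edges with Jaccard weight at or below this.
#' @param noneye_frac_threshold cluster detection-fraction threshold for
#'   non-eye marker removal.
#' @param tau detection-fraction threshold operationalizing "expressed in" for
#'   the specificity classifier.
#' @param marker_panels optional path to a marker-panel JSON file.
#' @param seed master seed.
#' @param pearson_residuals use Pearson-residual normalization (fixed
#'   overdispersion 0.1) instead of log CP10K.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(mito_max = 0.20, gene_min = 200, gene_max = 3500,
                            n_hvg = 2000, n_dims = 50, neighbors_k = 20,
                            resolution = 0.8, snn_prune = 1 / 15,
                            noneye_frac_threshold = 0.5, tau = 0.10,
                            marker_panels = NULL, seed = 1L,
                            pearson_residuals = FALSE) {
  cfg <- list(mito_max = mito_max, gene_min = gene_min, gene_max = gene_max,
              n_hvg = n_hvg, n_dims = n_dims, neighbors_k = neighbors_k,
              resolution = resolution, snn_prune = snn_prune,
              noneye_frac_threshold = noneye_frac_threshold, tau = tau,
              marker_panels = marker_panels, seed = seed,
              pearson_residuals = isTRUE(pearson_residuals))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!(cfg$gene_min < cfg$gene_max))
    stop("gene_min (", cfg$gene_min, ") must be < gene_max (", cfg$gene_max, ")")
  if (!(cfg$mito_max > 0 && cfg$mito_max <= 1))
    stop("mito_max (", cfg$mito_max, ") must be in (0, 1]")
  if (cfg$n_dims < 2) stop("n_dims (", cfg$n_dims, ") must be >= 2")
  if (cfg$n_hvg < 1) stop("n_hvg must be positive")
  if (cfg$neighbors_k < 2) stop("neighbors_k must be >= 2")
  if (cfg$resolution <= 0) stop("resolution must be positive")
  invisible(TRUE)
}

#' Load a pipeline configuration from JSON
#'
#' Missing keys take their defaults; unknown keys produce a warning (not an
#' error) and are dropped; invariant violations are reported with field names.
#' An empty file yields the all-defaults configuration.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals[intersect(names(vals), known)])
}

#' Default marker panels for adult-eye cell-type annotation
#'
#' The in-field panels: R8 by Rh5/Rh6/sens, R7 by Rh3/Rh4/pros, R1-6 by
#' ninaE, cone cells by ct/Crys, primary pigment by wrapper/Pdh, secondary
#' and tertiary pigment by santa-maria/w/Pdh, non-eye by fne/moody/repo.
#' `forbidden` lists per-type genes that the type must *not* express; the
#' ambient-correction stage uses them to estimate contamination.
#'
#' @param path optional JSON file `{panels: {...}, forbidden: {...}}`
#'   overriding the built-in panels.
#' @return list with elements `panels` and `forbidden` (type -> gene symbols).
#' @export
default_marker_panels <- function(path = NULL) {
  if (!is.null(path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    stopifnot(is.list(x$panels))
    if (is.null(x$forbidden)) x$forbidden <- list()
    return(x[c("panels", "forbidden")])
  }
  list(
    panels = list(
      `R1-6`     = c("ninaE"),
      R7         = c("Rh3", "Rh4", "pros"),
      R8         = c("Rh5", "Rh6", "sens"),
      cone       = c("ct", "Crys"),
      pigment1   = c("wrapper", "Pdh"),
      pigment23  = c("santa-maria", "w", "Pdh"),
      noneye     = c("fne", "moody", "repo")
    ),
    forbidden = list(
      `R1-6`     = c("Rh3", "Rh4", "Rh5", "Rh6"),
      R7         = c("Rh5", "Rh6", "ninaE"),
      R8         = c("Rh3", "Rh4", "ninaE"),
      cone       = c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6"),
      pigment1   = c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6"),
      pigment23  = c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6"),
      noneye     = c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6")
    )
  )
}
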