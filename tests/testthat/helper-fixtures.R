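# Shared fixtures, built once per test run and cached across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# The study-conditions dataset: generator defaults, 5000 cells.
acc_dataset <- function() fixture("dataset", function() {
  generate_retina_dataset(sim_config(n_cells = 5000), seed = 101)
})

acc_config <- function() pipeline_config(n_hvg = 500, seed = 11)

# Full QC -> ambient -> cluster -> markers pipeline on the default dataset.
acc_pipeline <- function() fixture("pipeline", function() {
  suppressWarnings(run_pipeline(acc_config(), sim = acc_dataset(),
                                stages = c("simulate", "qc", "ambient",
                                           "cluster", "markers")))
})

# Rhodopsin/ninaE ablation report on the default dataset (ground-truth
# subtype labels as the reference annotation, as the experiment transfers
# reference labels rather than re-inferring them).
acc_ablation <- function() fixture("ablation", function() {
  d <- acc_dataset()
  truth <- d$truth$cells
  ref <- stats::setNames(truth$subtype, truth$barcode)
  pipe <- acc_pipeline()
  comm <- pipe$cluster$communities
  # restrict to QC-passing cells so reference and matrix share barcodes
  m <- as_counts_public(d$counts)[names(comm), , drop = FALSE]
  suppressWarnings(run_ablation_experiment(m, ref[names(comm)], comm,
                                           config = acc_config(), seed = 21))
})

# Normalized expression + truth labels of the default dataset (no QC).
acc_expr <- function() fixture("expr", function() {
  d <- acc_dataset()
  list(expr = normalize_log_cp10k(d$counts$counts),
       truth = d$truth$cells, genes = d$truth$genes)
})

as_counts_public <- function(x) if (inherits(x, "count_matrix")) x$counts else x

# Tiny deterministic count_matrix for I/O and arithmetic tests.
toy_counts <- function() {
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 1),
                            dims = c(3, 2))
  count_matrix(m, barcodes = c("A", "B", "C"),
               genes = data.frame(id = c("g1", "g2"), symbol = c("G1", "G2")))
}

# Exact binomial 99% CI bounds for a proportion, by direct quantiles.
binom_ci99 <- function(n, p) c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p)) / n
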