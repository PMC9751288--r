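#' Construct a cells-by-genes count matrix
#'
#' The container every pipeline stage consumes and produces: a sparse
#' non-negative integer matrix oriented cells x genes, with unique cell
#' barcodes as row names, unique gene ids as column names, and a gene table
#' carrying (id, symbol) pairs as in 10x `features.tsv`.
#'
#' @param counts matrix or sparse Matrix, cells x genes, non-negative integers.
#' @param barcodes character vector of unique cell barcodes (default: rownames).
#' @param genes data.frame with columns `id` and `symbol` (default: colnames
#'   used for both).
#' @return an object of class `count_matrix` with elements `counts` (a
#'   `dgCMatrix`) and `genes`.
#' @export
count_matrix <- function(counts, barcodes = rownames(counts), genes = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (is.null(genes)) {
    ids <- colnames(counts)
    if (is.null(ids)) ids <- sprintf("G%05d", seq_len(ncol(counts)))
    genes <- data.frame(id = ids, symbol = ids, stringsAsFactors = FALSE)
  }
  if (is.null(barcodes)) barcodes <- sprintf("CELL-%06d", seq_len(nrow(counts)))
  validate_count_matrix_parts(counts, barcodes, genes)
  dimnames(counts) <- list(barcodes, genes$id)
  structure(list(counts = counts, genes = genes), class = "count_matrix")
}

validate_count_matrix_parts <- function(counts, barcodes, genes) {
  if (length(barcodes) != nrow(counts))
    stop("barcode count (", length(barcodes), ") does not match rows (", nrow(counts), ")")
  if (nrow(genes) != ncol(counts))
    stop("gene count (", nrow(genes), ") does not match columns (", ncol(counts), ")")
  dup <- barcodes[duplicated(barcodes)]
  if (length(dup)) stop("duplicate barcodes: ", paste(unique(dup), collapse = ", "))
  dup <- genes$id[duplicated(genes$id)]
  if (length(dup)) stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  if (length(counts@x) && any(counts@x < 0)) stop("negative counts are not allowed")
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      length(x$counts@x), "non-zero entries\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Accept either a count_matrix or a bare (sparse) matrix; return dgCMatrix.
as_counts <- function(x) {
  if (inherits(x, "count_matrix")) return(x$counts)
  methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
}

#' Write a count matrix as a 10x-style MatrixMarket directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate **integer**, 1-based,
#' genes x cells as in Cell Ranger output), `features.tsv` (id, symbol,
#' "Gene Expression") and `barcodes.tsv`.
#'
#' @param x a [count_matrix()] (or cells x genes matrix).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  m <- as_counts(x)
  if (length(m@x) && any(m@x != round(m@x)))
    stop("refusing to write non-integer counts as MatrixMarket integer")
  genes <- if (inherits(x, "count_matrix")) x$genes else
    data.frame(id = colnames(m), symbol = colnames(m))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tm <- Matrix::t(m)  # genes x cells on disk, the 10x convention
  trip <- Matrix::summary(tm)
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), nrow(trip))), con)
  if (nrow(trip))
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  close(con)
  utils::write.table(cbind(genes$id, genes$symbol, "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bc <- rownames(m)
  if (is.null(bc)) bc <- sprintf("CELL-%06d", seq_len(nrow(m)))
  writeLines(bc, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-style MatrixMarket directory
#'
#' Accepts both the genes x cells layout written by Cell Ranger and a
#' cells x genes layout; the orientation is resolved against the lengths of
#' `features.tsv` and `barcodes.tsv`, and the result is always cells x genes.
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return a [count_matrix()].
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))
  m <- methods::as(methods::as(Matrix::readMM(paths[1]), "CsparseMatrix"), "generalMatrix")
  feats <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "", comment.char = "")
  genes <- data.frame(id = feats[[1]],
                      symbol = if (ncol(feats) >= 2) feats[[2]] else feats[[1]],
                      stringsAsFactors = FALSE)
  barcodes <- readLines(paths[3])
  if (nrow(m) == nrow(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)               # genes x cells dialect -> transpose
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == nrow(genes))) {
    stop("matrix dimensions ", nrow(m), "x", ncol(m),
         " match neither features (", nrow(genes), ") x barcodes (",
         length(barcodes), ") nor its transpose")
  }
  if (length(m@x) && any(m@x < 0)) stop("negative values in matrix.mtx")
  count_matrix(m, barcodes = barcodes, genes = genes)
}

#' Write a pipeline report as JSON
#'
#' Schema-stable JSON serialization of pipeline stage results (QC summaries,
#' cluster tables, marker tables, ablation reports, ratio tests). Data frames
#' become arrays of records; scalars are unboxed.
#'
#' @param results named list of stage results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(is.list(results))
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report
#' @param path file written by [write_report()].
#' @return the parsed list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
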