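#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and the stage name, so re-running one stage never perturbs another.
#' The hash is a small deterministic polynomial over the stage-name bytes,
#' folded into the 31-bit positive integer range.
#'
#' @param seed master seed (single integer).
#' @param stage character stage name.
#' @return a single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells, by the
#' standard pair-counting formula on the contingency table.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions (up to label names).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Rank-sum test used for marker calling. For small groups (both sizes at
#' most `exact_max`) the null distribution of the rank sum is enumerated
#' exactly over all assignments of the observed (possibly tied) ranks, so the
#' p-value is exact under ties. Larger groups use the normal approximation
#' with the usual tie correction and continuity correction.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max enumerate exactly when both groups are at most this size.
#' @return two-sided p-value.
#' @export
wilcox_rank_p <- function(x, y, exact_max = 10L) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1L, ny >= 1L)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    combs <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    mu <- nx * (nx + ny + 1) / 2
    # two-sided: as extreme or more extreme in |rank sum - mean|
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(p)
  }
  mu <- nx * (nx + ny + 1) / 2
  ties <- table(r)
  n <- nx + ny
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  2 * stats::pnorm(z, lower.tail = FALSE)
}

# Shannon entropy (nats) of a count/probability vector; zero-mass bins dropped.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

# Detection-fraction matrix: clusters x genes, fraction of cells with count>0.
detection_by_cluster <- function(expr, labels) {
  labels <- as.character(labels)
  stopifnot(nrow(expr) == length(labels))
  cl <- sort(unique(labels))
  det <- matrix(0, length(cl), ncol(expr), dimnames = list(cl, colnames(expr)))
  nz <- expr
  nz@x <- rep(1, length(nz@x))
  for (k in cl) {
    idx <- which(labels == k)
    det[k, ] <- Matrix::colSums(nz[idx, , drop = FALSE]) / length(idx)
  }
  det
}

# Cluster-mean matrix: clusters x genes means of `expr` rows.
means_by_cluster <- function(expr, labels) {
  labels <- as.character(labels)
  cl <- sort(unique(labels))
  m <- matrix(0, length(cl), ncol(expr), dimnames = list(cl, colnames(expr)))
  for (k in cl) {
    idx <- which(labels == k)
    m[k, ] <- Matrix::colMeans(expr[idx, , drop = FALSE])
  }
  m
}
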