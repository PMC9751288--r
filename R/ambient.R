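#' Estimate the ambient-RNA ("soup") profile
#'
#' The soup profile is taken as the dataset-wide expression profile,
#' `s_g = colSums(x) / sum(x)`. In the eye this is dominated by ninaE, the
#' most abundant transcript, which contaminates every droplet.
#'
#' @param x a [count_matrix()] or cells x genes matrix (non-empty).
#' @return named numeric vector `s` summing to 1.
#' @export
estimate_soup_profile <- function(x) {
  m <- as_counts(x)
  tot <- sum(m)
  if (tot == 0) stop("cannot estimate a soup profile from an all-zero matrix")
  s <- Matrix::colSums(m) / tot
  stats::setNames(as.numeric(s), colnames(m))
}

#' Estimate per-cluster contamination fractions
#'
#' For each cluster, the contamination fraction rho is estimated from
#' "forbidden" genes -- genes the cluster's cell type cannot itself express
#' (e.g. Rh6 in pale R8s), so that any observed counts must be soup:
#' `rho_k = sum(counts of forbidden genes in k) / (sum(N_c in k) * sum(s_g over forbidden))`,
#' clipped to `[0, 0.5]`. Clusters whose forbidden set has zero soup mass are
#' flagged unusable rather than silently zero.
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @param labels per-cell cluster labels.
#' @param forbidden named list: cluster label -> forbidden gene ids.
#' @param soup optional precomputed soup profile.
#' @return data.frame: cluster, rho, se, n_cells, usable, n_forbidden.
#' @export
estimate_contamination <- function(x, labels, forbidden, soup = estimate_soup_profile(x)) {
  m <- as_counts(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  N <- Matrix::rowSums(m)
  cl <- sort(unique(labels))
  out <- lapply(cl, function(k) {
    idx <- which(labels == k)
    genes <- intersect(forbidden[[k]], colnames(m))
    s_mass <- sum(soup[genes])
    if (!length(genes) || s_mass <= 0) {
      return(data.frame(cluster = k, rho = NA_real_, se = NA_real_,
                        n_cells = length(idx), usable = FALSE,
                        n_forbidden = length(genes)))
    }
    obs <- sum(m[idx, genes, drop = FALSE])
    denom <- sum(N[idx]) * s_mass
    rho <- obs / denom
    if (rho > 0.5) {
      warning("cluster ", k, ": contamination estimate ", signif(rho, 3),
              " clipped at 0.5")
      rho <- 0.5
    }
    se <- sqrt(max(obs, 1)) / denom  # Poisson-scale standard error
    data.frame(cluster = k, rho = rho, se = se, n_cells = length(idx),
               usable = TRUE, n_forbidden = length(genes))
  })
  do.call(rbind, out)
}

#' Subtract expected soup counts
#'
#' The expected soup count for cell c and gene g is
#' `e_cg = rho_{cluster(c)} * N_c * s_g`. With `method = "cluster"` (the
#' default) the per-cluster expected soup total for each gene,
#' `T_kg = round_stochastic(sum_c e_cg)`, is removed from the cluster's
#' actually observed molecules of that gene (a seeded hypergeometric draw
#' across the cluster's cells, capped at availability). This balances the
#' removal over the cells that really carry the contaminating molecules and
#' can clear a forbidden gene essentially completely. `method = "cell"`
#' instead applies the per-entry rule
#' `x'_cg = max(0, x_cg - round_stochastic(e_cg))`, which is strictly local
#' but strands expected-removal mass on zero entries and therefore
#' under-corrects sparse genes. Either way the correction never increases
#' any entry, output stays integer, and corrected library sizes never exceed
#' the originals. Unusable clusters (rho = NA) are left uncorrected.
#'
#' @param x a [count_matrix()] or cells x genes matrix.
#' @param soup soup profile from [estimate_soup_profile()].
#' @param estimate data.frame from [estimate_contamination()].
#' @param labels per-cell cluster labels (same clusters as `estimate`).
#' @param seed seed for the stochastic rounding / allocation.
#' @param method `"cluster"` (balanced removal) or `"cell"` (per-entry).
#' @return corrected counts, same class/orientation as the input.
#' @export
correct_ambient <- function(x, soup, estimate, labels, seed = 1L,
                            method = c("cluster", "cell")) {
  method <- match.arg(method)
  m <- as_counts(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m))
  rho <- stats::setNames(estimate$rho, estimate$cluster)[labels]
  rho[is.na(rho)] <- 0
  N <- Matrix::rowSums(m)
  trip <- Matrix::summary(methods::as(m, "CsparseMatrix"))
  e <- rho[trip$i] * N[trip$i] * soup[colnames(m)[trip$j]]
  set.seed(derive_seed(seed, "correct_ambient"))
  newx <- trip$x
  if (method == "cell") {
    rnd <- floor(e) + (stats::runif(length(e)) < (e - floor(e)))
    newx <- pmax(0, trip$x - rnd)
  } else {
    soup_vec <- soup[colnames(m)]
    for (k in unique(labels)) {
      rho_k <- stats::setNames(estimate$rho, estimate$cluster)[k]
      if (is.na(rho_k) || rho_k <= 0) next
      cluster_N <- sum(N[labels == k])
      target <- rho_k * cluster_N * soup_vec  # expected soup per gene, whole cluster
      total <- floor(target) + (stats::runif(length(target)) < (target - floor(target)))
      sel <- which(labels[trip$i] == k)
      for (idx in split(sel, trip$j[sel])) {
        tg <- total[trip$j[idx[1]]]
        if (tg <= 0) next
        avail <- sum(trip$x[idx])
        if (tg >= avail) { newx[idx] <- 0; next }
        cs <- cumsum(trip$x[idx])
        pos <- sample.int(avail, tg)
        rem <- tabulate(findInterval(pos - 0.5, cs) + 1L, nbins = length(idx))
        newx[idx] <- trip$x[idx] - rem
      }
    }
  }
  out <- Matrix::drop0(Matrix::sparseMatrix(i = trip$i, j = trip$j, x = newx,
                                            dims = dim(m), dimnames = dimnames(m)))
  if (inherits(x, "count_matrix")) count_matrix(out, rownames(m), x$genes) else out
}
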