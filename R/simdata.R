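#' Configuration for the synthetic retina generator
#'
#' The generator emulates a droplet scRNA-seq capture of the adult
#' *Drosophila* compound eye: six major cell types in their anatomical
#' "expected" proportions (R1-6 30%, R7 5%, R8 5%, cone 20%, primary pigment
#' 10%, secondary/tertiary pigment 20%, out of the 90% of ommatidial cells
#' that are not bristle cells, renormalized), pale/yellow inner-photoreceptor
#' subtypes at 30:70, dorsal-third yellow R7s co-expressing Rh3 and Rh4,
#' a dorsal-rim-area (DRA) class expressing Rh3 plus hth, mutually exclusive
#' Rhodopsin expression, ninaE-dominated ambient RNA, mitochondrial
#' background, doublets, a small non-eye (neuron/glia) contingent, and a
#' decline in library depth with age.
#'
#' @param n_cells number of cells to simulate.
#' @param proportions named fractions per cell type (must sum to 1). Types:
#'   `R1-6`, `R7`, `R8`, `cone`, `pigment1`, `pigment23`, `noneye`.
#' @param pale_prob probability that an inner photoreceptor is pale
#'   (Rh3-R7 / Rh5-R8); default 0.3 for the canonical 30:70 pale:yellow ratio.
#' @param dorsal3_frac fraction of yellow R7s in the dorsal third
#'   (co-expressing Rh3 and Rh4).
#' @param dra_frac fraction of inner photoreceptors belonging to the DRA.
#' @param n_genes total genes (panel + mitochondrial + planted markers + filler).
#' @param n_markers_per_type planted markers per marker group.
#' @param marker_fold multiplicative expression boost of a planted marker in
#'   its home type(s) (>= 1).
#' @param rho_mean,rho_conc Beta mean/concentration of the per-cell ambient
#'   contamination fraction rho.
#' @param mito_frac_mean mean mitochondrial fraction of the library.
#' @param doublet_rate fraction of barcodes that are doublets (< 0.5).
#' @param depth_decline named per-timepoint library-size multipliers.
#' @param timepoint_probs named sampling probabilities over timepoints
#'   (default: uniform over `names(depth_decline)`).
#' @param sex sex label recorded for all cells of this dataset.
#' @param seed integer seed controlling gene-level parameters.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 5000,
                       proportions = NULL,
                       pale_prob = 0.3, dorsal3_frac = 0.15, dra_frac = 0.02,
                       n_genes = 2000, n_markers_per_type = 20, marker_fold = 8,
                       rho_mean = 0.05, rho_conc = 20,
                       mito_frac_mean = 0.08, doublet_rate = 0.01,
                       depth_decline = c(`1D` = 1, `3D` = 1, `7D` = 0.6),
                       timepoint_probs = NULL, sex = "M", seed = 1L) {
  if (is.null(proportions)) {
    expected <- c(`R1-6` = 30, R7 = 5, R8 = 5, cone = 20,
                  pigment1 = 10, pigment23 = 20) / 90  # bristle cells uncounted
    proportions <- c(expected * 0.97, noneye = 0.03)
  }
  if (is.null(timepoint_probs)) {
    timepoint_probs <- stats::setNames(rep(1 / length(depth_decline), length(depth_decline)),
                                       names(depth_decline))
  }
  cfg <- list(n_cells = n_cells, proportions = proportions, pale_prob = pale_prob,
              dorsal3_frac = dorsal3_frac, dra_frac = dra_frac, n_genes = n_genes,
              n_markers_per_type = n_markers_per_type, marker_fold = marker_fold,
              rho_mean = rho_mean, rho_conc = rho_conc,
              mito_frac_mean = mito_frac_mean, doublet_rate = doublet_rate,
              depth_decline = depth_decline, timepoint_probs = timepoint_probs,
              sex = sex, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cells < 0) stop("n_cells must be non-negative")
  if (abs(sum(cfg$proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", sum(cfg$proportions), ")")
  fracs <- c(cfg$proportions, cfg$pale_prob, cfg$dorsal3_frac, cfg$dra_frac,
             cfg$rho_mean, cfg$mito_frac_mean, cfg$doublet_rate)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$marker_fold < 1) stop("marker_fold must be >= 1")
  if (is.null(names(cfg$proportions))) stop("proportions must be named")
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  invisible(TRUE)
}

# Subtype universe. DRA inner photoreceptors are tracked per parent type so
# that "subtype implies consistent type" holds.
.sim_subtypes <- c("R1-6", "R7-pale", "R7-yellow", "R7-dorsal3", "R7-DRA",
                   "R8-pale", "R8-yellow", "R8-DRA",
                   "cone", "pigment1", "pigment23", "noneye")

subtype_to_type <- function(subtype) {
  out <- subtype
  out[startsWith(subtype, "R7")] <- "R7"
  out[startsWith(subtype, "R8")] <- "R8"
  out
}

#' Rhodopsin expression rules per simulated subtype
#'
#' The opsin exclusivity table: R1-6 express ninaE only; pale R7 Rh3; yellow
#' R7 Rh4; dorsal-third yellow R7 both Rh3 and Rh4; pale R8 Rh5; yellow R8
#' Rh6; DRA R7/R8 express Rh3 (plus hth) and no other Rhodopsin; all other
#' types express no Rhodopsin.
#'
#' @return named list: subtype -> character vector of permitted opsin genes.
#' @export
opsin_rules <- function() {
  list(`R1-6` = "ninaE",
       `R7-pale` = "Rh3", `R7-yellow` = "Rh4", `R7-dorsal3` = c("Rh3", "Rh4"),
       `R7-DRA` = "Rh3",
       `R8-pale` = "Rh5", `R8-yellow` = "Rh6", `R8-DRA` = "Rh3",
       cone = character(), pigment1 = character(), pigment23 = character(),
       noneye = character())
}

.opsin_genes <- c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6")
.mito_genes <- c("mt:CoI", "mt:CoII", "mt:CoIII", "mt:ATPase6", "mt:Cyt-b",
                 "mt:ND1", "mt:ND2", "mt:ND4", "mt:ND5", "mt:srRNA")

#' Gene table of the synthetic retina
#'
#' Deterministic given `config$seed`: panel genes with fixed biology-scale
#' means (Rhodopsins abundant, transcription factors sparse), mitochondrial
#' genes, planted marker groups (pan-photoreceptor, shared R7/8, cone,
#' primary pigment, secondary/tertiary pigment, non-eye) boosted
#' `marker_fold`-fold in their home types over a low off-target baseline, and
#' log-normal filler genes. Per-gene NB dispersion is drawn from a gamma
#' prior.
#'
#' @param config a [sim_config()].
#' @return data.frame: id, symbol, base_mean, size (NB size), marker_of, mito.
#' @export
sim_gene_table <- function(config) {
  set.seed(derive_seed(config$seed, "sim_gene_table"))
  panel <- c("ninaE", "Rh3", "Rh4", "Rh5", "Rh6", "sens", "pros", "ct", "Crys",
             "w", "Pdh", "santa-maria", "wrapper", "hth", "Skeletor",
             "fne", "moody", "repo")
  nm <- config$n_markers_per_type
  marker_groups <- list(panPR = "mkPR", R78 = "mkR78", cone = "mkCC",
                        pigment1 = "mkPM1", pigment23 = "mkPM23", noneye = "mkNE")
  marker_ids <- unlist(lapply(names(marker_groups), function(g)
    sprintf("%s-%03d", marker_groups[[g]], seq_len(nm))))
  marker_of <- rep(names(marker_groups), each = nm)
  n_named <- length(panel) + length(.mito_genes) + length(marker_ids)
  if (config$n_genes < n_named)
    stop("n_genes (", config$n_genes, ") smaller than the ", n_named, " structured genes")
  n_filler <- config$n_genes - n_named
  filler_ids <- sprintf("G%04d", seq_len(n_filler))
  ids <- c(panel, .mito_genes, marker_ids, filler_ids)
  genes <- data.frame(id = ids, symbol = ids,
                      base_mean = 0, size = 1,
                      marker_of = NA_character_, mito = FALSE,
                      stringsAsFactors = FALSE)
  genes$mito[genes$id %in% .mito_genes] <- TRUE
  genes$marker_of[match(marker_ids, genes$id)] <- marker_of
  # filler + marker baselines; markers sit low off-target so a marker_fold
  # boost still leaves off-target detection below typical tau
  genes$base_mean[match(filler_ids, genes$id)] <- stats::rlnorm(n_filler, log(0.2), 1)
  genes$base_mean[match(marker_ids, genes$id)] <- stats::rlnorm(length(marker_ids), log(0.055), 0.12)
  genes$size <- 1 / stats::rgamma(nrow(genes), shape = 2, scale = 0.15)
  genes$size[genes$mito] <- 10
  genes
}

# Subtype x gene mean-boost structure: returns function(subtype) -> mean vector.
sim_mean_matrix <- function(config, genes) {
  base <- genes$base_mean
  names(base) <- genes$id
  panel_means <- function(subtype) {
    mu <- base
    mu[.opsin_genes] <- 0
    mu[c("sens", "pros", "ct", "Crys", "w", "Pdh", "santa-maria", "wrapper",
         "hth", "Skeletor", "fne", "moody", "repo")] <- 0
    mu[.mito_genes] <- 0  # mitochondrial background is injected downstream
    set_mk <- function(group, fold) {
      sel <- !is.na(genes$marker_of) & genes$marker_of == group
      mu[sel] <<- mu[sel] * fold
    }
    f <- config$marker_fold
    type <- subtype_to_type(subtype)
    if (type %in% c("R1-6", "R7", "R8")) set_mk("panPR", f)
    if (type %in% c("R7", "R8")) set_mk("R78", f)
    if (type == "cone") set_mk("cone", f)
    if (type == "pigment1") set_mk("pigment1", f)
    if (type == "pigment23") set_mk("pigment23", f)
    if (type == "noneye") set_mk("noneye", f)
    switch(subtype,
      "R1-6" = { mu["ninaE"] <- 300 },
      "R7-pale" = { mu["Rh3"] <- 150; mu["pros"] <- 1.5 },
      "R7-yellow" = { mu["Rh4"] <- 150; mu["pros"] <- 1.5 },
      "R7-dorsal3" = { mu["Rh3"] <- 30; mu["Rh4"] <- 150; mu["pros"] <- 1.5 },
      "R7-DRA" = { mu["Rh3"] <- 150; mu["pros"] <- 1.5; mu["hth"] <- 3; mu["Skeletor"] <- 2 },
      "R8-pale" = { mu["Rh5"] <- 150; mu["sens"] <- 1.5 },
      "R8-yellow" = { mu["Rh6"] <- 150; mu["sens"] <- 1.5 },
      "R8-DRA" = { mu["Rh3"] <- 150; mu["sens"] <- 1.5; mu["hth"] <- 3; mu["Skeletor"] <- 2 },
      "cone" = { mu["ct"] <- 4; mu["Crys"] <- 6 },
      "pigment1" = { mu["wrapper"] <- 4; mu["Pdh"] <- 6; mu["w"] <- 0.4 },
      "pigment23" = { mu["santa-maria"] <- 3; mu["Pdh"] <- 6; mu["w"] <- 4 },
      "noneye" = { mu["fne"] <- 4; mu["moody"] <- 3; mu["repo"] <- 5 },
      stop("unknown cell label: ", subtype)
    )
    mu
  }
  panel_means
}

#' Draw per-cell true types and subtypes
#'
#' Multinomial type draw per cell; within R7/R8, a cell is DRA with
#' probability `dra_frac`, otherwise pale with probability `pale_prob`, else
#' yellow; within yellow R7s, dorsal-third with probability `dorsal3_frac`.
#'
#' @param config a [sim_config()].
#' @param seed draw seed (default `config$seed`).
#' @return data.frame with columns `type` and `subtype` (one row per cell).
#' @export
sample_cell_types <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, "sample_cell_types"))
  n <- config$n_cells
  type <- sample(names(config$proportions), n, replace = TRUE, prob = config$proportions)
  subtype <- type
  for (pr in c("R7", "R8")) {
    idx <- which(type == pr)
    if (!length(idx)) next
    u <- stats::runif(length(idx))
    dra <- u < config$dra_frac
    pale <- !dra & (stats::runif(length(idx)) < config$pale_prob)
    sub <- ifelse(dra, paste0(pr, "-DRA"),
                  ifelse(pale, paste0(pr, "-pale"), paste0(pr, "-yellow")))
    if (pr == "R7") {
      yel <- which(sub == "R7-yellow")
      d3 <- yel[stats::runif(length(yel)) < config$dorsal3_frac]
      sub[d3] <- "R7-dorsal3"
    }
    subtype[idx] <- sub
  }
  data.frame(type = type, subtype = subtype, stringsAsFactors = FALSE)
}

#' Synthesize clean (contamination-free) counts
#'
#' Negative-binomial counts per cell from the subtype-specific mean
#' structure of [sim_gene_table()]. Opsins and panel genes obey the
#' exclusivity table of [opsin_rules()] exactly: a gene forbidden in a
#' subtype has clean count zero in every cell of that subtype.
#'
#' @param labels data.frame from [sample_cell_types()].
#' @param config a [sim_config()].
#' @param seed draw seed (default `config$seed`).
#' @return a [count_matrix()] of clean counts.
#' @export
synthesize_counts <- function(labels, config, seed = config$seed) {
  genes <- sim_gene_table(config)
  mu_of <- sim_mean_matrix(config, genes)
  subtype <- labels$subtype
  unknown <- setdiff(unique(subtype), .sim_subtypes)
  if (length(unknown)) stop("unknown cell label: ", paste(unknown, collapse = ", "))
  n <- length(subtype)
  set.seed(derive_seed(seed, "synthesize_counts"))
  ii <- vector("list", length(.sim_subtypes)); jj <- ii; xx <- ii
  b <- 0L
  for (st in .sim_subtypes) {
    cells <- which(subtype == st)
    if (!length(cells)) next
    mu <- mu_of(st)
    b <- b + 1L
    si <- list(); sj <- list(); sx <- list()
    for (g in which(mu > 0)) {
      v <- stats::rnbinom(length(cells), size = genes$size[g], mu = mu[g])
      nzi <- which(v > 0)
      if (length(nzi)) {
        si[[length(si) + 1L]] <- cells[nzi]
        sj[[length(sj) + 1L]] <- rep.int(g, length(nzi))
        sx[[length(sx) + 1L]] <- v[nzi]
      }
    }
    ii[[b]] <- unlist(si); jj[[b]] <- unlist(sj); xx[[b]] <- unlist(sx)
  }
  m <- Matrix::sparseMatrix(i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
                            x = as.numeric(unlist(xx)), dims = c(n, nrow(genes)))
  count_matrix(m, barcodes = sprintf("CELL-%06d", seq_len(n)),
               genes = genes[, c("id", "symbol")])
}

#' Inject ambient RNA, mitochondrial background, doublets, and depth decline
#'
#' The ambient ("soup") model: the soup profile is the dataset-wide
#' expression profile (dominated by ninaE), each cell's contamination
#' fraction rho is Beta-distributed, and a Binomial(N_c, rho_c) subset of
#' each cell's molecules is *replaced* by multinomial draws from the soup, so
#' library size is conserved and rho_c is interpretable as the contaminated
#' share of the cell's molecules. Mitochondrial counts are then added to hit
#' a Beta-distributed per-cell target fraction, a `doublet_rate` fraction of
#' barcodes receives a second cell's molecules, and library sizes are
#' binomially thinned by the per-timepoint `depth_decline` multiplier.
#'
#' @param clean a [count_matrix()] of clean counts.
#' @param config a [sim_config()].
#' @param seed draw seed (default `config$seed`).
#' @param labels data.frame from [sample_cell_types()] (for ground truth).
#' @param timepoint optional per-cell timepoint labels (default: first
#'   timepoint for all cells).
#' @return list with `counts` (observed [count_matrix()]) and `truth`
#'   (ground-truth list: `cells` and `genes` data.frames).
#' @export
add_ambient_and_noise <- function(clean, config, seed = config$seed,
                                  labels = NULL, timepoint = NULL) {
  if (config$doublet_rate >= 0.5)
    stop("doublet_rate (", config$doublet_rate, ") >= 0.5 is implausible")
  m <- as_counts(clean)
  n <- nrow(m)
  genes <- sim_gene_table(config)
  if (is.null(timepoint)) timepoint <- rep(names(config$depth_decline)[1], n)
  stopifnot(length(timepoint) == n)
  set.seed(derive_seed(seed, "add_ambient_and_noise"))

  tot <- sum(m)
  soup <- if (tot > 0) Matrix::colSums(m) / tot else rep(0, ncol(m))
  rho <- if (config$rho_mean > 0 && n > 0) {
    stats::rbeta(n, config$rho_mean * config$rho_conc,
                 (1 - config$rho_mean) * config$rho_conc)
  } else rep(0, n)

  tm <- methods::as(Matrix::t(m), "CsparseMatrix")  # genes x cells: per-cell slices
  p <- tm@p; gi <- tm@i; gx <- tm@x
  ii <- list(); jj <- list(); xx <- list()
  for (cell in seq_len(n)) {
    lo <- p[cell] + 1L; hi <- p[cell + 1L]
    if (hi < lo) next
    g_idx <- gi[lo:hi] + 1L
    x <- gx[lo:hi]
    N <- sum(x)
    nsoup <- if (rho[cell] > 0) stats::rbinom(1L, N, rho[cell]) else 0L
    if (nsoup > 0) {
      cs <- cumsum(x)
      pos <- sample.int(N, nsoup)
      rem <- tabulate(findInterval(pos - 0.5, cs) + 1L, nbins = length(x))
      x <- x - rem
      add <- stats::rmultinom(1L, nsoup, soup)[, 1L]
      az <- which(add > 0)
      if (length(az)) {
        ii[[length(ii) + 1L]] <- rep.int(cell, length(az))
        jj[[length(jj) + 1L]] <- az
        xx[[length(xx) + 1L]] <- add[az]
      }
    }
    keep <- which(x > 0)
    if (length(keep)) {
      ii[[length(ii) + 1L]] <- rep.int(cell, length(keep))
      jj[[length(jj) + 1L]] <- g_idx[keep]
      xx[[length(xx) + 1L]] <- x[keep]
    }
  }
  out <- if (length(ii)) {
    Matrix::sparseMatrix(i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
                         x = as.numeric(unlist(xx)), dims = dim(m))
  } else m

  # mitochondrial background toward a per-cell Beta target fraction
  mito_idx <- which(genes$mito)
  if (config$mito_frac_mean > 0 && length(mito_idx) && n > 0) {
    f <- stats::rbeta(n, config$mito_frac_mean * 50, (1 - config$mito_frac_mean) * 50)
    Nn <- Matrix::rowSums(out)
    m_add <- round(Nn * f / (1 - f))
    w <- rev(seq_along(mito_idx))  # fixed decreasing weights across mt genes
    has <- which(m_add > 0)
    if (length(has)) {
      adds <- vapply(has, function(cell) stats::rmultinom(1L, m_add[cell], w)[, 1L],
                     integer(length(mito_idx)))
      out <- out + Matrix::sparseMatrix(
        i = rep(has, each = length(mito_idx))[as.vector(adds) > 0],
        j = rep(mito_idx, length(has))[as.vector(adds) > 0],
        x = as.vector(adds)[as.vector(adds) > 0], dims = dim(out))
    }
  }

  # doublets: a random subset of barcodes receives a partner cell's molecules
  doublet <- rep(FALSE, n)
  nd <- round(config$doublet_rate * n)
  if (nd > 0 && n >= 2) {
    dbl <- sample.int(n, nd)
    partner <- vapply(dbl, function(cell) sample(setdiff(seq_len(n), cell), 1L), 1L)
    out[dbl, ] <- out[dbl, , drop = FALSE] + out[partner, , drop = FALSE]
    doublet[dbl] <- TRUE
  }

  # per-timepoint depth decline by binomial thinning
  d <- unname(config$depth_decline[timepoint])
  d[is.na(d)] <- 1
  if (any(d < 1)) {
    out <- methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
    trip <- Matrix::summary(out)
    pr <- d[trip$i]
    thin <- trip$x
    sel <- pr < 1
    thin[sel] <- stats::rbinom(sum(sel), size = as.integer(trip$x[sel]), prob = pr[sel])
    out <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = thin, dims = dim(out))
  }
  out <- Matrix::drop0(out)

  barcodes <- rownames(m)
  if (is.null(barcodes)) barcodes <- sprintf("CELL-%06d", seq_len(n))
  truth <- list(
    cells = data.frame(barcode = barcodes,
                       type = if (!is.null(labels)) labels$type else NA_character_,
                       subtype = if (!is.null(labels)) labels$subtype else NA_character_,
                       rho = rho, doublet = doublet, timepoint = timepoint,
                       stringsAsFactors = FALSE),
    genes = data.frame(id = genes$id, marker_of = genes$marker_of,
                       soup_frac = soup, mito = genes$mito,
                       stringsAsFactors = FALSE))
  list(counts = count_matrix(out, barcodes = barcodes, genes = genes[, c("id", "symbol")]),
       truth = truth)
}

#' Generate a complete synthetic retina dataset
#'
#' Composes [sample_cell_types()], [synthesize_counts()], and
#' [add_ambient_and_noise()], and attaches per-cell timepoint and sex
#' covariates.
#'
#' @param config a [sim_config()].
#' @param seed draw seed (default `config$seed`).
#' @return list: `counts` (observed [count_matrix()]), `clean` (pre-noise
#'   [count_matrix()]), `annotation` (per-cell data.frame: barcode, timepoint,
#'   sex), `truth` (ground truth as in [add_ambient_and_noise()]).
#' @export
generate_retina_dataset <- function(config, seed = config$seed) {
  validate_sim_config(config)
  labels <- sample_cell_types(config, seed)
  set.seed(derive_seed(seed, "covariates"))
  tp <- sample(names(config$timepoint_probs), config$n_cells, replace = TRUE,
               prob = config$timepoint_probs)
  clean <- synthesize_counts(labels, config, seed)
  obs <- add_ambient_and_noise(clean, config, seed, labels = labels, timepoint = tp)
  annotation <- data.frame(barcode = rownames(obs$counts$counts),
                           timepoint = tp,
                           sex = rep(config$sex, config$n_cells),
                           stringsAsFactors = FALSE)
  list(counts = obs$counts, clean = clean, annotation = annotation, truth = obs$truth)
}

#' Write a generated dataset as a 10x-style directory
#'
#' `matrix.mtx` + `features.tsv` + `barcodes.tsv` for the observed counts,
#' `annotation.tsv` and `ground_truth_cells.tsv` / `ground_truth_genes.tsv`
#' as TSV, and the configuration as `sim_config.json`.
#'
#' @param dataset result of [generate_retina_dataset()].
#' @param config the [sim_config()] used.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_retina_dataset <- function(dataset, config, dir) {
  write_counts_mtx(dataset$counts, dir)
  utils::write.table(dataset$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$cells, file.path(dir, "ground_truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$genes, file.path(dir, "ground_truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
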