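#' Specify a synthetic single-cell expression experiment
#'
#' Negative-binomial counts with a block marker structure: each cell type owns
#' a disjoint set of marker genes whose mean is `marker_fc`-fold the baseline.
#' A configurable slice of genes is flagged mitochondrial so the QC filter has
#' something to act on.
#'
#' @param n_genes total gene count.
#' @param types character vector of cell-type names.
#' @param markers_per_type number of marker genes owned by each type
#'   (disjoint across types; `n_genes` must accommodate them).
#' @param marker_fc fold change of a marker gene in its own type.
#' @param base_mean_range genes draw a baseline mean uniformly (on log scale)
#'   from this range.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   must be > 0. Values near zero approach Poisson.
#' @param n_mito number of mitochondrial genes (named `MT-1..`).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size factors.
#' @param seed integer seed.
#' @return object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 2000, types = paste0("T", 1:5),
                            markers_per_type = 40, marker_fc = 6,
                            base_mean_range = c(0.05, 2), dispersion = 0.4,
                            n_mito = 20, libsize_meanlog = 0, libsize_sdlog = 0.2,
                            seed = 1L) {
  abort_if(dispersion <= 0, "dispersion must be > 0")
  abort_if(length(types) < 1, "need at least one type")
  abort_if(n_genes < length(types) * markers_per_type + n_mito,
           "n_genes too small for the requested disjoint marker sets")
  abort_if(any(base_mean_range <= 0), "base means must be positive")
  genes <- sprintf("G%05d", seq_len(n_genes))
  if (n_mito > 0) genes[seq_len(n_mito)] <- paste0("MT-", seq_len(n_mito))
  ## disjoint marker blocks, skipping the mitochondrial genes
  pool <- setdiff(seq_len(n_genes), seq_len(n_mito))
  marker_sets <- split(pool[seq_len(length(types) * markers_per_type)],
                       rep(seq_along(types), each = markers_per_type))
  names(marker_sets) <- types
  structure(list(n_genes = n_genes, types = types, genes = genes,
                 marker_sets = marker_sets, marker_fc = marker_fc,
                 base_mean_range = base_mean_range, dispersion = dispersion,
                 n_mito = n_mito, libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, seed = seed),
            class = "expression_spec")
}

## per-type mean matrix (genes x types) implied by a spec; drawn once per seed
type_means <- function(spec) {
  set.seed(as.integer(spec$seed))
  base <- exp(runif(spec$n_genes, log(spec$base_mean_range[1]),
                    log(spec$base_mean_range[2])))
  mu <- matrix(base, spec$n_genes, length(spec$types),
               dimnames = list(spec$genes, spec$types))
  for (tp in spec$types) mu[spec$marker_sets[[tp]], tp] <-
      mu[spec$marker_sets[[tp]], tp] * spec$marker_fc
  mu
}

#' Simulate labeled single-cell counts
#'
#' @param spec an [expression_spec()].
#' @param n_cells_per_type cells per type (scalar or named vector).
#' @param inject_low_complexity number of extra cells expressing only ~300
#'   genes (should be removed by [qc_filter()]).
#' @param inject_high_mito number of extra cells with ~40% mitochondrial
#'   counts (should be removed by [qc_filter()]).
#' @param seed integer seed (defaults to the spec's).
#' @return list with `counts` (genes x cells dgCMatrix), `labels` (per cell),
#'   `mito` (logical per gene), `mu` (genes x types mean matrix).
#' @export
simulate_sc_counts <- function(spec, n_cells_per_type = 100,
                               inject_low_complexity = 0,
                               inject_high_mito = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "expression_spec"))
  mu <- type_means(spec)
  abort_if(any(mu < 0), "negative expression means")
  if (length(n_cells_per_type) == 1)
    n_cells_per_type <- setNames(rep(n_cells_per_type, length(spec$types)),
                                 spec$types)
  set.seed(as.integer(seed))
  size <- 1 / spec$dispersion
  cols <- list(); labels <- character(0)
  for (tp in spec$types) {
    n <- n_cells_per_type[[tp]]
    if (n == 0) next
    ls <- rlnorm(n, spec$libsize_meanlog, spec$libsize_sdlog)
    m <- matrix(rnbinom(spec$n_genes * n, mu = outer(mu[, tp], ls), size = size),
                spec$n_genes, n)
    cols[[tp]] <- m
    labels <- c(labels, rep(tp, n))
  }
  counts <- do.call(cbind, cols)
  ## constructed QC violators: low-complexity cells express ~300 genes;
  ## high-mito cells carry ~40% mitochondrial counts
  if (inject_low_complexity > 0) {
    m <- matrix(0, spec$n_genes, inject_low_complexity)
    for (j in seq_len(inject_low_complexity)) {
      on <- sample(spec$n_genes, 300)
      m[on, j] <- rnbinom(300, mu = mu[on, 1], size = size) + 1
    }
    counts <- cbind(counts, m)
    labels <- c(labels, rep("low_complexity", inject_low_complexity))
  }
  if (inject_high_mito > 0) {
    mito_idx <- seq_len(spec$n_mito)
    m <- matrix(rnbinom(spec$n_genes * inject_high_mito, mu = mu[, 1], size = size),
                spec$n_genes, inject_high_mito)
    for (j in seq_len(inject_high_mito)) {
      tot <- sum(m[, j])
      m[mito_idx, j] <- stats::rmultinom(1, round(0.4 / 0.6 * tot), rep(1, spec$n_mito))
    }
    counts <- cbind(counts, m)
    labels <- c(labels, rep("high_mito", inject_high_mito))
  }
  dimnames(counts) <- list(spec$genes,
                           paste0("cell", seq_len(ncol(counts))))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       labels = labels,
       mito = startsWith(spec$genes, "MT-"),
       mu = mu)
}

#' Simulate bulk mixtures from a signature with known fractions
#'
#' `bulk = S %*% f` per mixture, fractions drawn from a symmetric Dirichlet,
#' optionally perturbed by multiplicative log-normal noise (`noise_sd` on the
#' log scale, so 0.05 is "5% noise") or additive Gaussian noise.
#'
#' @param signature genes x types matrix in linear scale.
#' @param n_mixtures number of bulk samples.
#' @param dirichlet_alpha concentration of the fraction prior.
#' @param noise_sd noise scale; 0 gives exact mixtures.
#' @param noise_type `"multiplicative"` (log-normal) or `"additive"`.
#' @param fractions optional mixtures x types matrix of fractions (rows on
#'   the simplex) overriding the Dirichlet draw.
#' @param seed integer seed.
#' @return list with `bulk` (genes x mixtures) and `fractions`
#'   (mixtures x types, rows summing to 1).
#' @export
simulate_mixtures <- function(signature, n_mixtures = 50, dirichlet_alpha = 1,
                              noise_sd = 0, noise_type = "multiplicative",
                              fractions = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  k <- ncol(signature)
  if (is.null(fractions)) {
    g <- matrix(rgamma(n_mixtures * k, shape = dirichlet_alpha), n_mixtures, k)
    fr <- g / rowSums(g)
  } else {
    fr <- as.matrix(fractions)
    abort_if(ncol(fr) != k, "fractions must have one column per type")
    abort_if(any(abs(rowSums(fr) - 1) > 1e-8), "fraction rows must sum to 1")
    n_mixtures <- nrow(fr)
  }
  colnames(fr) <- colnames(signature)
  rownames(fr) <- paste0("mix", seq_len(n_mixtures))
  bulk <- signature %*% t(fr)
  if (noise_sd > 0) {
    if (noise_type == "multiplicative") {
      bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, noise_sd),
                                nrow(bulk), ncol(bulk)))
    } else {
      bulk <- pmax(bulk + matrix(rnorm(length(bulk), 0, noise_sd),
                                 nrow(bulk), ncol(bulk)), 0)
    }
  }
  colnames(bulk) <- rownames(fr)
  list(bulk = bulk, fractions = fr)
}
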