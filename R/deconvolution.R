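#' Quality-control filter for single-cell expression
#'
#' Excludes cells with fewer than `min_genes` or more than `max_genes`
#' detected genes, or with strictly more than `max_mito` mitochondrial
#' transcript fraction. Boundary cells (exactly 400 genes, exactly 25%
#' mitochondrial) are kept: the exclusion rules are strict inequalities.
#'
#' @param counts genes x cells matrix (dense or sparse).
#' @param mito logical per-gene mitochondrial flag; default genes whose name
#'   starts with `"MT-"`.
#' @param min_genes,max_genes detected-gene bounds (defaults 400 / 10000).
#' @param max_mito mitochondrial fraction cutoff (default 0.25).
#' @return list with `counts` (the surviving columns), `keep` (logical per
#'   input cell), `stats` (tibble: cell, n_genes, mito_frac, keep).
#' @export
qc_filter <- function(counts, mito = startsWith(rownames(counts), "MT-"),
                      min_genes = 400, max_genes = 10000, max_mito = 0.25) {
  abort_if(is.null(rownames(counts)) && length(mito) != nrow(counts),
           "need a mito flag per gene")
  n_genes <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  mito_frac <- ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  keep <- n_genes >= min_genes & n_genes <= max_genes & mito_frac <= max_mito
  list(counts = counts[, keep, drop = FALSE],
       keep = keep,
       stats = tibble::tibble(cell = colnames(counts) %||%
                                as.character(seq_len(ncol(counts))),
                              n_genes = as.integer(n_genes),
                              mito_frac = as.numeric(mito_frac),
                              keep = keep))
}

#' Collapse probesets to genes
#'
#' Microarray platforms measure a gene with several probesets; for each gene
#' the probeset with the highest average expression across samples is kept.
#' Ties go to the lexicographically first probe id.
#'
#' @param expr probesets x samples matrix with probe ids as rownames.
#' @param probe_gene named character vector: probe id -> gene symbol.
#' @return genes x samples matrix.
#' @export
collapse_probesets <- function(expr, probe_gene) {
  abort_if(is.null(rownames(expr)), "expr needs probe ids as rownames")
  genes <- probe_gene[rownames(expr)]
  abort_if(anyNA(genes), "every probe id needs a gene mapping")
  avg <- rowMeans(expr)
  ord <- order(genes, -avg, rownames(expr))
  first <- ord[!duplicated(genes[ord])]
  out <- expr[first, , drop = FALSE]
  rownames(out) <- genes[first]
  out[order(rownames(out)), , drop = FALSE]
}

## Vectorized two-sided Wilcoxon rank-sum test of one group against the rest,
## normal approximation with tie correction, one gene per row. Ranks and tie
## corrections are precomputed once so the per-type call is a matrix product.
rank_sum_prep <- function(expr) {
  ranks <- t(apply(expr, 1, rank))
  tie_corr <- apply(expr, 1, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  list(ranks = ranks, tie_corr = tie_corr, n = ncol(expr))
}

rank_sum_test <- function(prep, in_group) {
  n1 <- sum(in_group); n <- prep$n; n2 <- n - n1
  w <- prep$ranks %*% in_group
  mu <- n1 * (n + 1) / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - prep$tie_corr / (n * (n - 1)))
  z <- ifelse(sig2 > 0, (w - mu) / sqrt(pmax(sig2, 0)), 0)
  2 * pnorm(-abs(z))
}

#' Build a single-cell-derived signature matrix
#'
#' KTB18-style construction: (1) stratified sampling of `n_cells` labeled
#' cells (proportional per type, largest-remainder rounding); (2) per-type
#' mean expression in linear space; (3) genes whose maximum per-type mean
#' falls below `min_expr` are dropped; (4) per type, candidate barcode genes
#' are the significantly up-regulated ones (two-sided rank-sum test of type
#' vs rest, Benjamini-Hochberg q < `q_cutoff`, positive fold change), ranked
#' by log fold change; (5) for every barcode-list size G between `gmin` and
#' `gmax` the union of each type's top-G candidates forms a candidate matrix
#' whose 2-norm condition number is computed; (6) the G minimizing the
#' condition number wins (smallest G on ties).
#'
#' @param expr genes x cells matrix, linear scale, non-negative.
#' @param labels cell-type label per cell.
#' @param n_cells cells to sample before profiling (default 10000, capped).
#' @param min_expr minimum expression threshold (default 0.1).
#' @param gmin,gmax barcode genes per type bounds (defaults 300 / 500).
#' @param q_cutoff BH q-value gate for candidate genes (default 0.05).
#' @param seed integer seed.
#' @return object of class `signature_matrix`: `matrix` (genes x types mean
#'   linear expression restricted to the selected union), `barcode` (named
#'   list of per-type gene vectors), `g` (chosen size), `condition_number`,
#'   `scan` (tibble: g, kappa).
#' @export
build_signature <- function(expr, labels, n_cells = 10000, min_expr = 0.1,
                            gmin = 300, gmax = 500, q_cutoff = 0.05,
                            seed = 1L) {
  abort_if(length(labels) != ncol(expr), "one label per cell required")
  types <- sort(unique(labels))
  abort_if(length(types) < 2, "need at least two cell types")
  abort_if(gmin <= 0 || gmin > gmax, "need 0 < gmin <= gmax")
  abort_if(min(expr) < 0, "expression must be non-negative (linear scale)")
  ## stratified subsample, proportional per type
  if (n_cells < ncol(expr)) {
    fake <- tibble::tibble(idx = seq_len(ncol(expr)), sample_id = labels)
    sel <- stratified_sample(fake, n_cells, seed = seed)$cells$idx
    expr <- expr[, sel, drop = FALSE]
    labels <- labels[sel]
  }
  expr <- as.matrix(expr)
  means <- vapply(types, function(tp)
    rowMeans(expr[, labels == tp, drop = FALSE]), numeric(nrow(expr)))
  keep <- apply(means, 1, max) >= min_expr
  expr <- expr[keep, , drop = FALSE]
  means <- means[keep, , drop = FALSE]
  abort_if(is.null(rownames(expr)), "expr needs gene names as rownames")
  ## per-type candidate barcode genes
  prep <- rank_sum_prep(expr)
  cand <- list()
  for (tp in types) {
    ing <- labels == tp
    p <- drop(rank_sum_test(prep, as.numeric(ing)))
    q <- p.adjust(p, "BH")
    rest <- rowMeans(means[, colnames(means) != tp, drop = FALSE])
    lfc <- log2((means[, tp] + 1e-9) / (rest + 1e-9))
    ok <- which(q < q_cutoff & lfc > 0)
    cand[[tp]] <- ok[order(-lfc[ok])]
    if (length(ok) < gmin)
      warning("type ", tp, " has only ", length(ok),
              " candidate barcode genes; lower bound relaxed")
  }
  ## condition-number scan over the barcode-list size
  gs <- seq(gmin, gmax)
  kappa <- vapply(gs, function(g) {
    rows <- sort(unique(unlist(lapply(cand, head, g))))
    m <- means[rows, , drop = FALSE]
    ev <- eigen(crossprod(m), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    if (min(ev) == 0) Inf else sqrt(max(ev) / min(ev))
  }, 0)
  best <- gs[which.min(kappa)]
  barcode <- lapply(cand, function(ii) rownames(expr)[head(ii, best)])
  rows <- sort(unique(unlist(lapply(cand, head, best))))
  structure(list(matrix = means[rows, , drop = FALSE],
                 barcode = barcode, g = best,
                 condition_number = min(kappa),
                 scan = tibble::tibble(g = gs, kappa = kappa)),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix>", nrow(x$matrix), "genes x", ncol(x$matrix),
      "types; barcode size", x$g,
      sprintf("(condition number %.3g)\n", x$condition_number))
  invisible(x)
}

#' Pseudobulk profiles with known composition
#'
#' Aggregates single-cell expression within groups (sum by default) and
#' records each group's true cell-type fractions, the standard validation
#' input for deconvolution.
#'
#' @param expr genes x cells matrix, linear scale.
#' @param labels cell-type label per cell.
#' @param groups group id per cell.
#' @param fun `"sum"` or `"mean"`.
#' @return list with `bulk` (genes x groups) and `fractions`
#'   (groups x types, rows summing to 1).
#' @export
pseudobulk <- function(expr, labels, groups, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  gs <- sort(unique(groups))
  types <- sort(unique(labels))
  bulk <- vapply(gs, function(g) {
    m <- expr[, groups == g, drop = FALSE]
    if (fun == "sum") Matrix::rowSums(m) else Matrix::rowMeans(m)
  }, numeric(nrow(expr)))
  fr <- t(vapply(gs, function(g)
    as.numeric(table(factor(labels[groups == g], levels = types))) /
      sum(groups == g), numeric(length(types))))
  dimnames(fr) <- list(gs, types)
  colnames(bulk) <- gs
  list(bulk = bulk, fractions = fr)
}

#' Estimate cell-type fractions by non-negative least squares
#'
#' For every bulk sample, solves `min || S f - b ||_2` subject to `f >= 0`
#' over the genes shared between the signature and the bulk profile, then
#' renormalizes `f` to sum to one. A documented stand-in for the ν-SVR solver
#' of CIBERSORT-class tools.
#'
#' @param sig a [build_signature()] result, or a plain genes x types matrix.
#' @param bulk genes x samples matrix, linear scale.
#' @param min_shared minimum shared gene count (warning below it, error at 0).
#' @return list of class `mixture_fractions`: `fractions` (samples x types,
#'   rows summing to 1), `residual` (relative fit residual per sample),
#'   `n_genes` used.
#' @export
estimate_fractions <- function(sig, bulk, min_shared = 50) {
  S <- if (inherits(sig, "signature_matrix")) sig$matrix else as.matrix(sig)
  bulk <- as.matrix(bulk)
  shared <- intersect(rownames(S), rownames(bulk))
  abort_if(length(shared) == 0, "no shared genes between signature and bulk")
  if (length(shared) < min_shared)
    warning("only ", length(shared), " shared genes")
  S <- S[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  k <- ncol(S)
  fr <- matrix(0, ncol(B), k, dimnames = list(colnames(B), colnames(S)))
  resid <- numeric(ncol(B))
  for (j in seq_len(ncol(B))) {
    b <- B[, j]
    abort_if(all(b == 0), paste0("all-zero bulk sample: ", colnames(B)[j]))
    fit <- pracma::lsqnonneg(S, b)
    f <- fit$x
    resid[j] <- sqrt(sum((S %*% f - b)^2)) / sqrt(sum(b^2))
    fr[j, ] <- if (sum(f) > 0) f / sum(f) else rep(1 / k, k)
  }
  structure(list(fractions = fr, residual = resid, n_genes = length(shared)),
            class = "mixture_fractions")
}

#' Correlate estimated with true fractions
#'
#' Per-type Pearson correlation across samples between estimated and true
#' fractions, plus the median over evaluable types. Types with zero variance
#' in either vector are flagged non-evaluable (merge such subsets with
#' [merge_types()] before evaluating, as is done for NK subsets).
#'
#' @param estimated samples x types matrix (or `mixture_fractions`).
#' @param truth samples x types matrix of true fractions.
#' @return list with `per_type` (tibble: type, r, evaluable) and `median_r`.
#' @export
evaluate_deconvolution <- function(estimated, truth) {
  E <- if (inherits(estimated, "mixture_fractions")) estimated$fractions
       else as.matrix(estimated)
  types <- intersect(colnames(E), colnames(truth))
  abort_if(length(types) == 0, "no shared types")
  per <- lapply(types, function(tp) {
    x <- E[, tp]; y <- truth[rownames(E), tp]
    ok <- sd(x) > 0 && sd(y) > 0
    tibble::tibble(type = tp, r = if (ok) cor(x, y) else NA_real_,
                   evaluable = ok)
  })
  per <- dplyr::bind_rows(per)
  list(per_type = per, median_r = median(per$r[per$evaluable]))
}

#' Merge cell-type labels
#'
#' Label-mapping preprocessing used e.g. to pool NK subsets before
#' deconvolution evaluation.
#'
#' @param labels character vector of labels.
#' @param map named character vector: old label -> new label.
#' @return relabeled vector.
#' @export
merge_types <- function(labels, map) {
  hit <- labels %in% names(map)
  labels[hit] <- unname(map[labels[hit]])
  labels
}
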