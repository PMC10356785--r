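#' Normalize marker intensities to trimmed Z-scores
#'
#' Raw MFI values are standardized within each imaging region (marker by
#' marker), then trimmed to the `[0, 5]` range so that outliers cannot
#' dominate downstream clustering. Degenerate groups (zero variance, or a
#' single cell) yield Z = 0, keeping the cells usable with that marker
#' uninformative.
#'
#' @param cells cell table with raw MFI columns.
#' @param markers character vector of marker column names.
#' @param trim lower/upper trim bounds (default `c(0, 5)`).
#' @param group grouping column for normalization (default `"region_id"`).
#' @return `cells` with one `<marker>_z` column per marker.
#' @export
normalize_mfi <- function(cells, markers, trim = c(0, 5), group = "region_id") {
  abort_if(trim[1] >= trim[2], "trim lower bound must be below upper bound")
  missing <- setdiff(markers, names(cells))
  abort_if(length(missing) > 0,
           paste0("missing marker columns: ", paste(missing, collapse = ", ")))
  g <- cells[[group]]
  abort_if(any(is.na(g) | !nzchar(as.character(g))), "empty group ids")
  idx <- split(seq_len(nrow(cells)), g)
  singletons <- names(idx)[lengths(idx) < 2]
  if (length(singletons))
    warning("groups with a single cell get Z = 0: ",
            paste(singletons, collapse = ", "))
  out <- cells
  for (mk in markers) {
    v <- cells[[mk]]
    z <- numeric(length(v))
    for (ii in idx) {
      if (length(ii) < 2) { z[ii] <- 0; next }
      s <- sd(v[ii])
      z[ii] <- if (s == 0 || !is.finite(s)) 0 else (v[ii] - mean(v[ii])) / s
    }
    out[[paste0(mk, "_z")]] <- pmin(pmax(z, trim[1]), trim[2])
  }
  out
}

z_matrix <- function(cells, markers) {
  cols <- paste0(markers, "_z")
  missing <- setdiff(cols, names(cells))
  abort_if(length(missing) > 0,
           paste0("normalized columns absent (run normalize_mfi first): ",
                  paste(missing, collapse = ", ")))
  as.matrix(cells[, cols, drop = FALSE])
}

#' Stratified proportional random sampling of cells
#'
#' Draws `size` cells so that each sample contributes in proportion to its
#' share of the dataset: the real quota of sample *i* is
#' `size * N_i / M` with `M = sum(N_i)`; quotas are rounded by the
#' largest-remainder method (ties broken in sample order) so the rounded
#' quotas sum to `size` exactly, and each stays within 1 of the real quota.
#'
#' @param cells cell table.
#' @param size total number of cells to draw (`<= nrow(cells)`).
#' @param seed integer seed.
#' @param sample_col stratification column (default `"sample_id"`).
#' @return list with `cells` (the subset, in original row order) and `plan`
#'   (tibble: stratum, n, quota, size_i).
#' @export
stratified_sample <- function(cells, size, seed = 1L, sample_col = "sample_id") {
  n_i <- table(cells[[sample_col]])
  m <- sum(n_i)
  abort_if(size > m, "requested sample size exceeds the number of cells")
  quota <- as.numeric(size * n_i / m)
  s_i <- floor(quota)
  rem <- quota - s_i
  left <- size - sum(s_i)
  if (left > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    s_i[take] <- s_i[take] + 1
  }
  set.seed(as.integer(seed))
  picked <- integer(0)
  strata <- names(n_i)
  for (k in seq_along(strata)) {
    rows <- which(cells[[sample_col]] == strata[k])
    if (!length(rows)) { warning("empty stratum skipped: ", strata[k]); next }
    picked <- c(picked, if (s_i[k] >= length(rows)) rows
                else rows[sample.int(length(rows), s_i[k])])
  }
  list(cells = cells[sort(picked), , drop = FALSE],
       plan = tibble::tibble(stratum = strata, n = as.integer(n_i),
                             quota = quota, size_i = as.integer(s_i)))
}

## Jaccard-weighted kNN graph, the PhenoGraph construction: nodes are cells,
## an edge joins cells appearing in each other's k-NN lists, weighted by the
## Jaccard overlap of their neighbor sets.
jaccard_knn_graph <- function(z, k_graph) {
  n <- nrow(z)
  abort_if(n < k_graph + 1,
           "fewer cells than k_graph + 1; reduce k_graph or supply more cells")
  nn <- RANN::nn2(z, k = k_graph + 1)$nn.idx[, -1, drop = FALSE]
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_graph),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)              # |N_i intersect N_j|
  E <- ((A + Matrix::t(A)) > 0) * 1            # kNN edge mask (union-directed)
  S <- shared * E
  tri <- Matrix::which(Matrix::triu(E, 1) > 0, arr.ind = TRUE)
  ns <- S[tri]
  w <- ns / (2 * k_graph - ns)                 # Jaccard of two k-sets
  keep <- w > 0
  igraph::graph_from_data_frame(
    data.frame(from = tri[keep, 1], to = tri[keep, 2], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Cluster a normalized marker matrix with three backends
#'
#' Backend 1 performs community detection (Leiden, modularity objective) on a
#' Jaccard-weighted kNN graph with `k_graph` neighbors; the number of
#' communities it finds fixes `k` for backend 2 (a self-organizing map whose
#' code vectors are hierarchically metaclustered to `k`) and backend 3
#' (k-means). All three are seeded and deterministic.
#'
#' @param z cells x markers matrix of trimmed Z-scores.
#' @param k_graph kNN graph neighbor count (default 30).
#' @param k cluster count for backends 2-3; default the count found by the
#'   graph backend.
#' @param som_grid SOM grid dimensions `c(x, y)`; capped so the grid never
#'   exceeds a third of the cells.
#' @param seed integer seed.
#' @return list with integer membership vectors `graph`, `som`, `kmeans`, and
#'   the cluster count `k`.
#' @export
run_backends <- function(z, k_graph = 30, k = NULL, som_grid = c(10, 10),
                         seed = 1L) {
  z <- as.matrix(z)
  seeds <- derive_seeds(seed, 3)
  set.seed(seeds[1])
  g <- jaccard_knn_graph(z, k_graph)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               weights = igraph::E(g)$weight, n_iterations = 5)
  memb_graph <- as.integer(igraph::membership(cl))
  k <- k %||% max(memb_graph)
  abort_if(k < 1, "k must be >= 1")

  ## SOM + hierarchical metaclustering of the code vectors
  set.seed(seeds[2])
  n <- nrow(z)
  xd <- max(2, min(som_grid[1], floor(sqrt(n / 3))))
  yd <- max(2, min(som_grid[2], floor(sqrt(n / 3))))
  gr <- class::somgrid(xdim = xd, ydim = yd, topo = "hexagonal")
  sm <- class::batchSOM(z, gr, radii = rep(seq(max(xd, yd) / 2, 0,
                                               length.out = 6), each = 2))
  codes <- sm$codes
  unit <- as.integer(class::knn1(codes, z, factor(seq_len(nrow(codes)))))
  meta <- if (k == 1) rep(1L, nrow(codes))
          else cutree(hclust(dist(codes), method = "ward.D2"),
                      k = min(k, nrow(unique(codes))))
  memb_som <- as.integer(meta[unit])

  set.seed(seeds[3])
  km <- kmeans(z, centers = min(k, nrow(unique(z))), nstart = 10,
               iter.max = 100)
  list(graph = memb_graph, som = memb_som, kmeans = as.integer(km$cluster),
       k = k)
}

#' Map clusters to phenotypes by signature correlation
#'
#' Each cluster's mean Z-profile over the phenotypic markers is Pearson-
#' correlated with every phenotype signature; the best-correlated phenotype is
#' assigned, provided the correlation reaches the minimum match score —
#' otherwise the cluster is "NOS" (not otherwise specified). Ties go to the
#' earlier signature in the table.
#'
#' @param partition integer cluster membership per cell.
#' @param z cells x markers Z matrix (columns must match the signature
#'   markers).
#' @param signatures tibble with a `phenotype` column and one numeric column
#'   per marker (e.g. from [signatures_from_model()] or [read_signatures()]).
#' @param min_score minimum correlation for assignment; defaults to the
#'   table's `min_score` attribute, else 0.3.
#' @return named character vector: phenotype per cluster id.
#' @export
annotate_clusters <- function(partition, z, signatures, min_score = NULL) {
  min_score <- min_score %||% attr(signatures, "min_score") %||% 0.3
  abort_if(nrow(signatures) < 1, "need at least one signature")
  mk <- colnames(z)
  missing <- setdiff(mk, names(signatures))
  ## signature columns may carry the marker names with or without the _z suffix
  if (length(missing)) {
    stripped <- sub("_z$", "", mk)
    abort_if(!all(stripped %in% names(signatures)),
             "signature table lacks columns for the clustering markers")
    mk <- stripped
  }
  sig <- as.matrix(signatures[, mk, drop = FALSE])
  ids <- sort(unique(partition))
  out <- setNames(character(length(ids)), ids)
  for (i in seq_along(ids)) {
    rows <- partition == ids[i]
    abort_if(!any(rows), "empty cluster in partition")
    centroid <- colMeans(z[rows, , drop = FALSE])
    r <- suppressWarnings(apply(sig, 1, cor, y = centroid))
    r[is.na(r)] <- -Inf
    best <- which.max(r)             # which.max takes the first on ties
    out[i] <- if (r[best] >= min_score) signatures$phenotype[best] else "NOS"
  }
  out
}

#' Consensus phenotype by majority vote over three backends
#'
#' A cell keeps a phenotype if at least two of the three backend annotations
#' agree; cells on which all three disagree become "NOS".
#'
#' @param labels_1,labels_2,labels_3 equal-length phenotype vectors.
#' @return consensus character vector.
#' @export
consensus_vote <- function(labels_1, labels_2, labels_3) {
  abort_if(length(labels_1) != length(labels_2) ||
             length(labels_2) != length(labels_3),
           "label vectors must have equal length")
  out <- rep("NOS", length(labels_1))
  out[labels_1 == labels_2 | labels_1 == labels_3] <-
    labels_1[labels_1 == labels_2 | labels_1 == labels_3]
  only23 <- labels_2 == labels_3 & labels_1 != labels_2
  out[only23] <- labels_2[only23]
  out
}

#' Extrapolate consensus labels to the full dataset
#'
#' Builds a 2-D embedding from a template of at most `n_template` cells per
#' annotated type (UMAP by default; PCA as a fully platform-deterministic
#' fallback), projects every cell into it, and assigns the modal label of the
#' `k_vote` nearest template cells. Ties are broken by the smaller mean
#' distance to the tied labels' voters, then by label order.
#'
#' @param z_ref reference cells x markers Z matrix (annotated subset).
#' @param labels_ref labels of the reference cells.
#' @param z_all matrix of all cells to label (same marker columns).
#' @param n_template template cells per type (default 500).
#' @param k_vote neighbors voting per cell (default 100); reduced with a
#'   warning if the template is smaller.
#' @param method `"umap"` or `"pca"`.
#' @param exclude labels never used as template (default `"NOS"`).
#' @param seed integer seed.
#' @return character vector of labels for the rows of `z_all`.
#' @export
extrapolate_labels <- function(z_ref, labels_ref, z_all, n_template = 500,
                               k_vote = 100, method = c("umap", "pca"),
                               exclude = "NOS", seed = 1L) {
  method <- match.arg(method)
  abort_if(k_vote < 1, "k_vote must be >= 1")
  keep <- !(labels_ref %in% exclude)
  abort_if(!any(keep), "no usable reference labels")
  z_ref <- as.matrix(z_ref)[keep, , drop = FALSE]
  labels_ref <- labels_ref[keep]
  set.seed(as.integer(seed))
  tmpl <- unlist(lapply(split(seq_along(labels_ref), labels_ref), function(ii) {
    if (length(ii) <= n_template) ii else sample(ii, n_template)
  }), use.names = FALSE)
  z_t <- z_ref[tmpl, , drop = FALSE]
  lab_t <- labels_ref[tmpl]
  if (k_vote > length(tmpl)) {
    warning("k_vote reduced to template size (", length(tmpl), ")")
    k_vote <- length(tmpl)
  }
  if (method == "umap" && length(tmpl) > 15) {
    model <- uwot::umap(z_t, n_neighbors = min(15, length(tmpl) - 1),
                        ret_model = TRUE, n_threads = 1, n_sgd_threads = 0)
    emb_t <- model$embedding
    emb_a <- uwot::umap_transform(as.matrix(z_all), model, n_threads = 1)
  } else {
    p <- prcomp(z_t, rank. = min(2, ncol(z_t)))
    emb_t <- p$x
    emb_a <- predict(p, as.matrix(z_all))[, seq_len(ncol(p$x)), drop = FALSE]
  }
  nn <- RANN::nn2(emb_t, emb_a, k = k_vote)
  vote_labels(matrix(lab_t[nn$nn.idx], nrow(emb_a), k_vote), nn$nn.dists)
}

## modal vote with mean-distance then label-order tie-break
vote_labels <- function(lab_mat, dist_mat) {
  levs <- sort(unique(as.vector(lab_mat)))
  n <- nrow(lab_mat)
  counts <- matrix(0L, n, length(levs))
  dsum <- matrix(0, n, length(levs))
  for (j in seq_along(levs)) {
    hit <- lab_mat == levs[j]
    counts[, j] <- rowSums(hit)
    dsum[, j] <- rowSums(dist_mat * hit)
  }
  out <- character(n)
  top <- matrixStats_rowMaxs(counts)
  for (i in seq_len(n)) {
    tied <- which(counts[i, ] == top[i])
    if (length(tied) > 1) {
      md <- dsum[i, tied] / counts[i, tied]
      tied <- tied[order(md, tied)]
    }
    out[i] <- levs[tied[1]]
  }
  out
}

matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' Full consensus phenotyping pipeline
#'
#' Runs the whole chain on a normalized cell table: stratified subsampling,
#' the three clustering backends, signature-based annotation of each backend's
#' clusters, the majority vote, and kNN label extrapolation from a template
#' embedding to every cell.
#'
#' @param cells cell table already passed through [normalize_mfi()].
#' @param markers phenotypic marker names (Z columns `<marker>_z` must exist).
#' @param signatures phenotype signature table (see [annotate_clusters()]).
#' @param subsample_size cells used for clustering (default 50000, capped at
#'   the dataset size).
#' @param k_graph kNN graph neighbors for the graph backend (default 30).
#' @param n_template,k_vote extrapolation template size per type and voting
#'   neighbor count (defaults 500 / 100).
#' @param method embedding method for extrapolation.
#' @param min_score minimum signature correlation (see [annotate_clusters()]).
#' @param label_col name of the output label column (default `"phenotype"`).
#' @param seed integer seed.
#' @return list of class `phenotyping_result`: `cells` (input plus the label
#'   column), `subset` (tibble of the clustered subset with per-backend and
#'   consensus labels), `backends`, `plan`.
#' @export
phenotype_cells <- function(cells, markers, signatures, subsample_size = 50000,
                            k_graph = 30, n_template = 500, k_vote = 100,
                            method = c("umap", "pca"), min_score = NULL,
                            label_col = "phenotype", seed = 1L) {
  method <- match.arg(method)
  seeds <- derive_seeds(seed, 3)
  sub <- stratified_sample(cells, min(subsample_size, nrow(cells)),
                           seed = seeds[1])
  z_sub <- z_matrix(sub$cells, markers)
  bk <- run_backends(z_sub, k_graph = k_graph, seed = seeds[2])
  ann <- lapply(bk[c("graph", "som", "kmeans")], function(memb) {
    map <- annotate_clusters(memb, z_sub, signatures, min_score = min_score)
    unname(map[as.character(memb)])
  })
  cons <- consensus_vote(ann$graph, ann$som, ann$kmeans)
  z_all <- z_matrix(cells, markers)
  full <- extrapolate_labels(z_sub, cons, z_all, n_template = n_template,
                             k_vote = k_vote, method = method, seed = seeds[3])
  out <- cells
  out[[label_col]] <- full
  structure(list(
    cells = out,
    subset = tibble::tibble(cell_id = sub$cells$cell_id,
                            graph = ann$graph, som = ann$som,
                            kmeans = ann$kmeans, consensus = cons),
    backends = bk, plan = sub$plan, label_col = label_col),
    class = "phenotyping_result")
}

#' @export
print.phenotyping_result <- function(x, ...) {
  cat("<phenotyping_result>", nrow(x$cells), "cells,",
      x$backends$k, "clusters from the graph backend\n")
  print(table(x$cells[[x$label_col]]))
  invisible(x)
}

#' Re-cluster the myeloid subset on monocyte markers
#'
#' Cells whose consensus phenotype falls in `parents` (dendritic cells,
#' macrophages and neutrophils by default) are grouped and sent through the
#' same cluster - annotate - vote - extrapolate chain, restricted to the
#' monocyte marker panel. Refined labels land in a separate column; parent
#' labels are preserved.
#'
#' @param cells phenotyped cell table.
#' @param markers the monocyte marker names (13 in the reference panel).
#' @param signatures signatures over those markers for the refined subtypes.
#' @param parents consensus labels defining the myeloid subset.
#' @param label_col column holding the parent labels.
#' @param refined_col output column (default `"refined"`).
#' @param ... passed to [phenotype_cells()] (seed, k_graph, method, ...).
#' @return `cells` with `refined_col` filled for myeloid cells, `NA` elsewhere.
#' @export
subcluster_myeloid <- function(cells, markers, signatures,
                               parents = c("DC", "Macrophage", "Neutrophil"),
                               label_col = "phenotype",
                               refined_col = "refined", ...) {
  missing <- setdiff(paste0(markers, "_z"), names(cells))
  abort_if(length(missing) > 0,
           paste0("monocyte marker columns missing: ",
                  paste(sub("_z$", "", missing), collapse = ", ")))
  sel <- cells[[label_col]] %in% parents
  out <- cells
  out[[refined_col]] <- NA_character_
  if (!any(sel)) {
    warning("no cells with parent labels ", paste(parents, collapse = "/"),
            "; nothing to subcluster")
    return(out)
  }
  res <- phenotype_cells(cells[sel, , drop = FALSE], markers, signatures,
                         label_col = refined_col, ...)
  out[[refined_col]][sel] <- res$cells[[refined_col]]
  out
}
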