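#' Assign each cell to a tissue compartment
#'
#' In-silico microdissection: every cell is tested against the labeled
#' polygons of its sample's compartment map with the fixed precedence
#' glomerular > large vessel > small vessel > tubular; cells inside none are
#' interstitial. Cells outside the field boundary are flagged and left
#' unassigned.
#'
#' @param cells cell table with `sample_id`, `x`, `y`.
#' @param map a [compartment_map()] (or a named list of them, keyed by
#'   sample id, for multi-sample tables).
#' @return `cells` with `compartment` and logical `outside_field` columns.
#' @export
assign_compartments <- function(cells, map) {
  maps <- if (inherits(map, "compartment_map"))
    setNames(list(map), map$sample_id) else map
  out <- cells
  out$compartment <- NA_character_
  out$outside_field <- FALSE
  for (sid in unique(cells$sample_id)) {
    m <- maps[[sid]]
    abort_if(is.null(m), paste0("no compartment map for sample ", sid))
    rows <- which(cells$sample_id == sid)
    x <- cells$x[rows]; y <- cells$y[rows]
    bad <- x < 0 | x > m$width | y < 0 | y > m$height | !is.finite(x) | !is.finite(y)
    out$outside_field[rows[bad]] <- TRUE
    ok <- rows[!bad]
    out$compartment[ok] <- compartment_of_points(cells$x[ok], cells$y[ok], m)
  }
  out
}

#' Compartment composition per sample
#'
#' Percentage of each sample's total cell population contributed by every
#' phenotype x compartment combination — the quantities displayed on
#' compartment radar plots.
#'
#' @param cells cell table with `compartment` and a phenotype column.
#' @param label_col phenotype column name.
#' @return tibble: sample_id, compartment, phenotype, n, pct (of the sample's
#'   total cells).
#' @export
compartment_composition <- function(cells, label_col = "phenotype") {
  cells |>
    dplyr::filter(!is.na(.data$compartment)) |>
    dplyr::count(.data$sample_id, .data$compartment,
                 phenotype = .data[[label_col]], name = "n") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Glomerular versus non-glomerular distribution of each phenotype
#'
#' Per sample and phenotype, the percentage of that phenotype's cells lying
#' inside versus outside glomeruli, plus a two-sided Mann-Whitney test across
#' samples per phenotype (the exact path is used automatically for small n
#' without ties).
#'
#' @param cells cell table with `compartment` and a phenotype column.
#' @param label_col phenotype column name.
#' @return list with `per_sample` (tibble: sample_id, phenotype, n, pct_in,
#'   pct_out) and `tests` (tibble: phenotype, n_samples, statistic, p_value).
#' @export
glomerular_inout <- function(cells, label_col = "phenotype") {
  per <- cells |>
    dplyr::filter(!is.na(.data$compartment)) |>
    dplyr::group_by(.data$sample_id, phenotype = .data[[label_col]]) |>
    dplyr::summarise(n = dplyr::n(),
                     pct_in = 100 * mean(.data$compartment == "glomerular"),
                     pct_out = 100 * mean(.data$compartment != "glomerular"),
                     .groups = "drop")
  empty <- setdiff(unique(cells[[label_col]]), unique(per$phenotype))
  if (length(empty)) warning("phenotypes with no assignable cells excluded: ",
                             paste(empty, collapse = ", "))
  tests <- per |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     statistic = suppressWarnings(
                       wilcox.test(.data$pct_in, .data$pct_out)$statistic),
                     p_value = suppressWarnings(
                       wilcox.test(.data$pct_in, .data$pct_out)$p.value),
                     .groups = "drop")
  list(per_sample = per, tests = tests)
}

#' Distance from each cell to the closest glomerulus
#'
#' Euclidean distance (micrometers) to the nearest glomerular polygon
#' boundary; cells inside a glomerulus get 0.
#'
#' @param cells cell table with `sample_id`, `x`, `y`.
#' @param map a [compartment_map()] or named list of maps keyed by sample id.
#' @return numeric vector of distances, one per cell.
#' @export
distance_to_glomerulus <- function(cells, map) {
  maps <- if (inherits(map, "compartment_map"))
    setNames(list(map), map$sample_id) else map
  out <- rep(NA_real_, nrow(cells))
  for (sid in unique(cells$sample_id)) {
    m <- maps[[sid]]
    abort_if(is.null(m), paste0("no compartment map for sample ", sid))
    rows <- which(cells$sample_id == sid)
    segs <- features_psp(m, "glomerular")
    d <- dist_to_segments(cells$x[rows], cells$y[rows], segs)
    inside <- rep(FALSE, length(rows))
    for (f in map_features(m, "glomerular")) {
      inside <- inside | points_in_feature(cells$x[rows], cells$y[rows], f)
    }
    d[inside] <- 0
    out[rows] <- d
  }
  out
}

#' Cumulative enrichment curve around glomeruli
#'
#' For each requested cell type, the percentage of the total cell population
#' that belongs to that type and lies within distance `x` of the closest
#' glomerulus, evaluated over a distance grid. Pooled groups concatenate their
#' samples before computing, yielding one curve per group.
#'
#' @param cells cell table with a phenotype column.
#' @param dist per-cell distances from [distance_to_glomerulus()].
#' @param types cell types to profile (default all).
#' @param grid distance grid in micrometers.
#' @param group_by optional column to pool samples by (e.g. a diagnostic
#'   group); `NULL` pools everything.
#' @param label_col phenotype column name.
#' @return tibble: group, cell_type, distance, pct. Curves are non-decreasing
#'   in distance and saturate at the type's overall percentage.
#' @export
enrichment_curve <- function(cells, dist, types = NULL, grid = seq(0, 500, 10),
                             group_by = NULL, label_col = "phenotype") {
  abort_if(length(dist) != nrow(cells), "dist must match cells")
  labs <- cells[[label_col]]
  types <- types %||% sort(unique(labs))
  grp <- if (is.null(group_by)) rep("all", nrow(cells)) else cells[[group_by]]
  res <- list()
  for (g in unique(grp)) {
    ing <- grp == g
    total <- sum(ing)
    for (tp in types) {
      sel <- ing & labs == tp
      pct <- vapply(grid, function(x) 100 * sum(sel & dist <= x) / total, 0)
      res[[length(res) + 1]] <- tibble::tibble(group = g, cell_type = tp,
                                               distance = grid, pct = pct)
    }
  }
  dplyr::bind_rows(res)
}

## ordered index pairs (i, j), i != j, with Euclidean distance <= d.
## kd-tree radius search; the radius is padded and the exact distance
## recomputed so the `<= d` comparison is bit-identical to the brute-force
## double loop.
neighbor_pairs <- function(x, y, d) {
  n <- length(x)
  if (n < 2) return(list(i = integer(0), j = integer(0), dist = numeric(0)))
  xy <- cbind(x, y)
  k <- min(n, 64)
  repeat {
    res <- RANN::nn2(xy, xy, k = k, searchtype = "radius", radius = d * 1.001)
    if (k == n || all(res$nn.idx[, k] == 0)) break
    k <- min(n, k * 2)
  }
  idx <- res$nn.idx
  i <- rep(seq_len(n), k)[as.vector(idx) > 0]
  j <- as.vector(idx)[as.vector(idx) > 0]
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  dd <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  keep <- dd <= d
  list(i = i[keep], j = j[keep], dist = dd[keep])
}

#' Count neighboring cell pairs of two types
#'
#' Number of ordered (source, target) pairs of distinct cells at Euclidean
#' distance at most `d`. Computed with a kd-tree radius search but
#' contractually equal to the brute-force double loop. With
#' `ordered = FALSE` each unordered pair is counted once.
#'
#' @param cells cell table with `x`, `y` and a phenotype column.
#' @param d neighborhood radius in micrometers (> 0).
#' @param source,target source and target cell types.
#' @param ordered count ordered pairs (default) or unordered.
#' @param label_col phenotype column name.
#' @return integer count.
#' @export
neighborhood_counts <- function(cells, d, source, target, ordered = TRUE,
                                label_col = "phenotype") {
  abort_if(d <= 0, "d must be > 0")
  labs <- cells[[label_col]]
  pr <- neighbor_pairs(cells$x, cells$y, d)
  hits <- labs[pr$i] == source & labs[pr$j] == target
  n <- sum(hits)
  if (!ordered) {
    n <- if (source == target) n / 2L
         else (n + sum(labs[pr$i] == target & labs[pr$j] == source)) / 2L
  }
  as.integer(n)
}

#' Permutation-null neighborhood enrichment test
#'
#' For each distance on the grid, counts observed (source, target) neighbor
#' pairs, then rebuilds the count under `n_perm` random relabelings that
#' preserve the tissue's cytometry and every cell's coordinates: labels of
#' non-structural cells are permuted within each sample while structural
#' cells (tubular and endothelial types by default) keep their identity. The
#' enrichment p-value uses the add-one estimator
#' `p = (1 + #\{perm >= obs\}) / (n_perm + 1)` (depletion analogous). The
#' signed exceedance statistic is the number of permutations below the
#' observed count when the observation sits above the permutation median, and
#' minus the number above it otherwise.
#'
#' @param cells cell table with `sample_id`, `x`, `y` and a phenotype column.
#' @param source,target cell types tested (must not be structural).
#' @param d distance grid in micrometers (default 10..100 step 10).
#' @param n_perm number of permutations (default 1000).
#' @param structural cell types frozen during randomization.
#' @param ordered ordered or unordered pair counts.
#' @param label_col phenotype column name.
#' @param seed integer seed (split into one stream per sample).
#' @return tibble of class `neighborhood_result`: sample_id, source, target,
#'   d, observed, perm_mean, perm_sd, n_higher, n_lower, n_tied, p_enrich,
#'   p_deplete, signed_exceedance, evaluable.
#' @export
neighborhood_test <- function(cells, source, target, d = seq(10, 100, 10),
                              n_perm = 1000,
                              structural = c("Tubular", "Endothelial"),
                              ordered = TRUE, label_col = "phenotype",
                              seed = 1L) {
  abort_if(any(d <= 0), "distances must be > 0")
  abort_if(n_perm < 1, "n_perm must be >= 1")
  abort_if(source %in% structural || target %in% structural,
           "source/target must not be in the structural (frozen) set")
  samples <- unique(cells$sample_id)
  seeds <- derive_seeds(seed, length(samples))
  d <- sort(d)
  res <- list()
  for (s in seq_along(samples)) {
    sub <- cells[cells$sample_id == samples[s], , drop = FALSE]
    labs <- sub[[label_col]]
    if (!(source %in% labs) || !(target %in% labs)) {
      res[[s]] <- tibble::tibble(sample_id = samples[s], source = source,
                                 target = target, d = d, observed = NA_integer_,
                                 perm_mean = NA_real_, perm_sd = NA_real_,
                                 n_higher = NA_integer_, n_lower = NA_integer_,
                                 n_tied = NA_integer_, p_enrich = NA_real_,
                                 p_deplete = NA_real_,
                                 signed_exceedance = NA_real_,
                                 evaluable = FALSE)
      next
    }
    pr <- neighbor_pairs(sub$x, sub$y, max(d))
    ord <- order(pr$dist)
    pi_ <- pr$i[ord]; pj <- pr$j[ord]; pd <- pr$dist[ord]
    breaks <- findInterval(d, pd)   # pairs 1..breaks[k] are within d[k]
    count_for <- function(lab) {
      hits <- lab[pi_] == source & lab[pj] == target
      if (!ordered) {
        rev_ <- lab[pi_] == target & lab[pj] == source
        hits <- if (source == target) hits else hits | rev_
      }
      cs <- cumsum(hits)
      out <- ifelse(breaks == 0, 0, cs[pmax(breaks, 1)])
      if (!ordered) out <- out / 2
      out
    }
    obs <- count_for(labs)
    free <- which(!(labs %in% structural))
    set.seed(seeds[s])
    perm <- matrix(0, n_perm, length(d))
    lab_r <- labs
    for (r in seq_len(n_perm)) {
      lab_r[free] <- labs[free][sample.int(length(free))]
      perm[r, ] <- count_for(lab_r)
    }
    n_higher <- colSums(perm > rep(obs, each = n_perm))
    n_lower <- colSums(perm < rep(obs, each = n_perm))
    n_tied <- n_perm - n_higher - n_lower
    p_enr <- (1 + n_higher + n_tied) / (n_perm + 1)
    p_dep <- (1 + n_lower + n_tied) / (n_perm + 1)
    med <- apply(perm, 2, median)
    signed <- ifelse(obs > med, n_lower, -n_higher)
    res[[s]] <- tibble::tibble(sample_id = samples[s], source = source,
                               target = target, d = d,
                               observed = as.integer(round(obs)),
                               perm_mean = colMeans(perm),
                               perm_sd = apply(perm, 2, sd),
                               n_higher = as.integer(n_higher),
                               n_lower = as.integer(n_lower),
                               n_tied = as.integer(n_tied),
                               p_enrich = p_enr, p_deplete = p_dep,
                               signed_exceedance = signed, evaluable = TRUE)
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("neighborhood_result", class(out))
  out
}
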