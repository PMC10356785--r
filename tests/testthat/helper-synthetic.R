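## Shared fixture builders and independent brute-force oracles. Oracles are
## deliberately naive (double loops, all-edges scans) and never call the code
## paths they check.

## cell table with block-separated marker intensities and known phenotypes,
## spread over samples and regions with batch effects
make_marker_cells <- function(n_cells, n_types = 5, separation = 5,
                              n_samples = 2, n_regions = 2, n_markers = 20,
                              seed = 1L) {
  types <- paste0("P", seq_len(n_types))
  model <- block_marker_model(types,
                              markers = sprintf("M%02d", seq_len(n_markers)),
                              separation = separation)
  set.seed(seed)
  samples <- paste0("S", seq_len(n_samples))
  sid <- sample(samples, n_cells, replace = TRUE)
  region <- paste0(sid, "_R", sample(n_regions, n_cells, replace = TRUE))
  ## per-region batch effects the normalization must absorb
  regs <- unique(region)
  model$region_gain <- setNames(runif(length(regs), 0.8, 1.3), regs)
  model$region_shift <- setNames(runif(length(regs), 0, 3), regs)
  cells <- tibble::tibble(
    cell_id = paste0("c", seq_len(n_cells)),
    sample_id = sid, region_id = region,
    x = runif(n_cells, 0, 1000), y = runif(n_cells, 0, 1000),
    nuclear_size = rlnorm(n_cells, log(35), 0.25),
    phenotype_true = sample(types, n_cells, replace = TRUE)
  )
  cells <- simulate_markers(cells, model, seed = seed + 1)
  markers <- colnames(model$log_mean)
  cells <- normalize_mfi(cells, markers)
  list(cells = cells, markers = markers, model = model,
       signatures = signatures_from_model(model))
}

## deterministic 6-cell toy matrix with known QC violations; genes 1..100 are
## mitochondrial. Expected survivors: cells 2, 3 and 6.
qc_toy <- function() {
  n_genes <- 10050
  genes <- sprintf("G%05d", seq_len(n_genes))
  genes[1:100] <- paste0("MT-", 1:100)
  m <- matrix(0, n_genes, 6, dimnames = list(genes, paste0("cell", 1:6)))
  m[101:499, 1] <- 1    # 399 detected genes -> excluded (< 400)
  m[1:100, 2] <- 1      # 100 mito counts ...
  m[101:400, 2] <- 1    # ... + 300 others: 400 genes, mito 25.0% -> kept
  m[101:2100, 3] <- 2   # ordinary cell -> kept
  m[1:10001, 4] <- 1    # 10001 detected genes -> excluded (> 10000)
  m[1:100, 5] <- 3      # 300 mito counts ...
  m[101:800, 5] <- 1    # ... + 700 others: mito 30% -> excluded
  m[101:2100, 6] <- 1   # ordinary cell -> kept
  m
}

## O(n^2) neighbor-count oracle
bf_neighborhood_counts <- function(cells, d, source, target,
                                   label_col = "phenotype") {
  x <- cells$x; y <- cells$y; lab <- cells[[label_col]]
  dm <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  diag(dm) <- Inf
  sum(dm <= d & outer(lab == source, lab == target))
}

## all-edges point-to-segment distance oracle
bf_dist_to_segments <- function(px, py, segs) {
  out <- rep(Inf, length(px))
  for (k in seq_along(segs$x0)) {
    vx <- segs$x1[k] - segs$x0[k]; vy <- segs$y1[k] - segs$y0[k]
    l2 <- vx^2 + vy^2
    t <- ((px - segs$x0[k]) * vx + (py - segs$y0[k]) * vy) / l2
    t <- pmax(0, pmin(1, t))
    dd <- sqrt((segs$x0[k] + t * vx - px)^2 + (segs$y0[k] + t * vy - py)^2)
    out <- pmin(out, dd)
  }
  out
}

bf_dist_to_glomerulus <- function(cells, map) {
  segs <- graftscape:::features_psp(map, "glomerular")
  d <- bf_dist_to_segments(cells$x, cells$y, segs)
  inside <- rep(FALSE, nrow(cells))
  for (f in graftscape:::map_features(map, "glomerular")) {
    inside <- inside | graftscape:::points_in_feature(cells$x, cells$y, f)
  }
  d[inside] <- 0
  d
}
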