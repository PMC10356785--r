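## a tiny handmade map used across tests: one glomerulus disc, one tubule
## overlapping it, one vessel rectangle
tiny_map <- function() {
  g <- graftscape:::disc_polygon(500, 500, 50)
  t1 <- graftscape:::disc_polygon(540, 500, 60, n_vertices = 48)
  v <- graftscape:::rect_polygon(100, 100, 40, 200)
  compartment_map("S1", 1000, 1000, list(
    list(label = "glomerular", x = g$x, y = g$y),
    list(label = "tubular", x = t1$x, y = t1$y),
    list(label = "large_vessel", x = v$x, y = v$y)))
}

test_that("compartment assignment follows the precedence rule", {
  map <- tiny_map()
  cells <- tibble::tibble(
    cell_id = as.character(1:5), sample_id = "S1",
    x = c(500, 540, 120, 900, 1500),
    y = c(500, 500, 150, 900, 500))
  out <- assign_compartments(cells, map)
  ## disc center; glomerulus+tubule overlap resolves to glomerular;
  ## vessel; none -> interstitial; outside the field -> flagged
  expect_equal(out$compartment[1:4],
               c("glomerular", "glomerular", "large_vessel", "interstitial"))
  expect_true(out$outside_field[5])
  expect_true(is.na(out$compartment[5]))
  ## a point in the tubule but not the glomerulus
  out2 <- assign_compartments(
    tibble::tibble(cell_id = "t", sample_id = "S1", x = 595, y = 500), map)
  expect_equal(out2$compartment, "tubular")
})

test_that("compartment composition partitions each phenotype's share", {
  fx <- simulate_tissue(tissue_spec(n_cells = 2000, seed = 9))
  cells <- assign_compartments(fx$cells, fx$map)
  cells$phenotype <- cells$phenotype_true
  comp <- compartment_composition(cells)
  ## summing a phenotype over compartments gives its overall percentage
  tot <- comp |> dplyr::group_by(sample_id, phenotype) |>
    dplyr::summarise(pct = sum(pct), .groups = "drop")
  overall <- cells |> dplyr::count(sample_id, phenotype) |>
    dplyr::group_by(sample_id) |>
    dplyr::mutate(pct = 100 * n / sum(n)) |> dplyr::ungroup()
  m <- merge(tot, overall, by = c("sample_id", "phenotype"))
  expect_equal(m$pct.x, m$pct.y)
  expect_equal(sum(comp$pct), 100)
  ## single-phenotype sample attributes every compartment share to it
  solo <- cells; solo$phenotype <- "only"
  comp1 <- compartment_composition(solo)
  expect_equal(sum(comp1$pct), 100)
  expect_true(all(comp1$phenotype == "only"))
})

test_that("glomerular enrichment shows up in compartment composition", {
  spec <- tissue_spec(n_cells = 6000, seed = 23, n_glomeruli = 8,
                      abundance = c(NK = 0.3, Tcell = 0.7),
                      tubule_fraction = 0, n_small_vessels = 0,
                      n_large_vessels = 0,
                      compartment_odds = list(NK = c(glomerular = 5)))
  ts <- simulate_tissue(spec)
  cells <- assign_compartments(ts$cells, ts$map)
  cells$phenotype <- cells$phenotype_true
  glom_area <- sum(vapply(graftscape:::map_features(ts$map, "glomerular"),
                          function(f) abs(graftscape:::polygon_area(f$x, f$y)), 0))
  a <- glom_area / (spec$width * spec$height)
  comp <- compartment_composition(cells)
  nk_glom <- comp$pct[comp$phenotype == "NK" & comp$compartment == "glomerular"]
  nk_total <- sum(comp$pct[comp$phenotype == "NK"])
  expect_gt(nk_glom / nk_total, 1.5 * a)   # well above the area expectation
})

test_that("glomerular in/out percentages behave at the extremes", {
  cells <- tibble::tibble(
    cell_id = as.character(1:8),
    sample_id = rep(c("S1", "S2"), each = 4),
    compartment = c("glomerular", "glomerular", "tubular", "interstitial",
                    "glomerular", "glomerular", "tubular", "interstitial"),
    phenotype = c("NK", "NK", "T", "T", "NK", "NK", "T", "T"))
  res <- glomerular_inout(cells)
  nk <- res$per_sample[res$per_sample$phenotype == "NK", ]
  expect_equal(nk$pct_in, c(100, 100))
  expect_equal(nk$pct_out, c(0, 0))
  expect_true(all(c("statistic", "p_value") %in% names(res$tests)))
})

test_that("distance to glomerulus matches geometry and the all-edges oracle", {
  map <- tiny_map()
  cells <- tibble::tibble(cell_id = c("in", "out"), sample_id = "S1",
                          x = c(500, 580), y = c(500, 500))
  d <- distance_to_glomerulus(cells, map)
  expect_equal(d[1], 0)
  expect_equal(d[2], 30, tolerance = 0.05)  # 96-gon boundary within 0.03 um
  ## random cells against the brute-force oracle
  set.seed(11)
  pts <- tibble::tibble(cell_id = as.character(1:300), sample_id = "S1",
                        x = runif(300, 0, 1000), y = runif(300, 0, 1000))
  fast <- distance_to_glomerulus(pts, map)
  slow <- bf_dist_to_glomerulus(pts, map)
  expect_lt(max(abs(fast - slow)), 1e-9)
})

test_that("enrichment curves are monotone and saturate at the type fraction", {
  ts <- simulate_tissue(tissue_spec(n_cells = 1500, seed = 13))
  cells <- ts$cells
  cells$phenotype <- cells$phenotype_true
  d <- distance_to_glomerulus(cells, ts$map)
  grid <- seq(0, 1600, 50)   # beyond the field diagonal at the top end
  cur <- enrichment_curve(cells, d, types = "NK", grid = grid)
  expect_true(all(diff(cur$pct) >= 0))
  expect_equal(max(cur$pct), 100 * mean(cells$phenotype == "NK"))
  ## planted glomerular enrichment is near its plateau at x = 0
  spec <- tissue_spec(n_cells = 4000, seed = 29, n_glomeruli = 8,
                      abundance = c(NK = 0.2, Tcell = 0.8),
                      tubule_fraction = 0, n_small_vessels = 0,
                      n_large_vessels = 0,
                      compartment_odds = list(NK = c(glomerular = 50)))
  ts2 <- simulate_tissue(spec)
  c2 <- ts2$cells; c2$phenotype <- c2$phenotype_true
  d2 <- distance_to_glomerulus(c2, ts2$map)
  cur2 <- enrichment_curve(c2, d2, types = "NK", grid = c(0, 2000))
  expect_gt(cur2$pct[1] / cur2$pct[2], 0.5)
})

test_that("neighborhood counts match hand cases and the O(n^2) oracle", {
  two <- tibble::tibble(cell_id = c("a", "b"), sample_id = "S",
                        x = c(0, 5), y = c(0, 0), phenotype = c("A", "B"))
  expect_equal(neighborhood_counts(two, 10, "A", "B"), 1L)
  expect_equal(neighborhood_counts(two, 4, "A", "B"), 0L)
  set.seed(19)
  cells <- tibble::tibble(cell_id = as.character(1:200), sample_id = "S",
                          x = runif(200, 0, 300), y = runif(200, 0, 300),
                          phenotype = sample(c("A", "B", "C"), 200, TRUE))
  for (d in seq(10, 100, 10)) {
    expect_identical(neighborhood_counts(cells, d, "A", "B"),
                     bf_neighborhood_counts(cells, d, "A", "B"))
  }
  ## unordered counts halve symmetric ordered counts
  expect_equal(neighborhood_counts(cells, 50, "A", "B", ordered = FALSE) +
                 neighborhood_counts(cells, 50, "B", "A", ordered = FALSE),
               neighborhood_counts(cells, 50, "A", "B") +
                 neighborhood_counts(cells, 50, "B", "A"))
})

test_that("permutation partition and degenerate-label invariants hold", {
  ts <- simulate_tissue(tissue_spec(n_cells = 600, seed = 31))
  cells <- ts$cells; cells$phenotype <- cells$phenotype_true
  res <- neighborhood_test(cells, "NK", "Tcell", d = c(20, 40), n_perm = 50,
                           seed = 3)
  expect_true(all(res$n_higher + res$n_lower + res$n_tied == 50))
  expect_true(all(res$p_enrich > 0 & res$p_enrich <= 1))
  ## all non-structural cells sharing one label makes the statistic invariant
  mono <- cells
  mono$phenotype[!(mono$phenotype %in% c("Tubular", "Endothelial"))] <- "A"
  res1 <- neighborhood_test(mono, "A", "A", d = 30, n_perm = 25, seed = 4)
  expect_equal(res1$p_enrich, 1)
  expect_equal(res1$p_deplete, 1)
  ## absent source type flags the result non-evaluable
  res2 <- neighborhood_test(cells, "NK", "Tcell", d = 30, n_perm = 10, seed = 5)
  missing <- cells[cells$phenotype != "NK", ]
  res3 <- neighborhood_test(missing, "NK", "Tcell", d = 30, n_perm = 10, seed = 5)
  expect_false(res3$evaluable[1])
  expect_true(res2$evaluable[1])
  expect_error(neighborhood_test(cells, "Tubular", "NK"), "structural")
})

test_that("frozen structural cells leave the immune-label null unchanged", {
  ## tiny instance: enumerate every arrangement of the immune labels and
  ## compare the exact null of the count with the sampled permutation null
  set.seed(8)
  n_imm <- 6
  cells <- tibble::tibble(
    cell_id = as.character(1:9), sample_id = "S",
    x = runif(9, 0, 40), y = runif(9, 0, 40),
    phenotype = c("A", "A", "B", "B", "C", "C", "Tubular", "Tubular",
                  "Endothelial"))
  perms <- graftscape:::all_permutations(n_imm)
  labs <- cells$phenotype
  exact <- apply(perms, 1, function(pp) {
    relab <- labs
    relab[1:n_imm] <- labs[1:n_imm][pp]
    c2 <- cells; c2$phenotype <- relab
    bf_neighborhood_counts(c2, 20, "A", "B")
  })
  res <- neighborhood_test(cells, "A", "B", d = 20, n_perm = 400, seed = 21)
  ## sampled permutation mean within Monte-Carlo error of the exact mean,
  ## and the sampled support inside the exact support
  expect_lt(abs(res$perm_mean - mean(exact)), 4 * sd(exact) / sqrt(400))
  obs <- bf_neighborhood_counts(cells, 20, "A", "B")
  expect_equal(res$observed, obs)
  p_exact <- (1 + sum(exact >= obs) * 400 / length(exact)) / 401
  expect_lt(abs(res$p_enrich - p_exact), 0.1)
})

test_that("planted co-localization is detected as enrichment", {
  spec <- tissue_spec(n_cells = 1500, seed = 41, colocalization = list(
    list(attractor = "Macrophage", attracted = "NK", sigma = 15,
         fraction = 0.6)))
  ts <- simulate_tissue(spec)
  cells <- ts$cells; cells$phenotype <- cells$phenotype_true
  res <- neighborhood_test(cells, "NK", "Macrophage", d = c(20, 30, 40),
                           n_perm = 200, seed = 6)
  expect_true(all(res$p_enrich <= 0.05))
  expect_true(all(res$signed_exceedance > 0))
})
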