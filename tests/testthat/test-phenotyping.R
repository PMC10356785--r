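test_that("normalization matches hand-computed Z-scores and the trim rule", {
  cells <- tibble::tibble(cell_id = as.character(1:3), sample_id = "S",
                          region_id = "R1", M1 = c(8, 10, 12))
  out <- normalize_mfi(cells, "M1")
  expect_equal(out$M1_z, c(0, 0, 1))          # -1 and 0 trimmed up to 0
  ## an extreme outlier exceeds the upper trim bound and is stored as 5
  many <- tibble::tibble(cell_id = as.character(1:41), sample_id = "S",
                         region_id = "R1", M1 = c(rep(10, 40), 1e5))
  z <- normalize_mfi(many, "M1")$M1_z
  expect_equal(max(z), 5)
  expect_equal(min(z), 0)
})

test_that("degenerate regions yield Z = 0", {
  cells <- tibble::tibble(cell_id = as.character(1:5), sample_id = "S",
                          region_id = c("R1", "R1", "R1", "R1", "R2"),
                          M1 = c(4, 4, 4, 4, 9))
  expect_warning(out <- normalize_mfi(cells, "M1"), "single cell")
  expect_equal(out$M1_z, rep(0, 5))
  expect_error(normalize_mfi(cells, "M9"), "missing marker")
})

test_that("pre-trim Z-scores have mean 0 and sd 1 per region and marker", {
  fx <- make_marker_cells(600, n_types = 3, n_markers = 6, seed = 12)
  for (rg in unique(fx$cells$region_id)) {
    rows <- fx$cells$region_id == rg
    for (mk in fx$markers) {
      v <- fx$cells[[mk]][rows]
      z <- (v - mean(v)) / sd(v)
      expect_lt(abs(mean(z)), 1e-9)
      expect_lt(abs(sd(z) - 1), 1e-9)
      stored <- fx$cells[[paste0(mk, "_z")]][rows]
      expect_true(all(stored >= 0 & stored <= 5))
      expect_equal(stored, pmin(pmax(z, 0), 5))
    }
  }
})

test_that("stratified sampling follows the proportional quota formula", {
  cells <- tibble::tibble(cell_id = as.character(1:100000),
                          sample_id = rep(c("A", "B"), c(60000, 40000)))
  plan <- stratified_sample(cells, 50000, seed = 1)$plan
  expect_equal(plan$size_i, c(30000, 20000))
  ## largest-remainder rounding with index-order tie-break
  cells2 <- tibble::tibble(cell_id = as.character(1:10),
                           sample_id = rep(c("A", "B", "C"), c(3, 3, 4)))
  res2 <- stratified_sample(cells2, 5, seed = 2)
  expect_equal(res2$plan$quota, c(1.5, 1.5, 2))
  expect_equal(res2$plan$size_i, c(2, 1, 2))
  ## S = M returns the whole dataset
  res3 <- stratified_sample(cells2, 10, seed = 3)
  expect_identical(res3$cells, cells2)
  expect_error(stratified_sample(cells2, 11), "exceeds")
})

test_that("stratified quotas are exact and within 1 of the real quota", {
  set.seed(42)
  for (rep in 1:50) {
    p <- sample(2:8, 1)
    n_i <- sample(5:200, p, replace = TRUE)
    cells <- tibble::tibble(
      cell_id = as.character(seq_len(sum(n_i))),
      sample_id = rep(paste0("S", seq_len(p)), n_i))
    s <- sample.int(sum(n_i), 1)
    res <- stratified_sample(cells, s, seed = rep)
    expect_identical(sum(res$plan$size_i), s)
    expect_true(all(abs(res$plan$size_i - res$plan$quota) < 1))
    expect_equal(nrow(res$cells), s)
  }
})

test_that("consensus vote implements the two-of-three rule", {
  expect_equal(consensus_vote("Tcell", "Tcell", "NK"), "Tcell")
  expect_equal(consensus_vote("A", "B", "C"), "NOS")
  expect_equal(consensus_vote("A", "A", "A"), "A")
  expect_error(consensus_vote(c("A", "B"), "A", "A"), "equal length")
})

test_that("consensus vote is permutation-invariant in its arguments", {
  set.seed(7)
  l <- replicate(3, sample(c("A", "B", "C", "D"), 40, replace = TRUE),
                 simplify = FALSE)
  ref <- consensus_vote(l[[1]], l[[2]], l[[3]])
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pp in perms) {
    expect_identical(consensus_vote(l[[pp[1]]], l[[pp[2]]], l[[pp[3]]]), ref)
  }
})

test_that("cluster annotation assigns by correlation with NOS fallback", {
  sig <- tibble::tibble(phenotype = c("A", "B"),
                        M1 = c(3, 0), M2 = c(0, 3), M3 = c(1, 1))
  z <- rbind(matrix(rep(c(3, 0, 1), 10), 10, byrow = TRUE),
             matrix(rep(c(0, 3, 1), 10), 10, byrow = TRUE))
  colnames(z) <- c("M1", "M2", "M3")
  part <- rep(1:2, each = 10)
  expect_equal(unname(annotate_clusters(part, z, sig)), c("A", "B"))
  ## centroid uncorrelated with every signature falls back to NOS
  z_bad <- matrix(rep(c(1, 1, 1), 10), 10, byrow = TRUE,
                  dimnames = list(NULL, c("M1", "M2", "M3")))
  expect_equal(unname(annotate_clusters(rep(1, 10), z_bad, sig)), "NOS")
  ## duplicated signatures: first in table order wins
  sig2 <- tibble::tibble(phenotype = c("first", "second"),
                         M1 = c(3, 3), M2 = c(0, 0), M3 = c(1, 1))
  expect_equal(unname(annotate_clusters(part, z, sig2)[1]), "first")
})

test_that("backends recover two well-separated blobs up to refinement", {
  set.seed(21)
  n <- 200
  ## blob 1 high on markers 3-4, blob 2 high on markers 1-2, 10 sd apart
  z <- rbind(cbind(matrix(rnorm(n * 2, 0, 1), n, 2),
                   matrix(rnorm(n * 2, 10, 1), n, 2)),
             cbind(matrix(rnorm(n * 2, 10, 1), n, 2),
                   matrix(rnorm(n * 2, 0, 1), n, 2)))
  colnames(z) <- paste0("M", 1:4)
  truth <- rep(1:2, each = n)
  bk <- run_backends(z, k_graph = 30, seed = 5)
  for (part in bk[c("graph", "som", "kmeans")]) {
    ## every cluster must lie entirely inside one blob (pure refinement)
    purity <- vapply(split(truth, part),
                     function(tt) max(table(tt)) / length(tt), 0)
    expect_true(all(purity == 1))
  }
  ## annotation collapses the refinement back to exactly the two phenotypes
  sig <- tibble::tibble(phenotype = c("lo", "hi"),
                        M1 = c(0, 3), M2 = c(0, 3), M3 = c(3, 0), M4 = c(3, 0))
  lab <- unname(annotate_clusters(bk$graph, z, sig)[as.character(bk$graph)])
  expect_equal(lab, rep(c("lo", "hi"), each = n))
  ## determinism
  bk2 <- run_backends(z, k_graph = 30, seed = 5)
  expect_identical(bk, bk2)
  ## forcing k = 1 collapses backends 2-3 to one cluster
  bk1 <- run_backends(z, k_graph = 30, k = 1, seed = 5)
  expect_equal(length(unique(bk1$som)), 1)
  expect_equal(length(unique(bk1$kmeans)), 1)
})

test_that("label extrapolation handles degenerate templates and separable data", {
  set.seed(3)
  z <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("M1", "M2")))
  ## single-type template labels everything with that type
  expect_equal(unique(extrapolate_labels(z, rep("only", 30), z, k_vote = 5,
                                         method = "pca", seed = 1)), "only")
  ## k_vote = 1 returns a template cell its own label
  z3 <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2),
              matrix(rnorm(40, -8), 20, 2))
  colnames(z3) <- c("M1", "M2")
  lab3 <- rep(c("a", "b", "c"), each = 20)
  self <- extrapolate_labels(z3, lab3, z3, k_vote = 1, method = "pca", seed = 2)
  expect_identical(self, lab3)
  ## well-separated blobs: >= 99% agreement with ground truth
  set.seed(9)
  big <- rbind(matrix(rnorm(600, 0), 300, 2), matrix(rnorm(600, 10), 300, 2),
               matrix(rnorm(600, -10), 300, 2))
  colnames(big) <- c("M1", "M2")
  truth <- rep(c("a", "b", "c"), each = 300)
  ref_idx <- sort(sample(900, 450))
  out <- extrapolate_labels(big[ref_idx, ], truth[ref_idx], big,
                            n_template = 120, k_vote = 20, seed = 4)
  expect_gte(mean(out == truth), 0.99)
  ## oversized k_vote is reduced with a warning
  expect_warning(extrapolate_labels(z3, lab3, z3, k_vote = 500,
                                    method = "pca", seed = 5), "reduced")
})

test_that("myeloid subclustering refines only the parent subset", {
  fx <- make_marker_cells(1200, n_types = 3, n_markers = 8, seed = 31)
  ## rename blocks so the first two types are myeloid parents
  cells <- fx$cells
  cells$phenotype <- c(P1 = "Macrophage", P2 = "DC",
                       P3 = "Tcell")[cells$phenotype_true]
  sig <- fx$signatures
  sig$phenotype <- c("Mono_classical", "Mono_nonclassical", "other")
  res <- subcluster_myeloid(cells, fx$markers, sig,
                            parents = c("Macrophage", "DC"),
                            subsample_size = 500, method = "pca", seed = 2)
  myeloid <- cells$phenotype %in% c("Macrophage", "DC")
  expect_true(all(is.na(res$refined[!myeloid])))
  expect_true(all(!is.na(res$refined[myeloid])))
  expect_identical(res$phenotype, cells$phenotype)   # parents preserved
  ## the two myeloid ground-truth blocks separate into two refined labels
  tab <- table(res$refined[myeloid], cells$phenotype_true[myeloid])
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.95)
  expect_error(subcluster_myeloid(cells, c(fx$markers, "CD999"), sig),
               "CD999")
  expect_warning(subcluster_myeloid(cells, fx$markers, sig,
                                    parents = "Neutrophil"), "nothing")
})

test_that("full phenotyping chain recovers separable synthetic labels", {
  fx <- make_marker_cells(3000, n_types = 4, separation = 5, seed = 77)
  res <- phenotype_cells(fx$cells, fx$markers, fx$signatures,
                         subsample_size = 1200, seed = 5)
  ## signatures carry the simulator's names P1..P4
  acc <- mean(res$cells$phenotype == res$cells$phenotype_true)
  expect_gte(acc, 0.95)
  ## same seed reproduces the result
  res2 <- phenotype_cells(fx$cells, fx$markers, fx$signatures,
                          subsample_size = 1200, seed = 5)
  expect_identical(res$cells$phenotype, res2$cells$phenotype)
})
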