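#' Specify a synthetic biopsy tissue
#'
#' Describes one simulated multiplex-IF field: its geometry (glomeruli, large
#' and small vessels, tubular mask; the interstitium is the complement), the
#' cell population to scatter over it, per-phenotype compartment preferences,
#' and optional pairwise co-localization effects. All lengths are micrometers
#' in image coordinates (origin top-left, y downward).
#'
#' @param sample_id sample identifier.
#' @param width,height field size in micrometers.
#' @param n_cells number of cells to place.
#' @param abundance named numeric vector of phenotype abundances; must sum to 1.
#' @param n_glomeruli number of non-overlapping glomerular discs.
#' @param glom_radius_mean,glom_radius_sd glomerulus radius distribution (um).
#' @param large_vessels list of `c(x0, y0, w, h)` rectangles; `NULL` places
#'   `n_large_vessels` random rectangles.
#' @param n_large_vessels,large_vessel_size rectangle count and `c(w, h)` used
#'   when `large_vessels` is `NULL`.
#' @param n_small_vessels,small_vessel_radius small-vessel disc count/radius.
#' @param tubule_fraction target fraction of the field covered by the tubular
#'   mask (achieved approximately by a Boolean union of discs).
#' @param tubule_radius radius of the tubular discs (um).
#' @param compartment_odds named list mapping phenotype to a named numeric
#'   vector of odds multipliers over compartments (missing entries default
#'   to 1). Odds `o` for compartment `c` make a cell of that phenotype `o`
#'   times more likely, per unit area, to sit in `c` than in a neutral
#'   compartment.
#' @param colocalization list of co-localization effects, each
#'   `list(attractor =, attracted =, sigma =, fraction =)`: `fraction` of the
#'   attracted phenotype's cells are moved to a random attractor cell plus an
#'   isotropic Gaussian displacement of scale `sigma` (um).
#' @param n_regions number of imaging regions (vertical strips) the field is
#'   split into; regions carry independent staining batch effects.
#' @param seed integer seed.
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(sample_id = "S1", width = 1000, height = 1000,
                        n_cells = 1500,
                        abundance = c(Tcell = 0.25, NK = 0.15, Macrophage = 0.20,
                                      Tubular = 0.30, Endothelial = 0.10),
                        n_glomeruli = 6, glom_radius_mean = 60, glom_radius_sd = 8,
                        large_vessels = NULL, n_large_vessels = 2,
                        large_vessel_size = c(60, 250),
                        n_small_vessels = 8, small_vessel_radius = 15,
                        tubule_fraction = 0.35, tubule_radius = 40,
                        compartment_odds = list(), colocalization = list(),
                        n_regions = 2, seed = 1L) {
  abort_if(abs(sum(abundance) - 1) > 1e-8, "abundance vector must sum to 1")
  abort_if(is.null(names(abundance)) || any(!nzchar(names(abundance))),
           "abundance must be a named vector")
  abort_if(any(abundance < 0), "abundances must be >= 0")
  for (v in c(width, height, glom_radius_mean, tubule_radius, small_vessel_radius))
    abort_if(!is_scalar_number(v) || v <= 0, "geometric parameters must be > 0")
  abort_if(tubule_fraction < 0 || tubule_fraction >= 1,
           "tubule_fraction must be in [0, 1)")
  for (cl in colocalization) {
    abort_if(!all(c("attractor", "attracted", "sigma", "fraction") %in% names(cl)),
             "colocalization effect needs attractor/attracted/sigma/fraction")
    abort_if(cl$sigma <= 0, "colocalization sigma must be > 0")
    abort_if(cl$fraction < 0 || cl$fraction > 1, "fraction must be in [0, 1]")
    abort_if(!all(c(cl$attractor, cl$attracted) %in% names(abundance)),
             "colocalization phenotypes must appear in abundance")
  }
  for (ph in names(compartment_odds)) {
    abort_if(!ph %in% names(abundance), paste0("odds for unknown phenotype ", ph))
    abort_if(any(compartment_odds[[ph]] < 0), "compartment odds must be >= 0")
  }
  structure(as.list(environment()), class = "tissue_spec")
}

## draw the labeled geometry for one spec (consumes the current RNG stream)
build_geometry <- function(spec) {
  feats <- list()
  ## non-overlapping glomerular discs, kept away from the field edge
  centers <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (nrow(centers) < spec$n_glomeruli && tries < 5000) {
    tries <- tries + 1
    r <- max(5, rnorm(1, spec$glom_radius_mean, spec$glom_radius_sd))
    cx <- runif(1, r, spec$width - r); cy <- runif(1, r, spec$height - r)
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
            centers[, 3] + r + 10)) {
      centers <- rbind(centers, c(cx, cy, r))
      d <- disc_polygon(cx, cy, r)
      feats[[length(feats) + 1]] <- list(label = "glomerular", x = d$x, y = d$y)
    }
  }
  ## large vessels: given rectangles or random ones
  rects <- spec$large_vessels
  if (is.null(rects) && spec$n_large_vessels > 0) {
    rects <- replicate(spec$n_large_vessels, {
      w <- spec$large_vessel_size[1]; h <- spec$large_vessel_size[2]
      if (runif(1) < 0.5) { tmp <- w; w <- h; h <- tmp }
      c(runif(1, 0, spec$width - w), runif(1, 0, spec$height - h), w, h)
    }, simplify = FALSE)
  }
  for (rc in rects %||% list()) {
    p <- rect_polygon(rc[1], rc[2], rc[3], rc[4])
    feats[[length(feats) + 1]] <- list(label = "large_vessel", x = p$x, y = p$y)
  }
  for (i in seq_len(spec$n_small_vessels)) {
    r <- spec$small_vessel_radius
    d <- disc_polygon(runif(1, r, spec$width - r), runif(1, r, spec$height - r),
                      r, n_vertices = 32)
    feats[[length(feats) + 1]] <- list(label = "small_vessel", x = d$x, y = d$y)
  }
  map <- compartment_map(spec$sample_id, spec$width, spec$height, feats)
  ## tubular mask: add discs until a Monte-Carlo estimate of the covered area
  ## reaches the target. The base (non-tubular) compartment of the probe grid
  ## is computed once; each candidate disc then only needs a circle test.
  if (spec$tubule_fraction > 0) {
    gx <- runif(4000, 0, spec$width); gy <- runif(4000, 0, spec$height)
    base <- compartment_of_points(gx, gy, map)
    open <- base == "interstitial"
    covered <- rep(FALSE, length(gx))
    r <- spec$tubule_radius
    for (i in seq_len(1000)) {
      if (mean(covered) >= spec$tubule_fraction) break
      cx <- runif(1, 0, spec$width); cy <- runif(1, 0, spec$height)
      covered <- covered | (open & (gx - cx)^2 + (gy - cy)^2 <= r^2)
      d <- disc_polygon(cx, cy, r, n_vertices = 32)
      map$features[[length(map$features) + 1]] <-
        list(label = "tubular", x = d$x, y = d$y)
    }
  }
  map
}

#' Simulate a tissue: geometry plus cell positions with known phenotypes
#'
#' Cells are placed by rejection sampling: a uniform candidate position is
#' accepted with probability proportional to the phenotype's odds multiplier
#' for the compartment it falls in, so an odds of `o` yields an inside/outside
#' odds ratio of exactly `o` relative to the compartment's area fraction.
#' Co-localization effects then move a stated fraction of the attracted
#' phenotype next to random attractor cells (isotropic Gaussian displacement).
#'
#' @param spec a [tissue_spec()].
#' @return list with `cells` (tibble: cell_id, sample_id, region_id, x, y,
#'   nuclear_size, phenotype_true), `map` (a `compartment_map`).
#' @export
simulate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  seeds <- derive_seeds(spec$seed, 3)
  set.seed(seeds[1])
  map <- build_geometry(spec)

  set.seed(seeds[2])
  n_by_ph <- drop(stats::rmultinom(1, spec$n_cells, spec$abundance))
  names(n_by_ph) <- names(spec$abundance)
  xs <- ys <- numeric(0); phs <- character(0)
  for (ph in names(n_by_ph)) {
    need <- n_by_ph[[ph]]
    if (need == 0) next
    odds <- rep(1, length(COMPARTMENT_LEVELS))
    names(odds) <- COMPARTMENT_LEVELS
    user <- spec$compartment_odds[[ph]]
    if (!is.null(user)) odds[names(user)] <- user
    got_x <- got_y <- numeric(0)
    guard <- 0
    neutral <- all(odds == odds[1])   # uniform placement needs no rejection
    while (length(got_x) < need && guard < 200) {
      guard <- guard + 1
      m <- max(32, 2 * (need - length(got_x)))
      px <- runif(m, 0, spec$width); py <- runif(m, 0, spec$height)
      keep <- if (neutral) rep(TRUE, m) else {
        comp <- compartment_of_points(px, py, map)
        runif(m) < odds[comp] / max(odds)
      }
      got_x <- c(got_x, px[keep]); got_y <- c(got_y, py[keep])
    }
    abort_if(length(got_x) < need,
             paste0("could not place cells for ", ph,
                    " (all compartment odds zero?)"))
    xs <- c(xs, got_x[seq_len(need)]); ys <- c(ys, got_y[seq_len(need)])
    phs <- c(phs, rep(ph, need))
  }

  set.seed(seeds[3])
  for (cl in spec$colocalization) {
    anchors <- which(phs == cl$attractor)
    movers <- which(phs == cl$attracted)
    if (!length(anchors) || !length(movers)) next
    n_mv <- round(cl$fraction * length(movers))
    if (n_mv == 0) next
    mv <- sample(movers, n_mv)
    to <- sample(anchors, n_mv, replace = TRUE)
    xs[mv] <- pmin(pmax(xs[to] + rnorm(n_mv, 0, cl$sigma), 0), spec$width)
    ys[mv] <- pmin(pmax(ys[to] + rnorm(n_mv, 0, cl$sigma), 0), spec$height)
  }

  region <- paste0(spec$sample_id, "_R",
                   pmin(spec$n_regions,
                        1 + floor(xs / spec$width * spec$n_regions)))
  cells <- tibble::tibble(
    cell_id = paste0(spec$sample_id, "_c", seq_along(xs)),
    sample_id = spec$sample_id,
    region_id = region,
    x = xs, y = ys,
    nuclear_size = rlnorm(length(xs), log(35), 0.25),
    phenotype_true = phs
  )
  list(cells = cells, map = map)
}

#' Specify the marker-intensity model
#'
#' Per phenotype x marker log-normal mean fluorescence intensities, with
#' per-region batch effects (a multiplicative gain and an additive shift) and
#' additive Gaussian background noise — the structure the per-region Z-score
#' normalization is designed to remove.
#'
#' @param log_mean phenotype x marker matrix of log-intensity means (dimnames
#'   required).
#' @param log_sd scalar or matrix of log-intensity standard deviations (> 0).
#' @param region_gain,region_shift named numeric vectors keyed by region id;
#'   regions not listed get gain 1 / shift 0.
#' @param noise_sd additive background noise sd (>= 0).
#' @return object of class `marker_model`.
#' @export
marker_model <- function(log_mean, log_sd = 0.3, region_gain = numeric(0),
                         region_shift = numeric(0), noise_sd = 0.05) {
  abort_if(is.null(rownames(log_mean)) || is.null(colnames(log_mean)),
           "log_mean needs phenotype rownames and marker colnames")
  if (length(log_sd) == 1) {
    log_sd <- matrix(log_sd, nrow(log_mean), ncol(log_mean),
                     dimnames = dimnames(log_mean))
  }
  abort_if(any(log_sd <= 0), "log_sd must be > 0")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 region_gain = region_gain, region_shift = region_shift,
                 noise_sd = noise_sd),
            class = "marker_model")
}

#' Simulate raw marker intensities for placed cells
#'
#' `MFI = exp(N(mu, sd)) * gain(region) + shift(region) + N(0, noise_sd)`,
#' floored at zero.
#'
#' @param cells cell table with `phenotype_true` and `region_id`.
#' @param model a [marker_model()].
#' @param seed integer seed.
#' @return `cells` with one raw-MFI column per marker appended.
#' @export
simulate_markers <- function(cells, model, seed = 1L) {
  stopifnot(inherits(model, "marker_model"))
  unknown <- setdiff(unique(cells$phenotype_true), rownames(model$log_mean))
  abort_if(length(unknown) > 0,
           paste0("phenotypes missing from marker model: ",
                  paste(unknown, collapse = ", ")))
  set.seed(as.integer(seed))
  n <- nrow(cells)
  idx <- match(cells$phenotype_true, rownames(model$log_mean))
  gain <- model$region_gain[cells$region_id]; gain[is.na(gain)] <- 1
  shift <- model$region_shift[cells$region_id]; shift[is.na(shift)] <- 0
  out <- cells
  for (mk in colnames(model$log_mean)) {
    mu <- model$log_mean[idx, mk]; sdv <- model$log_sd[idx, mk]
    raw <- exp(rnorm(n, mu, sdv)) * unname(gain) + unname(shift)
    if (model$noise_sd > 0) raw <- raw + rnorm(n, 0, model$noise_sd)
    out[[mk]] <- unname(pmax(raw, 0))
  }
  out
}

#' Block-structured marker model with guaranteed phenotype separation
#'
#' Assigns each phenotype a dedicated block of markers whose log-mean sits
#' `separation` standard deviations above the background log-mean, the
#' situation the consensus phenotyping pipeline assumes when its accuracy is
#' benchmarked.
#'
#' @param phenotypes character vector of phenotype names.
#' @param markers character vector of marker names (default a 20-marker IF
#'   panel naming convention, `M01..M20`).
#' @param separation centroid separation in units of `log_sd`.
#' @param log_sd within-phenotype log-intensity sd.
#' @param base log-mean of a marker in phenotypes that do not express it.
#' @param ... passed to [marker_model()] (region effects, noise).
#' @return a [marker_model()].
#' @export
block_marker_model <- function(phenotypes,
                               markers = sprintf("M%02d", seq_len(20)),
                               separation = 5, log_sd = 0.3, base = 1, ...) {
  abort_if(length(markers) < length(phenotypes),
           "need at least one marker per phenotype")
  lm <- matrix(base, length(phenotypes), length(markers),
               dimnames = list(phenotypes, markers))
  blocks <- split(seq_along(markers),
                  rep(seq_along(phenotypes), length.out = length(markers)))
  for (i in seq_along(phenotypes)) {
    lm[i, blocks[[i]]] <- base + separation * log_sd
  }
  marker_model(lm, log_sd = log_sd, ...)
}

#' Expected Z-profile signatures for a marker model
#'
#' Converts a marker model into the numeric phenotype signatures the automated
#' cluster annotation correlates cluster centroids against: per marker, the
#' phenotype log-means standardized across phenotypes, with negatives floored
#' at zero to mirror the `[0, 5]` trimming of the observed Z-scores.
#'
#' @param model a [marker_model()].
#' @param min_score minimum Pearson correlation stored alongside the profiles.
#' @return tibble with `phenotype` and one column per marker, plus a
#'   `min_score` attribute; ready for [annotate_clusters()].
#' @export
signatures_from_model <- function(model, min_score = 0.3) {
  lm <- model$log_mean
  z <- scale(lm)
  z[is.nan(z)] <- 0
  z <- pmax(z, 0)
  out <- tibble::as_tibble(as.data.frame(z), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(phenotype = rownames(lm)), out)
  attr(out, "min_score") <- min_score
  out
}
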