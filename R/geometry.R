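## Polygon plumbing shared by the tissue simulator and the spatial module.
## A compartment map stores labeled simple polygons in image coordinates
## (micrometers, origin top-left, y increasing downward). The interstitium is
## never stored: it is the complement of the labeled compartments.

COMPARTMENT_LEVELS <- c("glomerular", "large_vessel", "small_vessel",
                        "tubular", "interstitial")

#' Create a compartment map
#'
#' @param sample_id sample identifier.
#' @param width,height field-of-view size in micrometers.
#' @param features list of features, each a `list(label =, x =, y =)` with
#'   `label` one of `"glomerular"`, `"large_vessel"`, `"small_vessel"`,
#'   `"tubular"` and `x`, `y` the polygon ring vertices (open ring, i.e. the
#'   first vertex is not repeated at the end).
#' @return an object of class `compartment_map`.
#' @export
compartment_map <- function(sample_id, width, height, features = list()) {
  abort_if(!is_scalar_number(width) || width <= 0, "field width must be > 0")
  abort_if(!is_scalar_number(height) || height <= 0, "field height must be > 0")
  for (f in features) {
    abort_if(!all(c("label", "x", "y") %in% names(f)), "feature needs label/x/y")
    abort_if(!f$label %in% setdiff(COMPARTMENT_LEVELS, "interstitial"),
             paste0("unknown compartment label: ", f$label))
    abort_if(length(f$x) < 3 || length(f$x) != length(f$y),
             "polygon needs >= 3 vertices with equal-length x/y")
    abort_if(abs(polygon_area(f$x, f$y)) <= 0, "zero-area compartment polygon")
  }
  structure(list(sample_id = sample_id, width = width, height = height,
                 features = features),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  labs <- vapply(x$features, `[[`, "", "label")
  cat("<compartment_map> sample", x$sample_id,
      sprintf("(%g x %g um)\n", x$width, x$height))
  if (length(labs)) print(table(labs)) else cat("  no labeled polygons\n")
  invisible(x)
}

## signed area (shoelace); positive for counterclockwise rings in standard axes
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

## regular polygon approximating a disc; 96 vertices keeps the boundary within
## ~0.05 um of the true circle for glomerulus-sized radii
disc_polygon <- function(cx, cy, r, n_vertices = 96) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

rect_polygon <- function(x0, y0, w, h) {
  list(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
}

## counterclockwise orientation as required by spatstat.geom::owin
as_owin_poly <- function(f) {
  x <- f$x; y <- f$y
  if (polygon_area(x, y) < 0) { x <- rev(x); y <- rev(y) }
  spatstat.geom::owin(poly = list(x = x, y = y))
}

## which of the points fall inside (boundary included) feature f; bounding-box
## prefilter keeps the owin query cheap when polygons are small
points_in_feature <- function(x, y, f) {
  hit <- x >= min(f$x) & x <= max(f$x) & y >= min(f$y) & y <= max(f$y)
  if (!any(hit)) return(hit)
  w <- as_owin_poly(f)
  hit[hit] <- spatstat.geom::inside.owin(x[hit], y[hit], w)
  hit
}

map_features <- function(map, label) {
  Filter(function(f) f$label == label, map$features)
}

## compartment of each point under the fixed precedence rule
compartment_of_points <- function(x, y, map,
                                  precedence = c("glomerular", "large_vessel",
                                                 "small_vessel", "tubular")) {
  comp <- rep(NA_character_, length(x))
  for (lab in precedence) {
    open <- is.na(comp)
    if (!any(open)) break
    for (f in map_features(map, lab)) {
      open_idx <- which(is.na(comp))
      if (!length(open_idx)) break
      ins <- points_in_feature(x[open_idx], y[open_idx], f)
      comp[open_idx[ins]] <- lab
    }
  }
  comp[is.na(comp)] <- "interstitial"
  comp
}

## all polygon edges of the features with the given label, as a psp object
features_psp <- function(map, label, pad = 1) {
  feats <- map_features(map, label)
  abort_if(!length(feats), paste0("map has no ", label, " features"))
  x0 <- y0 <- x1 <- y1 <- numeric(0)
  for (f in feats) {
    nx <- c(f$x[-1], f$x[1]); ny <- c(f$y[-1], f$y[1])
    x0 <- c(x0, f$x); y0 <- c(y0, f$y); x1 <- c(x1, nx); y1 <- c(y1, ny)
  }
  list(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

## minimum distance from each point to any segment in segs (list of x0..y1)
dist_to_segments <- function(x, y, segs) {
  xr <- range(c(x, segs$x0, segs$x1)); yr <- range(c(y, segs$y0, segs$y1))
  W <- spatstat.geom::owin(xr + c(-1, 1), yr + c(-1, 1))
  P <- spatstat.geom::ppp(x, y, window = W, check = FALSE)
  S <- spatstat.geom::psp(segs$x0, segs$y0, segs$x1, segs$y1,
                          window = W, check = FALSE)
  spatstat.geom::nncross(P, S)$dist
}
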