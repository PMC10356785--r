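#' Read and write cell tables
#'
#' Cell tables travel as plain CSV, one row per segmented cell. Core columns:
#' `cell_id`, `sample_id`, `region_id`, `x`, `y` (micrometers, image
#' convention), `nuclear_size`, one raw-MFI column per marker, and whatever
#' label columns downstream stages have added (`<marker>_z`, `phenotype`,
#' `refined`, `compartment`).
#'
#' @param cells cell table.
#' @param path file path.
#' @return `read_cell_table` returns a tibble; `write_cell_table` returns
#'   `path` invisibly.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells, path)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a compartment map as GeoJSON
#'
#' One Feature per labeled polygon with a `compartment` property; the field
#' boundary travels in the FeatureCollection's `properties` together with the
#' sample id. Coordinates are micrometers in image convention.
#'
#' @param map a [compartment_map()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_compartment_geojson <- function(map, path) {
  features <- lapply(map$features, function(f) {
    ring <- cbind(f$x, f$y)
    ring <- rbind(ring, ring[1, ])           # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(compartment = f$label),
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, as.list,
                                                  simplify = FALSE))))
  })
  fc <- list(type = "FeatureCollection",
             properties = list(sample_id = map$sample_id,
                               width = map$width, height = map$height),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_compartment_geojson
#' @export
read_compartment_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  feats <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    x <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    y <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    n <- length(x)
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
    list(label = f$properties$compartment, x = x, y = y)
  })
  compartment_map(fc$properties$sample_id, fc$properties$width,
                  fc$properties$height, feats)
}

#' Write and read sparse counts as MatrixMarket MTX plus TSV annotations
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (`matrix.mtx`, `genes.tsv`, `cells.tsv`).
#' @param labels optional cell-type label per cell, stored in `cells.tsv`.
#' @return `write_counts_mtx` returns `dir` invisibly; `read_counts_mtx`
#'   returns a list with `counts` and `labels` (NULL when absent).
#' @export
write_counts_mtx <- function(counts, dir, labels = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = rownames(counts)),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  cells <- tibble::tibble(cell = colnames(counts))
  if (!is.null(labels)) cells$label <- labels
  readr::write_tsv(cells, file.path(dir, "cells.tsv"), col_names = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  dimnames(counts) <- list(genes[[1]], cells[[1]])
  list(counts = counts,
       labels = if (ncol(cells) > 1) cells[[2]] else NULL)
}

#' Read and write phenotype signature tables
#'
#' TSV with a `phenotype` column and one numeric column per marker; an
#' optional `min_score` attribute rides along as a commented header line.
#'
#' @param signatures signature tibble (see [annotate_clusters()]).
#' @param path file path.
#' @return tibble (read) or `path` invisibly (write).
#' @export
write_signatures <- function(signatures, path) {
  readr::write_tsv(signatures, path)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
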