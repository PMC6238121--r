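# Population-level usage raster from individual core areas, candidate-site
# delineation at a population threshold (PT), and the inclusion metric used
# to validate parameter choices.

#' Fraction-of-individuals usage raster
#'
#' Overlays one core area per bird on the shared lattice: each cell's value
#' is the number of birds whose core area covers the cell divided by the
#' number of birds.
#'
#' @param core_areas list of [core_area()] objects (one per bird, equal grid
#'   resolution).
#' @return an object of class `usage_raster`: `cells` (integer matrix over
#'   the union of cores), `value` (fraction per cell), `n_individuals`,
#'   `res`.
#' @export
usage_raster <- function(core_areas) {
  stopifnot(length(core_areas) >= 1,
            all(vapply(core_areas, inherits, TRUE, "core_area")))
  res <- core_areas[[1]]$res
  if (!all(vapply(core_areas, function(c) c$res, 0) == res))
    stop("core areas must share one grid resolution")
  keys <- unlist(lapply(core_areas, function(c) unique(.cell_key(c$cells))))
  tab <- table(keys)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  cells <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
  structure(list(cells = cells,
                 value = as.vector(tab) / length(core_areas),
                 n_individuals = length(core_areas), res = res),
            class = "usage_raster")
}

#' @export
print.usage_raster <- function(x, ...) {
  cat(sprintf("<usage_raster> %d birds, %d cells @ %g km, max fraction %.2f\n",
              x$n_individuals, nrow(x$cells), x$res, max(x$value)))
  invisible(x)
}

#' Delineate a candidate mIBA site at a population threshold
#'
#' Cells used by at least `pt` percent of the tracked individuals qualify
#' (inclusive, so PT = 20 with exactly one bird in five qualifies);
#' 4-connected qualifying cells are merged into polygons with holes
#' preserved. An empty site is allowed and reported with area 0.
#'
#' @param raster a [usage_raster()].
#' @param pt population threshold, percent. The protocol uses 10, 12.5 or 20
#'   depending on sample representativeness (20 is the precautionary value);
#'   other values are accepted with a warning.
#' @param provenance optional named list recorded with the site (dataset id,
#'   h, UD% used).
#' @return an object of class `candidate_site` with `cells`, `rings`,
#'   `area_km2`, `pt` and `provenance`.
#' @export
delineate <- function(raster, pt, provenance = list()) {
  stopifnot(inherits(raster, "usage_raster"), pt > 0, pt <= 100)
  if (!pt %in% c(10, 12.5, 20))
    warning("PT = ", pt, "% is outside the protocol set {10, 12.5, 20}")
  keep <- raster$value >= pt / 100 - 1e-12
  cells <- raster$cells[keep, , drop = FALSE]
  structure(list(cells = cells, res = raster$res,
                 rings = cells_to_rings(cells, raster$res),
                 area_km2 = nrow(cells) * raster$res^2,
                 pt = pt, n_individuals = raster$n_individuals,
                 provenance = provenance),
            class = "candidate_site")
}

#' @export
print.candidate_site <- function(x, ...) {
  cat(sprintf("<candidate_site> PT %g%%: %g km2 (%d cells, %d rings)\n",
              x$pt, x$area_km2, nrow(x$cells), length(x$rings)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               unlist(x$provenance), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Inclusion of validation positions in a candidate site
#'
#' Percentage of positions falling inside the site (positions on the site
#' boundary count as inside). This is the protocol's quality metric for a
#' parameter combination.
#'
#' @param site a [delineate()] result (or merged site with `cells`/`res`).
#' @param positions data frame or matrix with `x`, `y` columns (km).
#' @return percentage in \[0, 100\].
#' @export
inclusion <- function(site, positions) {
  x <- if (is.matrix(positions)) positions[, 1] else positions$x
  y <- if (is.matrix(positions)) positions[, 2] else positions$y
  if (length(x) == 0) stop("empty validation set")
  if (nrow(site$cells) == 0) return(0)
  100 * mean(.points_in_cells(x, y, site$cells, site$res))
}
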