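# Grid geometry. All rasters share one implicit global lattice: at resolution
# `res`, cell (i, j) is the square of side `res` centred at (i*res, j*res) km
# in the colony plane. Rasters from different datasets of the same colony are
# therefore always aligned, and unions/overlays reduce to integer set
# operations. Polygon rings are traced along cell edges: outer rings
# counter-clockwise, holes clockwise, 4-connected components kept separate.

.cell_key <- function(cells) paste(cells[, 1], cells[, 2])

#' Trace boundary polygons of a set of grid cells
#'
#' @param cells two-column integer matrix of cell indices (i, j).
#' @param res cell size (km).
#' @return list of rings; each ring is a closed two-column matrix of x/y
#'   vertices (km). Counter-clockwise rings are outer boundaries, clockwise
#'   rings are holes.
#' @keywords internal
cells_to_rings <- function(cells, res) {
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2)
  if (nrow(cells) == 0) return(list())
  inset <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(cells))) assign(.cell_key(cells[k, , drop = FALSE]), TRUE, inset)
  has <- function(i, j) !is.null(inset[[paste(i, j)]])

  # directed boundary edges with the interior on the left, vertices on the
  # doubled lattice (corner (2i+1, 2j+1) etc.) so keys are integers
  from <- character(0); e_from <- list(); e_to <- list()
  add_edge <- function(a, b) {
    from <<- c(from, paste(a, collapse = " "))
    e_from[[length(e_from) + 1]] <<- a
    e_to[[length(e_to) + 1]] <<- b
  }
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    sw <- c(2 * i - 1, 2 * j - 1); se <- c(2 * i + 1, 2 * j - 1)
    ne <- c(2 * i + 1, 2 * j + 1); nw <- c(2 * i - 1, 2 * j + 1)
    if (!has(i, j - 1)) add_edge(sw, se)   # south edge, heading east
    if (!has(i + 1, j)) add_edge(se, ne)   # east edge, heading north
    if (!has(i, j + 1)) add_edge(ne, nw)   # north edge, heading west
    if (!has(i - 1, j)) add_edge(nw, sw)   # west edge, heading south
  }
  n_e <- length(e_from)
  used <- logical(n_e)
  by_start <- split(seq_len(n_e), from)

  rings <- list()
  for (start in seq_len(n_e)) {
    if (used[start]) next
    ring <- list(e_from[[start]])
    cur <- start
    repeat {
      used[cur] <- TRUE
      v <- e_to[[cur]]
      ring[[length(ring) + 1]] <- v
      cand <- by_start[[paste(v, collapse = " ")]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) == 1) cur <- cand[1]
      else {
        # checkerboard corner: prefer the left turn so that diagonally
        # touching cells stay in separate (4-connected) rings
        d <- e_from[[cur]]; dir <- v - d
        left <- c(-dir[2], dir[1])
        nxt <- vapply(cand, function(e) {
          out <- e_to[[e]] - e_from[[e]]
          sum(out * left)
        }, 0)
        cur <- cand[which.max(nxt)]
      }
    }
    rings[[length(rings) + 1]] <-
      do.call(rbind, ring) * (res / 2)
  }
  lapply(rings, function(r) { colnames(r) <- c("x", "y"); r })
}

# signed (shoelace) area of a closed ring; positive = counter-clockwise
.ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Even-odd point-in-polygon test over a list of rings
#'
#' Points exactly on a ring edge count as inside.
#'
#' @param x,y point coordinates (km).
#' @param rings list of closed rings as returned by [cells_to_rings()].
#' @return logical vector.
#' @keywords internal
point_in_rings <- function(x, y, rings) {
  inside <- logical(length(x))
  for (r in rings) {
    rx <- r[, 1]; ry <- r[, 2]; n <- nrow(r)
    for (p in seq_along(x)) {
      px <- x[p]; py <- y[p]
      cross <- FALSE
      on_edge <- FALSE
      for (k in seq_len(n - 1)) {
        x1 <- rx[k]; y1 <- ry[k]; x2 <- rx[k + 1]; y2 <- ry[k + 1]
        # on-segment check (axis-aligned edges)
        if (abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) < 1e-9 &&
            px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
            py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) {
          on_edge <- TRUE; break
        }
        if ((y1 > py) != (y2 > py) &&
            px < x1 + (py - y1) * (x2 - x1) / (y2 - y1)) cross <- !cross
      }
      if (on_edge) inside[p] <- TRUE
      else if (cross) inside[p] <- !inside[p]
    }
  }
  inside
}

# cells (up to 4) of the global lattice whose closed square contains a point
.cells_containing <- function(x, y, res) {
  u <- x / res; v <- y / res
  ic <- floor(u + 0.5); jc <- floor(v + 0.5)
  out <- list(cbind(ic, jc))
  on_i <- abs(u - (ic - 0.5)) < 1e-9
  on_j <- abs(v - (jc - 0.5)) < 1e-9
  if (any(on_i)) out[[length(out) + 1]] <- cbind(ifelse(on_i, ic - 1, ic), jc)
  if (any(on_j)) out[[length(out) + 1]] <- cbind(ic, ifelse(on_j, jc - 1, jc))
  if (any(on_i & on_j)) out[[length(out) + 1]] <-
      cbind(ifelse(on_i, ic - 1, ic), ifelse(on_j, jc - 1, jc))
  out
}

# membership of points in a cell set (closed squares; edge points inside)
.points_in_cells <- function(x, y, cells, res) {
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_len(nrow(cells))) assign(.cell_key(cells[k, , drop = FALSE]), TRUE, keys)
  hit <- logical(length(x))
  for (cand in .cells_containing(x, y, res)) {
    kk <- paste(cand[, 1], cand[, 2])
    for (p in seq_along(x))
      if (!hit[p] && !is.null(keys[[kk[p]]])) hit[p] <- TRUE
  }
  hit
}

#' Export grid polygons as GeoJSON (WGS84)
#'
#' Converts a `core_area` or `candidate_site` (or merged site) back to
#' longitude/latitude via the inverse colony projection and writes a GeoJSON
#' `Feature` with a `MultiPolygon` geometry; clockwise rings are attached as
#' holes of the outer ring containing them.
#'
#' @param x an object with `rings` (km, colony plane) and `area_km2`.
#' @param colony the [colony()] the plane is centred on.
#' @param path output file.
#' @param properties named list of extra feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, colony, path, properties = list()) {
  rings <- x$rings
  if (!length(rings)) {
    gj <- list(type = "Feature", properties = c(list(area_km2 = 0), properties),
               geometry = list(type = "MultiPolygon", coordinates = list()))
  } else {
    sa <- vapply(rings, .ring_signed_area, 0)
    outers <- which(sa > 0); holes <- which(sa <= 0)
    polys <- lapply(outers, function(o) list(rings[[o]]))
    for (h in holes) {
      v <- rings[[h]][1, ]
      owner <- which(vapply(outers, function(o)
        point_in_rings(v[1], v[2], rings[o]), TRUE))[1]
      if (!is.na(owner)) polys[[owner]] <- c(polys[[owner]], rings[h])
    }
    coords <- lapply(polys, function(p) lapply(p, function(r) {
      ll <- plane_to_lonlat(r[, 1], r[, 2], colony$lon, colony$lat)
      lapply(seq_len(nrow(ll)), function(i) c(ll[i, 1], ll[i, 2]))
    }))
    gj <- list(type = "Feature",
               properties = c(list(area_km2 = x$area_km2), properties),
               geometry = list(type = "MultiPolygon", coordinates = coords))
  }
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
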