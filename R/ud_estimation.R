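# Per-individual kernel utilization distributions on the shared colony grid,
# UD% core areas as superlevel sets of sorted cell masses, and the
# first-passage-time (area-restricted-search) scale used to benchmark fixed
# kernel bandwidths.

#' Kernel utilization distribution of one bird
#'
#' Bivariate Gaussian kernel density of the interpolated positions with fixed
#' isotropic bandwidth `h_km`, evaluated on the global lattice (cell centres
#' at integer multiples of `resolution_km`) padded at least `3 h` beyond the
#' data extent, then normalized so cell sums times cell area equal 1.
#'
#' @param track an `interp_track` (or any data frame with `x`, `y` in km).
#' @param h_km kernel smoothing bandwidth (km, > 0). The protocol's optimum
#'   for Pygoscelis penguins is about 7 km.
#' @param resolution_km grid cell size (km), default 1.
#' @param pad_factor grid padding in multiples of `h_km` (>= 3).
#' @return an object of class `ud_surface`: integer cell index vectors `ix`,
#'   `iy`, normalized density matrix `z` (length(ix) x length(iy)), the raw
#'   discrete integral `norm`, and provenance fields.
#' @export
estimate_ud <- function(track, h_km, resolution_km = 1, pad_factor = 3) {
  x <- track$x; y <- track$y
  stopifnot(length(x) >= 1, is.finite(h_km), h_km > 0, resolution_km > 0,
            pad_factor >= 3)
  res <- resolution_km
  pad <- pad_factor * h_km
  ix <- seq.int(floor((min(x) - pad) / res), ceiling((max(x) + pad) / res))
  iy <- seq.int(floor((min(y) - pad) / res), ceiling((max(y) + pad) / res))
  gx <- ix * res; gy <- iy * res
  n <- length(x)
  A <- exp(-outer(gx, x, "-")^2 / (2 * h_km^2))
  B <- exp(-outer(gy, y, "-")^2 / (2 * h_km^2))
  raw <- (A %*% t(B)) / (n * 2 * pi * h_km^2)
  norm <- sum(raw) * res^2
  structure(list(ix = ix, iy = iy, res = res, z = raw / norm, norm = norm,
                 h_km = h_km, n_positions = n,
                 bird_id = attr(track, "bird_id") %||% track$bird_id[1] %||% NA),
            class = "ud_surface")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ud_surface <- function(x, ...) {
  cat(sprintf("<ud_surface> bird %s: %d x %d cells @ %g km, h = %g km\n",
              x$bird_id, length(x$ix), length(x$iy), x$res, x$h_km))
  invisible(x)
}

# exact Gaussian-mixture density of positions (xs, ys) at points (px, py);
# equals surface$z * surface$norm on grid nodes
.kde_at <- function(xs, ys, px, py, h) {
  vapply(seq_along(px), function(k)
    mean(exp(-((xs - px[k])^2 + (ys - py[k])^2) / (2 * h^2))) / (2 * pi * h^2),
    0)
}

#' Core-use area of a utilization distribution
#'
#' Finds the superlevel set holding the smallest density mass at least
#' `ud_percent` percent of the total: cell masses are sorted in decreasing
#' order (ties broken by cell index, so the result is deterministic) and
#' accumulated until the target mass is reached. The selected cells are
#' polygonized into 4-connected boundary rings with holes preserved.
#'
#' @param surface a [estimate_ud()] result.
#' @param ud_percent percentage of the density mass to enclose, in (0, 100).
#'   50 is the classic foraging core; values up to 80 suit wide-ranging
#'   incubation trips.
#' @return an object of class `core_area`: integer `cells`, `res`, `rings`,
#'   `area_km2`, `enclosed_mass` (percent) and `threshold` (density at the
#'   last included cell).
#' @export
core_area <- function(surface, ud_percent) {
  stopifnot(inherits(surface, "ud_surface"),
            ud_percent > 0, ud_percent < 100)
  res <- surface$res
  m <- as.vector(surface$z) * res^2
  ord <- order(-m, seq_along(m))
  cum <- cumsum(m[ord])
  k <- which(cum >= ud_percent / 100)[1]
  if (is.na(k)) k <- length(m)
  sel <- ord[seq_len(k)]
  ij <- arrayInd(sel, dim(surface$z))
  cells <- cbind(surface$ix[ij[, 1]], surface$iy[ij[, 2]])
  structure(list(cells = cells, res = res,
                 rings = cells_to_rings(cells, res),
                 area_km2 = k * res^2,
                 ud_percent = ud_percent,
                 enclosed_mass = 100 * cum[k],
                 threshold = m[ord[k]] / res^2,
                 bird_id = surface$bird_id),
            class = "core_area")
}

#' @export
print.core_area <- function(x, ...) {
  cat(sprintf("<core_area> bird %s: UD%g%% -> %g km2 (%d cells, %d rings)\n",
              x$bird_id, x$ud_percent, x$area_km2, nrow(x$cells),
              length(x$rings)))
  invisible(x)
}

# first passage times through circles of radius r centred on every position
# of one track; returns the variance of log(FPT) per radius
.fpt_log_var <- function(track, radii) {
  x <- track$x; y <- track$y; t <- track$t_h
  n <- length(x)
  half <- function(ord) {
    # ord: index order walking away from each focal point
    out <- matrix(NA_real_, n, length(radii))
    for (p in seq_len(n)) {
      idx <- if (ord == "fwd") p:n else p:1
      if (length(idx) < 2) next
      d <- sqrt((x[idx] - x[p])^2 + (y[idx] - y[p])^2)
      dmax <- cummax(d)
      tt <- abs(t[idx] - t[p])
      cnt <- findInterval(radii, dmax)         # last index with dmax <= r
      k <- cnt + 1
      ok <- k <= length(idx) & cnt >= 1
      if (!any(ok)) next
      kk <- k[ok]
      d0 <- d[kk - 1]; d1 <- d[kk]
      frac <- pmin(1, pmax(0, (radii[ok] - d0) / pmax(d1 - d0, 1e-12)))
      out[p, ok] <- tt[kk - 1] + frac * (tt[kk] - tt[kk - 1])
    }
    out
  }
  fpt <- half("fwd") + half("bwd")
  apply(fpt, 2, function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 5) return(NA_real_)
    stats::var(log(v))
  })
}

#' First-passage-time foraging scale of a dataset
#'
#' For each bird, first passage time (time to cross a circle of radius `r`
#' centred on each position, forward plus backward along the track) is
#' computed at every radius; the bird's area-restricted-search scale is the
#' radius maximizing the variance of log FPT. The dataset scale is the
#' median over birds (the median, rather than the mean, resists the skewed
#' per-bird scales typical of penguin data).
#'
#' @param tracks list of `interp_track` objects.
#' @param radii_km radii grid (km), default 1-20 km in 1-km steps.
#' @return an object of class `ars_scale`: `scale_km` (dataset median),
#'   `per_bird` (named vector, `NA` where the log-FPT variance profile is
#'   flat or undefined) and the `var_profile` matrix (bird x radius).
#' @export
ars_scale <- function(tracks, radii_km = 1:20) {
  stopifnot(length(tracks) >= 1, all(radii_km > 0))
  vp <- t(vapply(tracks, .fpt_log_var, numeric(length(radii_km)),
                 radii = radii_km))
  per_bird <- apply(vp, 1, function(v) {
    if (all(!is.finite(v)) || max(v, na.rm = TRUE) <= 1e-12) return(NA_real_)
    radii_km[which.max(v)]
  })
  names(per_bird) <- vapply(tracks, function(t) attr(t, "bird_id") %||% "?", "")
  if (all(is.na(per_bird)))
    stop("ARS scale undefined: no track crosses any radius with variable FPT")
  structure(list(scale_km = stats::median(per_bird, na.rm = TRUE),
                 per_bird = per_bird, var_profile = vp, radii_km = radii_km),
            class = "ars_scale")
}

#' @export
print.ars_scale <- function(x, ...) {
  cat(sprintf("<ars_scale> median ARS scale %.2f km over %d birds (%d undefined)\n",
              x$scale_km, length(x$per_bird), sum(is.na(x$per_bird))))
  invisible(x)
}
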