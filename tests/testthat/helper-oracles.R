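# Shared fixtures and independent oracles, all built in code.

# independent joint-Gaussian log-likelihood of the integrated-OU model for
# one axis: assembles the full state covariance and evaluates the marginal
# normal density of the observations directly (no Kalman recursion)
oracle_ctcrw_ll <- function(z, tau2, times, beta, sigma2, v_pos) {
  n <- length(times)
  phi_f <- function(dt) {
    e <- 1 - exp(-beta * dt)
    matrix(c(1, 0, e / beta, exp(-beta * dt)), 2, 2)
  }
  q_f <- function(dt) {
    e <- 1 - exp(-beta * dt); e2 <- 1 - exp(-2 * beta * dt)
    qxx <- sigma2 / beta^2 * (dt - 2 * e / beta + e2 / (2 * beta))
    qxv <- sigma2 / (2 * beta^2) * e^2
    qvv <- sigma2 / (2 * beta) * e2
    matrix(c(qxx, qxv, qxv, qvv), 2, 2)
  }
  M <- numeric(2 * n); S <- matrix(0, 2 * n, 2 * n)
  M[1:2] <- c(z[1], 0)
  S[1:2, 1:2] <- diag(c(v_pos, sigma2 / (2 * beta)))
  for (k in 2:n) {
    dt <- times[k] - times[k - 1]
    Phi <- phi_f(dt)
    ia <- (2 * k - 3):(2 * k - 2); ib <- (2 * k - 1):(2 * k)
    M[ib] <- Phi %*% M[ia]
    S[ib, ib] <- Phi %*% S[ia, ia] %*% t(Phi) + q_f(dt)
    for (j in 1:(k - 1)) {
      ja <- (2 * j - 1):(2 * j)
      S[ib, ja] <- Phi %*% S[ia, ja]
      S[ja, ib] <- t(S[ib, ja])
    }
  }
  pos <- seq(1, 2 * n, by = 2)
  mu <- M[pos]; V <- S[pos, pos] + diag(tau2)
  L <- chol(V)
  r <- backsolve(L, z - mu, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# build a projected track data frame directly from plane coordinates
make_track <- function(x, y, t_h, bird = "b1", loc_class = "G") {
  data.frame(bird_id = bird,
             timestamp = as.POSIXct("2020-01-01", tz = "UTC") + t_h * 3600,
             lon = NA_real_, lat = NA_real_,
             loc_class = loc_class, x = x, y = y,
             stringsAsFactors = FALSE)
}

# wrap bare positions as an interp_track
make_interp <- function(x, y, t_h = seq_along(x) - 1, bird = "b1") {
  df <- data.frame(time = as.POSIXct("2020-01-01", tz = "UTC") + t_h * 3600,
                   t_h = t_h, x = x, y = y, sd = 0)
  attr(df, "bird_id") <- bird
  attr(df, "interval_hours") <- if (length(t_h) > 1) diff(t_h)[1] else 1
  class(df) <- c("interp_track", "data.frame")
  df
}

# core_area-like object from an explicit cell set (for raster/site oracles)
make_core <- function(cells, res = 1, bird = "b") {
  structure(list(cells = cells, res = res,
                 rings = pengiba:::cells_to_rings(cells, res),
                 area_km2 = nrow(cells) * res^2, ud_percent = NA,
                 enclosed_mass = NA, threshold = NA, bird_id = bird),
            class = "core_area")
}

# hand-built ARS track: commute out, diffusive loitering inside a patch of
# given radius, commute home
make_ars_track <- function(patch_centre = c(40, 0), patch_radius = 5,
                           loiter_h = 20, speed = 5, dt = 0.5, seed = 9,
                           bird = "b1") {
  set.seed(seed)
  out_t <- seq(0, patch_centre[1] / speed, by = dt)
  ox <- speed * out_t; oy <- rep(0, length(out_t))
  n_lo <- ceiling(loiter_h / dt)
  lo <- matrix(0, n_lo, 2); p <- patch_centre
  for (k in seq_len(n_lo)) {
    repeat {
      cand <- p + stats::rnorm(2, 0, 1.2 * sqrt(dt))
      if (sqrt(sum((cand - patch_centre)^2)) <= patch_radius) break
    }
    p <- cand; lo[k, ] <- p
  }
  lot <- max(out_t) + dt * seq_len(n_lo)
  back_t <- seq(max(lot) + dt, max(lot) + patch_centre[1] / speed, by = dt)
  bx <- seq(lo[n_lo, 1], 0, length.out = length(back_t))
  by <- seq(lo[n_lo, 2], 0, length.out = length(back_t))
  make_interp(c(ox, lo[, 1], bx), c(oy, lo[, 2], by),
              c(out_t, lot, back_t), bird = bird)
}

# small tracking CSV + colony table on disk; returns the two paths
write_toy_csv <- function(dir = NULL, rows = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("toy")
    dir.create(dir)
  }
  if (is.null(rows)) {
    rows <- data.frame(
      bird_id = rep(c("p1", "p2"), each = 5),
      species = "chinstrap", site_name = "Toy Colony",
      colony_latitude = -60.7, colony_longitude = -45.6,
      breed_stage = "brood", device = "GPS",
      datetime = rep(sprintf("2020-01-01T0%d:00:00", 0:4), 2),
      latitude = -60.7 + seq(0.01, 0.05, by = 0.01),
      longitude = -45.6, argos_quality = "G")
  }
  tracking <- file.path(dir, "tracks.csv")
  utils::write.csv(rows, tracking, row.names = FALSE)
  meta <- file.path(dir, "colonies.csv")
  utils::write.csv(data.frame(species = "chinstrap", colony = "Toy Colony",
                              stage = "brood", device = "GPS",
                              colony_size_pairs = 12000),
                   meta, row.names = FALSE)
  c(tracking = tracking, colony_table = meta)
}
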