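test_that("Kalman filter log-likelihood matches the joint-Gaussian oracle", {
  for (s in 1:3) {
    set.seed(s)
    n <- sample(8:20, 1)
    times <- sort(c(0, cumsum(stats::runif(n - 1, 0.2, 2))))
    tr <- simulate_ctcrw_track(times, beta = 0.8, sigma = 3,
                               obs_sd = 0.3, seed = 100 + s)
    for (pars in list(c(0.8, 3), c(2, 1), c(0.3, 5))) {
      ll_kf <- ctcrw_loglik(tr, pars[1], pars[2], c(G = 0.3))
      vp <- stats::var(tr$x) + stats::var(tr$y) + 0.3^2 + 1
      th <- as.numeric(tr$timestamp - tr$timestamp[1], units = "hours")
      ll_or <- oracle_ctcrw_ll(tr$x, rep(0.09, n), th, pars[1], pars[2]^2, vp) +
        oracle_ctcrw_ll(tr$y, rep(0.09, n), th, pars[1], pars[2]^2, vp)
      expect_equal(ll_kf, ll_or, tolerance = 1e-6)
    }
  }
})

test_that("fit recovers known parameters from a long simulated track", {
  tr <- simulate_ctcrw_track(seq(0, 0.25 * 1999, by = 0.25), beta = 1,
                             sigma = 2, obs_sd = 0.01, seed = 5)
  f <- fit_ctcrw(tr, c(G = 0.01))
  expect_lt(abs(f$beta - 1) / 1, 0.15)
  expect_lt(abs(f$sigma - 2) / 2, 0.15)
})

test_that("degenerate tracks are rejected or flagged", {
  expect_error(fit_ctcrw(make_track(1:3, 1:3, 0:2)), "at least 5 fixes")
  short <- make_track(1:6, 1:6, seq(0, 0.5, by = 0.1))
  expect_error(fit_ctcrw(short), "span")
  stat <- make_track(rep(3, 6), rep(4, 6), 0:5)
  f <- fit_ctcrw(stat)
  expect_true(f$stationary)
  expect_equal(f$sigma, 0)
  it <- interpolate_track(stat, f, 1)
  expect_true(all(abs(it$x - 3) < 1e-3 & abs(it$y - 4) < 1e-3))
})

test_that("smoothing reproduces near-noiseless observations and never extrapolates", {
  tr <- simulate_ctcrw_track(seq(0, 24, by = 1), beta = 1, sigma = 2,
                             obs_sd = 1e-4, seed = 2)
  f <- fit_ctcrw(tr, c(G = 1e-4))
  it <- interpolate_track(tr, f, 1)
  expect_lt(max(abs(it$x - tr$x)), 1e-3)   # within 1 m at observation times
  expect_lt(max(abs(it$y - tr$y)), 1e-3)
  expect_gte(min(it$t_h), 0)
  expect_lte(max(it$t_h), 24)
  expect_error(interpolate_track(tr, f, 30), "exceeds track span")
})

test_that("smoother is invariant to time origin and rigid rotation", {
  tr <- simulate_ctcrw_track(seq(0, 48, by = 2), beta = 0.7, sigma = 1.5,
                             obs_sd = 0.2, seed = 11)
  f <- fit_ctcrw(tr, c(G = 0.2))
  it <- interpolate_track(tr, f, 2)
  # time shift
  tr_s <- tr; tr_s$timestamp <- tr$timestamp + 86400 * 10
  f_s <- fit_ctcrw(tr_s, c(G = 0.2))
  it_s <- interpolate_track(tr_s, f_s, 2)
  expect_equal(it_s$x, it$x, tolerance = 1e-8)
  # rotation by 37 degrees
  a <- 37 * pi / 180
  tr_r <- tr
  tr_r$x <- cos(a) * tr$x - sin(a) * tr$y
  tr_r$y <- sin(a) * tr$x + cos(a) * tr$y
  f_r <- fit_ctcrw(tr_r, c(G = 0.2))
  it_r <- interpolate_track(tr_r, f_r, 2)
  back_x <- cos(a) * it_r$x + sin(a) * it_r$y
  back_y <- -sin(a) * it_r$x + cos(a) * it_r$y
  expect_equal(back_x, it$x, tolerance = 1e-4)
  expect_equal(back_y, it$y, tolerance = 1e-4)
})

test_that("fast-reversion midpoint approaches the linear interpolant", {
  # two fixes, beta large: velocity decorrelates almost immediately, so the
  # smoothed midpoint must sit inside the segment bounding box near its middle
  tr <- make_track(c(0, 10), c(0, 4), c(0, 2))
  p <- structure(list(beta = 50, sigma = 5, stationary = FALSE,
                      obs_sd = c(1e-4, 1e-4), times_h = c(0, 2)),
                 class = "pengiba_ctcrw")
  it <- interpolate_track(tr, p, 1)
  mid <- it[it$t_h == 1, ]
  expect_gte(mid$x, 0); expect_lte(mid$x, 10)
  expect_gte(mid$y, 0); expect_lte(mid$y, 4)
  expect_lt(abs(mid$x - 5), 1)
  expect_lt(abs(mid$y - 2), 0.5)
})

test_that("dataset interpolation falls back to linear for unfittable tracks", {
  good <- make_track(cumsum(stats::runif(30, 0.3, 1)),
                     cumsum(stats::rnorm(30)), seq(0, 29) * 0.5)
  bad <- make_track(c(0, 1, 2), c(0, 1, 0), c(0, 2, 4), bird = "b2")
  ds <- tracking_dataset(colony("C", "adelie", -45, -60, 10, "brood"), "GPS",
                         list(good, bad))
  ds$projected <- TRUE
  expect_warning(out <- interpolate_dataset(ds, 0.5), "linear interpolation")
  expect_length(out, 2)
  expect_equal(out[["b2"]]$x[out[["b2"]]$t_h == 2], 1)  # linear at a fix
})
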