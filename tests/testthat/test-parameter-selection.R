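toy_dataset <- function(n = 10, seed = 1) {
  set.seed(seed)
  tracks <- lapply(seq_len(n), function(b)
    make_track(cumsum(stats::runif(20, 0.5, 2)) + 2,
               stats::rnorm(20, b, 1), seq(0, 9.5, by = 0.5),
               bird = sprintf("b%02d", b)))
  ds <- tracking_dataset(colony("T", "chinstrap", -45, -60, 1000, "brood"),
                         "GPS", tracks)
  ds$projected <- TRUE
  ds
}

test_that("test/validation split is by bird, seeded and disjoint", {
  ds <- toy_dataset(10)
  sp <- split_test_validation(ds, 0.5, seed = 3)
  expect_length(sp$test$tracks, 5)
  expect_equal(length(unique(sp$validation_positions$bird_id)), 5)
  expect_length(intersect(names(sp$test$tracks),
                          unique(sp$validation_positions$bird_id)), 0)
  sp2 <- split_test_validation(ds, 0.5, seed = 3)
  expect_identical(names(sp$test$tracks), names(sp2$test$tracks))
  sp3 <- split_test_validation(ds, 0.5, seed = 4)
  expect_false(identical(names(sp$test$tracks), names(sp3$test$tracks)))
  expect_error(split_test_validation(ds, 1.0, seed = 1), "empty")
  expect_error(split_test_validation(toy_dataset(3), 0.5, 1), "at least 4")
})

test_that("default grids yield 210 combinations; singleton grid matches a direct run", {
  tracks <- lapply(1:3, function(b) {
    set.seed(b)
    make_interp(stats::rnorm(25, 10, 4), stats::rnorm(25, 0, 4),
                bird = paste0("b", b))
  })
  vp <- data.frame(x = stats::rnorm(50, 10, 5), y = stats::rnorm(50, 0, 5))
  g <- grid_search(tracks, vp)
  expect_equal(nrow(g), 10 * 7 * 3)
  expect_false(any(g$failed))
  g1 <- grid_search(tracks, vp, h_values = 7, ud_values = 55, pt_values = 20)
  expect_equal(nrow(g1), 1)
  uds <- lapply(tracks, estimate_ud, h_km = 7)
  site <- delineate(usage_raster(lapply(uds, core_area, ud_percent = 55)), 20)
  expect_equal(g1$area_km2, site$area_km2)
  expect_equal(g1$inclusion, inclusion(site, vp))
  expect_warning(grid_search(tracks, vp, h_values = c(7, 7), ud_values = 55,
                             pt_values = 20), "duplicate")
})

test_that("nested grids give identical values on shared combinations", {
  tracks <- lapply(1:3, function(b) {
    set.seed(10 + b)
    make_interp(stats::rnorm(20, 5, 3), stats::rnorm(20, 0, 3),
                bird = paste0("b", b))
  })
  vp <- data.frame(x = stats::rnorm(30, 5, 4), y = stats::rnorm(30, 0, 4))
  big <- grid_search(tracks, vp, h_values = c(3, 5, 7),
                     ud_values = c(50, 60), pt_values = 20)
  small <- grid_search(tracks, vp, h_values = 5, ud_values = c(50, 60),
                       pt_values = 20)
  shared <- merge(small, big, by = c("h_km", "ud_percent", "pt"))
  expect_equal(shared$area_km2.x, shared$area_km2.y)
  expect_equal(shared$inclusion.x, shared$inclusion.y)
})

test_that("the asymptote rule picks the first <5%-variation point", {
  g <- data.frame(h_km = 1:4, ud_percent = 50, pt = 20,
                  area_km2 = c(100, 200, 300, 400),
                  inclusion = c(40, 60, 71, 73), failed = FALSE)
  expect_equal(select_optimum(g)$area_km2, 300)
  # invariant to input order
  expect_equal(select_optimum(g[c(3, 1, 4, 2), ])$area_km2, 300)
  # all inclusions equal: smallest area wins
  g2 <- g; g2$inclusion <- 50
  expect_equal(select_optimum(g2)$area_km2, 100)
  # never saturating: warning and max-inclusion fallback
  g3 <- g; g3$inclusion <- c(10, 20, 40, 80)
  expect_warning(pick <- select_optimum(g3), "asymptote")
  expect_equal(pick$inclusion, 80)
  expect_error(select_optimum(g[1, ]), "at least 2")
})

test_that("UD%~distance calibration reproduces the published fit", {
  tab <- penguin_parameter_tests()
  expect_equal(nrow(tab), 10)
  fit <- fit_ud_distance_calibration(tab)
  expect_equal(round(fit$slope, 5), 0.18773)
  expect_equal(round(fit$intercept, 5), 53.21025)
  expect_equal(round(fit$pearson_r, 2), 0.89)
  expect_lt(fit$p_value, 0.001)
  # collinear toy input
  toy <- data.frame(mean_max_distance_km = c(1, 2, 3, 4),
                    best_ud_percent = c(3, 5, 7, 9))
  f2 <- fit_ud_distance_calibration(toy)
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 1)
  expect_equal(f2$pearson_r, 1)
  expect_error(fit_ud_distance_calibration(
    data.frame(mean_max_distance_km = c(2, 2, 2),
               best_ud_percent = c(1, 2, 3))), "zero variance")
})

test_that("the calibration function evaluates and clamps to [50, 80]", {
  fit <- fit_ud_distance_calibration(penguin_parameter_tests())
  expect_equal(ud_from_maxdist(0, fit), 53.21025, tolerance = 1e-4)
  expect_equal(ud_from_maxdist(76.12, fit), 67.5, tolerance = 0.01)
  expect_equal(ud_from_maxdist(200, fit), 80)
  expect_equal(ud_from_maxdist(1e-9, fit), 53.21025, tolerance = 1e-4)
  expect_equal(predict(fit, 76.12), 67.5, tolerance = 0.01)
})

test_that("stage comparison reproduces the published Welch test", {
  tab <- penguin_parameter_tests()
  w <- compare_stage_inclusion(tab)
  expect_equal(round(w$t, 2), 2.96)
  expect_equal(round(w$df, 2), 6.71)
  expect_equal(round(w$p_value, 4), 0.0222)
  expect_equal(round(unname(w$means), 2), c(82.37, 68.48))
  # identical groups -> t = 0
  same <- data.frame(stage = rep(c("brood", "incubation"), each = 3),
                     inclusion = c(70, 75, 80, 70, 75, 80))
  expect_equal(compare_stage_inclusion(same)$t, 0)
  # degenerate inputs guarded
  expect_error(compare_stage_inclusion(
    data.frame(stage = c("brood", "incubation", "incubation"),
               inclusion = c(1, 2, 3))), "at least 2")
  expect_error(compare_stage_inclusion(
    data.frame(stage = rep(c("brood", "incubation"), each = 2),
               inclusion = c(5, 5, 9, 9))), "zero variance")
})

test_that("bandwidth shows no distance effect on the published table", {
  ct <- correlate_h_distance(penguin_parameter_tests())
  expect_equal(round(ct$r, 2), 0.44)
  expect_gt(ct$p_value, 0.05)
  expect_equal(ct$n, 10)
  lin <- data.frame(best_h_km = 1:5, mean_max_distance_km = 1:5)
  expect_equal(correlate_h_distance(lin)$r, 1)
  set.seed(42)
  indep <- data.frame(best_h_km = stats::rnorm(200),
                      mean_max_distance_km = stats::rnorm(200))
  expect_lt(abs(correlate_h_distance(indep)$r), 0.15)
})

test_that("sensitivity perturbations report small changes around a smooth optimum", {
  tracks <- lapply(1:4, function(b) {
    set.seed(20 + b)
    make_interp(stats::rnorm(25, 8, 4), stats::rnorm(25, 0, 4),
                bird = paste0("b", b))
  })
  vp <- data.frame(x = stats::rnorm(40, 8, 5), y = stats::rnorm(40, 0, 5))
  opt <- data.frame(h_km = 7, ud_percent = 55, pt = 20)
  s <- sensitivity_around_optimum(tracks, vp, opt)
  ref <- s[s$h_km == 7 & s$ud_percent == 55, ]
  expect_equal(ref$d_area_pct, 0)
  expect_true(all(is.finite(s$d_area_pct)))
})
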