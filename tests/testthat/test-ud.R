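test_that("gridded KDE equals the brute-force kernel sum", {
  set.seed(3)
  x <- stats::rnorm(150, 0, 12); y <- stats::rnorm(150, 5, 9)
  ud <- estimate_ud(data.frame(x = x, y = y), h_km = 7)
  idx <- cbind(sample(length(ud$ix), 20), sample(length(ud$iy), 20))
  for (k in 1:20) {
    gx <- ud$ix[idx[k, 1]] * ud$res; gy <- ud$iy[idx[k, 2]] * ud$res
    brute <- mean(exp(-((x - gx)^2 + (y - gy)^2) / (2 * 7^2))) / (2 * pi * 7^2)
    expect_lt(abs(ud$z[idx[k, 1], idx[k, 2]] * ud$norm - brute) / brute, 1e-8)
  }
})

test_that("surface normalizes to unit mass and peaks at a lone position", {
  ud <- estimate_ud(data.frame(x = 3, y = -2), h_km = 5)
  expect_equal(sum(ud$z) * ud$res^2, 1, tolerance = 1e-6)
  peak <- which(ud$z == max(ud$z), arr.ind = TRUE)
  expect_equal(ud$ix[peak[1]] * ud$res, 3, tolerance = ud$res)
  expect_equal(ud$iy[peak[2]] * ud$res, -2, tolerance = ud$res)
  expect_error(estimate_ud(data.frame(x = 1, y = 1), h_km = -1))
})

test_that("two distant kernels give two modes of equal mass", {
  ud <- estimate_ud(data.frame(x = c(0, 100), y = c(0, 0)), h_km = 7)
  mass_left <- sum(ud$z[ud$ix < 50, ]) * ud$res^2
  expect_equal(mass_left, 0.5, tolerance = 1e-6)
  # two local maxima: density at both centres far exceeds the midpoint
  at <- function(px) ud$z[which.min(abs(ud$ix - px)), which.min(abs(ud$iy))]
  expect_gt(at(0), 100 * at(50))
  expect_gt(at(100), 100 * at(50))
})

test_that("core area matches the closed form for a single kernel", {
  # one bivariate Gaussian kernel: the 50% superlevel set is a disc of
  # radius h*sqrt(2 ln 2) ~ 8.24 km, area ~ 213.3 km^2
  ud <- estimate_ud(data.frame(x = 0, y = 0), h_km = 7)
  ca <- core_area(ud, 50)
  r <- 7 * sqrt(2 * log(2))
  expect_lt(abs(ca$area_km2 - pi * r^2), 2 * pi * r * ud$res)  # one-cell rim
  expect_gte(ca$enclosed_mass, 50)
  expect_lt(ca$enclosed_mass, 50 + 100 * max(ud$z) * ud$res^2)
})

test_that("core areas nest, grow with UD%, and respect mass bounds", {
  set.seed(8)
  ud <- estimate_ud(data.frame(x = stats::rnorm(60, 0, 8),
                               y = stats::rnorm(60, 0, 8)), h_km = 4)
  prev_cells <- character(0); prev_area <- 0
  for (p in seq(50, 95, by = 5)) {
    ca <- core_area(ud, p)
    expect_gte(ca$enclosed_mass, p)
    expect_lt(ca$enclosed_mass, p + 100 * max(ud$z) * ud$res^2 + 1e-9)
    keys <- paste(ca$cells[, 1], ca$cells[, 2])
    expect_true(all(prev_cells %in% keys))   # nesting
    expect_gte(ca$area_km2, prev_area)       # monotone area
    prev_cells <- keys; prev_area <- ca$area_km2
  }
})

test_that("for fixed points the core area grows with h once h exceeds the spread", {
  pts <- data.frame(x = c(0, 2, -1), y = c(0, 1, -2))
  areas <- vapply(c(5, 7, 9, 12), function(h)
    core_area(estimate_ud(pts, h), 50)$area_km2, 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("polygonization separates 4-connected components and keeps holes", {
  # two diagonal cells: two separate square rings
  rings <- pengiba:::cells_to_rings(rbind(c(0, 0), c(1, 1)), 1)
  expect_length(rings, 2)
  areas <- vapply(rings, pengiba:::.ring_signed_area, 0)
  expect_equal(sort(areas), c(1, 1))
  # 3x3 block minus centre: outer ring + clockwise hole, shoelace sums to 8
  cells <- as.matrix(expand.grid(0:2, 0:2))
  cells <- cells[!(cells[, 1] == 1 & cells[, 2] == 1), ]
  rings <- pengiba:::cells_to_rings(cells, 1)
  expect_length(rings, 2)
  sa <- vapply(rings, pengiba:::.ring_signed_area, 0)
  expect_equal(sum(sa), 8)
  expect_lt(min(sa), 0)   # the hole is clockwise
})

test_that("FPT variance peaks near the patch scale and the median aggregates birds", {
  tr <- make_ars_track(patch_radius = 5, seed = 9)
  v <- pengiba:::.fpt_log_var(tr, 1:20)
  expect_gte(which.max(v), 2)
  a1 <- ars_scale(list(tr), 1:20)
  expect_gte(a1$scale_km, 2.5); expect_lte(a1$scale_km, 10)
  # three birds with different patch scales: the dataset scale is the median
  birds <- list(make_ars_track(patch_radius = 3, seed = 1, bird = "s3"),
                make_ars_track(patch_radius = 5, seed = 2, bird = "s5"),
                make_ars_track(patch_centre = c(60, 0), patch_radius = 12,
                               loiter_h = 40, seed = 3, bird = "s12"))
  a <- ars_scale(birds, 1:20)
  expect_equal(a$scale_km, stats::median(a$per_bird))
})

test_that("a straight constant-speed track has no ARS scale", {
  tr <- make_interp(seq(0, 50, by = 0.5), rep(0, 101), seq(0, 10, by = 0.1))
  expect_error(ars_scale(list(tr), 1:10), "undefined")
})
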