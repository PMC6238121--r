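test_that("CSV rows are grouped into per-bird tracks sorted in time", {
  paths <- write_toy_csv()
  ds <- read_tracking_csv(paths["tracking"], paths["colony_table"])
  expect_s3_class(ds, "tracking_dataset")
  expect_length(ds$tracks, 2)
  expect_equal(unname(vapply(ds$tracks, nrow, 0L)), c(5L, 5L))
  expect_equal(ds$colony$size_pairs, 12000L)

  # shuffled rows come back strictly increasing in time per bird
  rows <- utils::read.csv(paths["tracking"])
  set.seed(4)
  shuffled <- rows[sample.int(nrow(rows)), ]
  p2 <- write_toy_csv(rows = shuffled)
  ds2 <- read_tracking_csv(p2["tracking"], p2["colony_table"])
  for (tr in ds2$tracks)
    expect_true(all(diff(as.numeric(tr$timestamp)) > 0))
})

test_that("duplicate and unparsable rows are dropped and counted", {
  rows <- utils::read.csv(write_toy_csv()["tracking"])
  rows <- rbind(rows, rows[1, ], rows[3, ])        # two duplicate fixes
  rows$latitude[2] <- 400                          # invalid coordinate
  p <- write_toy_csv(rows = rows)
  ds <- read_tracking_csv(p["tracking"], p["colony_table"])
  expect_equal(ds$load_report$dropped_duplicate_timestamp, 2)
  expect_equal(ds$load_report$dropped_bad_coordinate, 1)
  expect_equal(sum(vapply(ds$tracks, nrow, 0L)), 9L)
})

test_that("reader errors on missing columns, empty input, unknown colony", {
  p <- write_toy_csv()
  rows <- utils::read.csv(p["tracking"])
  bad <- rows[, setdiff(names(rows), "latitude")]
  pb <- write_toy_csv(rows = bad)
  expect_error(read_tracking_csv(pb["tracking"], pb["colony_table"]),
               "missing required column")
  rows2 <- rows; rows2$datetime <- "not-a-time"
  p2 <- write_toy_csv(rows = rows2)
  expect_error(read_tracking_csv(p2["tracking"], p2["colony_table"]),
               "no valid rows")
  rows3 <- rows; rows3$site_name <- "Nowhere"
  p3 <- write_toy_csv(rows = rows3)
  expect_error(read_tracking_csv(p3["tracking"], p3["colony_table"]),
               "not found")
})

test_that("write/read round trip preserves fixes on declared columns", {
  paths <- write_toy_csv()
  ds <- read_tracking_csv(paths["tracking"], paths["colony_table"])
  out <- file.path(dirname(paths["tracking"]), "echo.csv")
  write_tracking_csv(ds, out)
  p2 <- write_toy_csv(rows = utils::read.csv(out))
  ds2 <- read_tracking_csv(p2["tracking"], p2["colony_table"])
  for (b in names(ds$tracks)) {
    expect_equal(ds2$tracks[[b]]$lon, ds$tracks[[b]]$lon)
    expect_equal(ds2$tracks[[b]]$lat, ds$tracks[[b]]$lat)
    expect_equal(ds2$tracks[[b]]$timestamp, ds$tracks[[b]]$timestamp)
    expect_equal(ds2$tracks[[b]]$loc_class, ds$tracks[[b]]$loc_class)
  }
})

test_that("projection is centred, invertible, and metric near the colony", {
  clon <- -45.6; clat <- -60.72
  expect_equal(unname(lonlat_to_plane(clon, clat, clon, clat)), cbind(0, 0),
               ignore_attr = TRUE)
  # round trip < 1 m for scattered points
  set.seed(7)
  lon <- clon + stats::runif(30, -3, 3)
  lat <- clat + stats::runif(30, -1.5, 1.5)
  xy <- lonlat_to_plane(lon, lat, clon, clat)
  ll <- plane_to_lonlat(xy[, 1], xy[, 2], clon, clat)
  xy2 <- lonlat_to_plane(ll[, 1], ll[, 2], clon, clat)
  expect_lt(max(sqrt(rowSums((xy2 - xy)^2))), 1e-3)

  # 100 km due geodesic north -> planar distance within 0.5%
  p <- geosphere::destPoint(c(clon, clat), 0, 100000)
  xyn <- lonlat_to_plane(p[1], p[2], clon, clat)
  expect_lt(abs(sqrt(sum(xyn^2)) - 100) / 100, 0.005)
  # pairwise distances within 1% of geodesics up to ~200 km out
  far_lon <- clon + stats::runif(12, -4, 4)
  far_lat <- clat + stats::runif(12, -1.8, 1.8)
  fxy <- lonlat_to_plane(far_lon, far_lat, clon, clat)
  for (i in 1:11) for (j in (i + 1):12) {
    geo <- geosphere::distGeo(c(far_lon[i], far_lat[i]),
                              c(far_lon[j], far_lat[j])) / 1000
    pla <- sqrt(sum((fxy[i, ] - fxy[j, ])^2))
    if (geo > 1) expect_lt(abs(pla - geo) / geo, 0.01)
  }
})

test_that("at-sea filter applies the buffer, is idempotent, errors when empty", {
  mk <- function() {
    tr <- list(make_track(c(0.1, 5, 6, 0.2), c(0, 0, 1, 0.1), 0:3),
               make_track(c(0.05, 7, 8), c(0, 1, 0), 0:2, bird = "b2"))
    d <- tracking_dataset(colony("C", "gentoo", -45, -60, 100, "brood"),
                          "GPS", tr)
    d$projected <- TRUE
    d
  }
  ds <- mk()
  f <- filter_at_sea(ds, 0.5)
  expect_equal(sum(vapply(f$tracks, nrow, 0L)), 4L)
  expect_true(all(unlist(lapply(f$tracks, function(t) sqrt(t$x^2 + t$y^2))) >= 0.5))
  # idempotent
  f2 <- filter_at_sea(f, 0.5)
  expect_equal(lapply(f2$tracks, function(t) t$x), lapply(f$tracks, function(t) t$x))
  # buffer 0 keeps everything
  f0 <- filter_at_sea(ds, 0)
  expect_equal(sum(vapply(f0$tracks, nrow, 0L)), 7L)
  # everything at the colony -> error
  near <- tracking_dataset(ds$colony, "GPS",
                           list(make_track(c(0.1, 0.2), c(0, 0), 0:1)))
  near$projected <- TRUE
  expect_error(filter_at_sea(near, 0.5), "no at-sea fixes")
})
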