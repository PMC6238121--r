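# Seeded generator of central-place-foraging penguin tracks: trip-structured
# movement (outbound commute, area-restricted loitering in prey patches,
# return to the colony), stage-dependent trip range, and device-dependent fix
# frequency and positional error. Emulates the structure of Seabird Tracking
# Database datasets so every pipeline stage can be exercised without real
# data.

#' Configuration for the track simulator
#'
#' Stage presets centre the trip range on values typical of Pygoscelis
#' colonies: incubation 120 km, brood 25 km, creche 55 km, with
#' correspondingly longer loitering bouts and fewer trips during incubation.
#'
#' @param species,colony_name,colony_lon,colony_lat,colony_size_pairs colony
#'   identity (defaults place a 20,000-pair chinstrap colony in the South
#'   Orkneys).
#' @param stage breeding stage; sets range/trip presets unless overridden.
#' @param n_birds number of simulated individuals.
#' @param device `"GPS"` (15-min fixes, 50 m error) or `"PTT"` (90-min
#'   fixes, Argos-class errors).
#' @param max_trip_distance_km hard cap on distance from the colony (km).
#' @param n_patches,patch_radius_km,patch_bearings prey patches: count,
#'   radius, and bearings (degrees clockwise from north; default evenly
#'   spread over a 120 degree offshore sector).
#' @param patch_distance_frac patch centres sit at this fraction of the trip
#'   range.
#' @param speed_kmh commuting speed.
#' @param n_trips,loiter_hours trips per bird and loitering time per trip.
#' @param fix_interval_minutes,fix_jitter_minutes mean fix spacing and
#'   uniform jitter.
#' @param argos_class_mix sampling probabilities of Argos location classes
#'   for PTT devices (must sum to 1).
#' @param seed integer seed; the simulation is a deterministic function of
#'   the configuration including this seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(species = "chinstrap", colony_name = "Simulated Colony",
                       colony_lon = -45.60, colony_lat = -60.72,
                       colony_size_pairs = 20000,
                       stage = "brood", n_birds = 10, device = "GPS",
                       max_trip_distance_km = NULL,
                       n_patches = 2, patch_radius_km = 5,
                       patch_bearings = NULL, patch_distance_frac = 0.7,
                       speed_kmh = 4,
                       n_trips = NULL, loiter_hours = NULL,
                       fix_interval_minutes = NULL, fix_jitter_minutes = NULL,
                       argos_class_mix = c("3" = 0.1, "2" = 0.15, "1" = 0.25,
                                           "0" = 0.2, A = 0.15, B = 0.15),
                       seed = 1) {
  stage <- .norm_stage(stage)
  preset <- switch(stage,
                   incubation = list(range = 120, trips = 1, loiter = 24),
                   brood      = list(range = 25,  trips = 3, loiter = 4),
                   creche     = list(range = 55,  trips = 2, loiter = 8))
  max_trip_distance_km <- max_trip_distance_km %||% preset$range
  n_trips <- n_trips %||% preset$trips
  loiter_hours <- loiter_hours %||% preset$loiter
  device <- match.arg(device, c("GPS", "PTT"))
  fix_interval_minutes <- fix_interval_minutes %||%
    if (device == "GPS") 15 else 90
  fix_jitter_minutes <- fix_jitter_minutes %||% fix_interval_minutes / 5
  patch_bearings <- patch_bearings %||%
    seq(30, 150, length.out = max(n_patches, 1))
  stopifnot(n_birds >= 1, n_patches >= 1, patch_radius_km > 0,
            speed_kmh > 0, max_trip_distance_km > 0,
            fix_interval_minutes > 0, abs(sum(argos_class_mix) - 1) < 1e-9)
  if (patch_distance_frac * max_trip_distance_km + patch_radius_km >
      max_trip_distance_km)
    stop("patches extend beyond max_trip_distance_km; reduce ",
         "patch_distance_frac or patch_radius_km")
  structure(list(species = .norm_species(species), colony_name = colony_name,
                 colony_lon = colony_lon, colony_lat = colony_lat,
                 colony_size_pairs = colony_size_pairs, stage = stage,
                 n_birds = n_birds, device = device,
                 max_trip_distance_km = max_trip_distance_km,
                 n_patches = n_patches, patch_radius_km = patch_radius_km,
                 patch_bearings = patch_bearings,
                 patch_distance_frac = patch_distance_frac,
                 speed_kmh = speed_kmh, n_trips = n_trips,
                 loiter_hours = loiter_hours,
                 fix_interval_minutes = fix_interval_minutes,
                 fix_jitter_minutes = fix_jitter_minutes,
                 argos_class_mix = argos_class_mix, seed = seed),
            class = "sim_config")
}

# one trip's true path at dt_h resolution, returned as x/y matrix
.sim_trip <- function(cfg, patch_xy, dt_h = 0.1) {
  v <- cfg$speed_kmh * dt_h
  rmax <- cfg$max_trip_distance_km
  pos <- c(0, 0)
  path <- list(pos)
  push <- function(p) {
    r <- sqrt(sum(p^2))
    if (r > rmax) p <- p * (rmax / r)          # hard range cap
    path[[length(path) + 1]] <<- p
    p
  }
  head_noise <- 0
  # outbound: correlated headings around the bearing to the patch
  target <- patch_xy + stats::rnorm(2, 0, cfg$patch_radius_km / 3)
  while (sqrt(sum((pos - target)^2)) > v * 1.5) {
    head_noise <- 0.7 * head_noise + stats::rnorm(1, 0, 0.35)
    ang <- atan2(target[2] - pos[2], target[1] - pos[1]) + head_noise
    pos <- push(pos + v * c(cos(ang), sin(ang)))
    if (length(path) > 5000) break
  }
  # loitering: slow, high-turning walk kept inside the patch
  ang <- stats::runif(1, 0, 2 * pi)
  for (k in seq_len(ceiling(cfg$loiter_hours / dt_h))) {
    ang <- ang + stats::rnorm(1, 0, 1.6)
    step <- 0.4 * v * c(cos(ang), sin(ang))
    cand <- pos + step
    if (sqrt(sum((cand - patch_xy)^2)) > cfg$patch_radius_km)
      cand <- pos + 0.4 * v * (patch_xy - pos) / sqrt(sum((patch_xy - pos)^2))
    pos <- push(cand)
  }
  # return commute
  while (sqrt(sum(pos^2)) > v * 1.5) {
    head_noise <- 0.7 * head_noise + stats::rnorm(1, 0, 0.35)
    ang <- atan2(-pos[2], -pos[1]) + head_noise
    pos <- push(pos + v * c(cos(ang), sin(ang)))
    if (length(path) > 15000) break
  }
  do.call(rbind, path)
}

#' Simulate a tracking dataset
#'
#' Generates `n_birds` trip-structured tracks under the configuration,
#' samples fixes at the device's interval with jitter, adds
#' device-appropriate positional noise (GPS 50 m; Argos class drawn from
#' `argos_class_mix` with the SDs of [default_argos_sd]), and returns a
#' [tracking_dataset()] in geographic coordinates, byte-identical for a
#' given configuration.
#'
#' @param config a [sim_config()].
#' @return a `tracking_dataset` (writable with [write_tracking_csv()]).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dt_h <- 0.1
  bear_rad <- (90 - cfg$patch_bearings) * pi / 180   # compass -> math angle
  d_patch <- cfg$patch_distance_frac * cfg$max_trip_distance_km
  patches <- cbind(d_patch * cos(bear_rad), d_patch * sin(bear_rad))
  origin <- as.POSIXct("2019-12-15 00:00:00", tz = "UTC")
  sds <- default_argos_sd

  tracks <- lapply(seq_len(cfg$n_birds), function(b) {
    # true path: trips separated by 2 h colony attendance
    path <- NULL; t_h <- NULL; t0 <- 0
    for (tr in seq_len(cfg$n_trips)) {
      p <- patches[sample.int(nrow(patches), 1), ]
      xy <- .sim_trip(cfg, p, dt_h)
      path <- rbind(path, xy)
      t_h <- c(t_h, t0 + seq(0, by = dt_h, length.out = nrow(xy)))
      t0 <- t_h[length(t_h)] + 2
    }
    span <- max(t_h)
    iv <- cfg$fix_interval_minutes / 60
    jit <- cfg$fix_jitter_minutes / 60
    ft <- cumsum(pmax(iv / 4, iv + stats::runif(ceiling(span / iv) + 2, -jit, jit)))
    ft <- c(0, ft[ft <= span])
    xi <- stats::approx(t_h, path[, 1], xout = ft, ties = "ordered")$y
    yi <- stats::approx(t_h, path[, 2], xout = ft, ties = "ordered")$y
    if (cfg$device == "GPS") {
      cls <- rep("G", length(ft))
    } else {
      cls <- sample(names(cfg$argos_class_mix), length(ft), replace = TRUE,
                    prob = cfg$argos_class_mix)
    }
    sd <- unname(sds[cls])
    xo <- xi + stats::rnorm(length(ft), 0, sd)
    yo <- yi + stats::rnorm(length(ft), 0, sd)
    ll <- plane_to_lonlat(xo, yo, cfg$colony_lon, cfg$colony_lat)
    data.frame(bird_id = sprintf("bird%02d", b),
               timestamp = origin + round(ft * 3600),
               lon = ll[, "lon"], lat = ll[, "lat"], loc_class = cls,
               stringsAsFactors = FALSE)
  })
  col <- colony(cfg$colony_name, cfg$species, cfg$colony_lon, cfg$colony_lat,
                cfg$colony_size_pairs, cfg$stage)
  tracking_dataset(col, cfg$device, tracks)
}
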