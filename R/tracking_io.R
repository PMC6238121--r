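# Reading, validation, filtering and projection of central-place tracking data.
# The CSV dialect mirrors Seabird Tracking Database exports: one row per fix
# with the colony repeated on every row.

.SPECIES_LEVELS <- c("adelie", "chinstrap", "gentoo")
.STAGE_LEVELS   <- c("incubation", "brood", "creche")

.norm_species <- function(x) {
  s <- tolower(trimws(x))
  s <- gsub("[éè]", "e", s)           # accents
  s <- gsub("\\s*penguin\\s*$", "", s)
  s[s %in% c("adelie", "pygoscelis adeliae")] <- "adelie"
  s[s %in% c("chinstrap", "pygoscelis antarcticus")] <- "chinstrap"
  s[s %in% c("gentoo", "pygoscelis papua")] <- "gentoo"
  if (!all(s %in% .SPECIES_LEVELS))
    stop("unknown species: ", paste(unique(x[!s %in% .SPECIES_LEVELS]), collapse = ", "))
  s
}

.norm_stage <- function(x) {
  s <- tolower(trimws(x))
  s <- gsub("[èé]", "e", s)
  s[s %in% c("brood-guard", "brood_guard", "broodguard", "chick-rearing")] <- "brood"
  if (!all(s %in% .STAGE_LEVELS))
    stop("unknown breeding stage: ", paste(unique(x[!s %in% .STAGE_LEVELS]), collapse = ", "))
  s
}

#' Construct a colony record
#'
#' @param name colony name.
#' @param species one of `"adelie"`, `"chinstrap"`, `"gentoo"` (common names
#'   such as `"Chinstrap penguin"` are normalized).
#' @param lon,lat colony position, decimal degrees WGS84.
#' @param size_pairs colony size in breeding pairs (positive integer).
#' @param stage breeding stage: `"incubation"`, `"brood"` or `"creche"`.
#' @return an object of class `colony`.
#' @export
colony <- function(name, species, lon, lat, size_pairs, stage) {
  stopifnot(is.character(name), length(name) == 1,
            abs(lat) <= 90, abs(lon) <= 180,
            is.finite(size_pairs), size_pairs > 0)
  structure(list(name = name, species = .norm_species(species),
                 lon = as.numeric(lon), lat = as.numeric(lat),
                 size_pairs = as.integer(round(size_pairs)),
                 stage = .norm_stage(stage)),
            class = "colony")
}

#' Assemble a tracking dataset
#'
#' A dataset is one species x colony x breeding stage x device collection of
#' individual tracks. Each track must hold at least 2 fixes, sorted and
#' strictly increasing in time.
#'
#' @param colony a [colony()] object.
#' @param device `"GPS"` or `"PTT"`.
#' @param tracks named list of data frames, one per bird, each with columns
#'   `bird_id`, `timestamp` (POSIXct UTC), `lon`, `lat`, `loc_class`.
#' @param load_report optional list of row-drop counts from the reader.
#' @return an object of class `tracking_dataset`.
#' @export
tracking_dataset <- function(colony, device, tracks, load_report = NULL) {
  stopifnot(inherits(colony, "colony"), device %in% c("GPS", "PTT"),
            is.list(tracks), length(tracks) >= 1)
  for (tr in tracks) {
    if (nrow(tr) < 2) stop("each track needs at least 2 fixes")
    if (length(unique(tr$bird_id)) != 1) stop("mixed bird_id within a track")
    if (any(diff(as.numeric(tr$timestamp)) <= 0))
      stop("timestamps must be strictly increasing within a track")
  }
  names(tracks) <- vapply(tracks, function(t) as.character(t$bird_id[1]), "")
  structure(list(colony = colony, device = device, tracks = tracks,
                 projected = FALSE, load_report = load_report),
            class = "tracking_dataset")
}

#' @export
print.tracking_dataset <- function(x, ...) {
  nfix <- sum(vapply(x$tracks, nrow, 0L))
  cat(sprintf("<tracking_dataset> %s / %s / %s / %s\n", x$colony$species,
              x$colony$name, x$colony$stage, x$device))
  cat(sprintf("  %d birds, %d fixes%s\n", length(x$tracks), nfix,
              if (isTRUE(x$projected)) ", projected (km, colony origin)" else ""))
  invisible(x)
}

# lenient multi-format UTC parser: unparsable entries become NA (counted by
# the caller) instead of aborting the read
.parse_utc <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y/%m/%d %H:%M:%OS", "%d/%m/%Y %H:%M:%OS")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  out
}

.required_cols <- c("bird_id", "species", "site_name", "colony_latitude",
                    "colony_longitude", "breed_stage", "device",
                    "latitude", "longitude")

#' Read a tracking CSV plus colony metadata
#'
#' Expects columns `bird_id`, `species`, `site_name`, `colony_latitude`,
#' `colony_longitude`, `breed_stage`, `device`, `latitude`, `longitude`,
#' either `date_gmt` + `time_gmt` or a combined ISO-8601 `datetime`, and an
#' optional `argos_quality`. Rows are grouped by bird, sorted by time,
#' duplicate (bird, timestamp) rows dropped keeping the first, and unparsable
#' rows dropped and counted in the load report.
#'
#' @param path tracking CSV.
#' @param colony_table colony metadata CSV with columns `species`, `colony`
#'   (or `site`), `stage`, `colony_size_pairs` (one row must match the
#'   tracking file's species/colony/stage).
#' @return a [tracking_dataset()] whose `load_report` counts dropped rows.
#' @export
read_tracking_csv <- function(path, colony_table) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.required_cols, names(raw))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  has_dt <- "datetime" %in% names(raw)
  if (!has_dt && !all(c("date_gmt", "time_gmt") %in% names(raw)))
    stop("missing required column(s): datetime (or date_gmt + time_gmt)")

  ts_chr <- if (has_dt) raw$datetime else paste(raw$date_gmt, raw$time_gmt)
  ts <- .parse_utc(ts_chr)
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  bad_time  <- is.na(ts)
  bad_coord <- is.na(lon) | is.na(lat) | abs(lat) > 90 | abs(lon) > 180
  keep <- !(bad_time | bad_coord)
  report <- list(n_rows = nrow(raw),
                 dropped_bad_timestamp = sum(bad_time),
                 dropped_bad_coordinate = sum(bad_coord & !bad_time))
  df <- data.frame(bird_id = as.character(raw$bird_id)[keep],
                   timestamp = ts[keep], lon = lon[keep], lat = lat[keep],
                   loc_class = if ("argos_quality" %in% names(raw))
                     toupper(trimws(as.character(raw$argos_quality)))[keep]
                   else rep("G", sum(keep)),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no valid rows in ", path)
  df$loc_class[is.na(df$loc_class) | df$loc_class == ""] <- "G"

  df <- df[order(df$bird_id, df$timestamp), ]
  dup <- duplicated(df[c("bird_id", "timestamp")])
  report$dropped_duplicate_timestamp <- sum(dup)
  df <- df[!dup, ]

  species <- .norm_species(raw$species[1])
  stage   <- .norm_stage(raw$breed_stage[1])
  device  <- toupper(trimws(raw$device[1]))
  if (!device %in% c("GPS", "PTT")) stop("device must be GPS or PTT, got ", device)
  site    <- as.character(raw$site_name[1])

  meta <- utils::read.csv(colony_table, stringsAsFactors = FALSE)
  cname <- if ("colony" %in% names(meta)) meta$colony else meta$site
  if (is.null(cname)) stop("colony table needs a 'colony' or 'site' column")
  hit <- .norm_species(meta$species) == species & cname == site
  if ("stage" %in% names(meta)) hit <- hit & .norm_stage(meta$stage) == stage
  if (!any(hit)) stop("colony '", site, "' (", species, ", ", stage,
                      ") not found in ", colony_table)
  size <- meta$colony_size_pairs[which(hit)[1]]

  col <- colony(site, species, raw$colony_longitude[1], raw$colony_latitude[1],
                size, stage)
  tracks <- split(df, df$bird_id)
  short <- vapply(tracks, nrow, 0L) < 2
  report$dropped_short_tracks <- sum(short)
  tracks <- tracks[!short]
  if (!length(tracks)) stop("no track with >= 2 fixes in ", path)
  tracks <- lapply(tracks, function(t) { rownames(t) <- NULL; t })
  tracking_dataset(col, device, tracks, load_report = report)
}

#' Write a tracking dataset back to the CSV dialect read by [read_tracking_csv()]
#'
#' @param dataset a [tracking_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  df <- do.call(rbind, lapply(dataset$tracks, function(t)
    data.frame(bird_id = t$bird_id,
               species = dataset$colony$species,
               site_name = dataset$colony$name,
               colony_latitude = dataset$colony$lat,
               colony_longitude = dataset$colony$lon,
               breed_stage = dataset$colony$stage,
               device = dataset$device,
               datetime = format(t$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               latitude = t$lat, longitude = t$lon,
               argos_quality = t$loc_class,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project all fixes onto the colony-centred equal-area plane
#'
#' Adds `x`/`y` columns (km east/north of the colony) to every track via
#' [lonlat_to_plane()]. The colony itself maps to (0, 0).
#'
#' @param dataset a [tracking_dataset()].
#' @return the dataset with `projected = TRUE`.
#' @export
project_to_colony_plane <- function(dataset) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  cl <- dataset$colony
  dataset$tracks <- lapply(dataset$tracks, function(t) {
    xy <- lonlat_to_plane(t$lon, t$lat, cl$lon, cl$lat)
    t$x <- xy[, "x"]; t$y <- xy[, "y"]
    t
  })
  dataset$projected <- TRUE
  dataset
}

#' Drop fixes at or around the colony
#'
#' Removes fixes closer than `colony_buffer_km` to the colony; the remainder
#' are treated as at-sea locations. Whole tracks are used without splitting
#' into trips, so attendance at the nest is excised by this buffer alone.
#' Tracks left with fewer than 2 fixes are dropped and counted.
#'
#' @param dataset a projected [tracking_dataset()].
#' @param colony_buffer_km radius (km) around the colony to excise; default
#'   0.5 km removes nest attendance without touching nearshore foraging.
#' @return the filtered dataset; its `load_report` gains the removal counts.
#' @export
filter_at_sea <- function(dataset, colony_buffer_km = 0.5) {
  stopifnot(inherits(dataset, "tracking_dataset"), colony_buffer_km >= 0)
  if (!isTRUE(dataset$projected)) stop("project_to_colony_plane() first")
  removed_fixes <- 0L
  tracks <- lapply(dataset$tracks, function(t) {
    keep <- sqrt(t$x^2 + t$y^2) >= colony_buffer_km
    removed_fixes <<- removed_fixes + sum(!keep)
    t[keep, , drop = FALSE]
  })
  short <- vapply(tracks, nrow, 0L) < 2
  tracks <- tracks[!short]
  if (!length(tracks)) stop("no at-sea fixes left after applying a ",
                            colony_buffer_km, " km colony buffer")
  tracks <- lapply(tracks, function(t) { rownames(t) <- NULL; t })
  dataset$tracks <- tracks
  dataset$load_report <- c(dataset$load_report,
                           list(colony_buffer_removed_fixes = removed_fixes,
                                colony_buffer_dropped_tracks = sum(short)))
  dataset
}
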