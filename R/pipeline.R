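# End-to-end orchestration: tracking data (read or simulated) -> projection
# -> at-sea filter -> CTCRW interpolation -> per-bird UDs -> core areas ->
# usage raster -> candidate site -> abundance -> criteria, with optional
# "auto" resolution of UD% (distance calibration) and PT (bootstrap
# representativeness).

#' Run the full candidate-mIBA pipeline on one dataset
#'
#' @param dataset a [tracking_dataset()] (raw; will be projected and
#'   filtered), e.g. from [read_tracking_csv()] or [simulate_dataset()].
#' @param h_km kernel bandwidth; default 7 km, the protocol optimum.
#' @param ud_percent core UD percentage, or `"auto"` to evaluate the
#'   distance calibration fitted to the bundled parameter-test table via
#'   [ud_from_maxdist()].
#' @param pt population threshold (percent), or `"auto"` to run
#'   [bootstrap_inclusion_curve()] and use its recommended PT.
#' @param interval_hours interpolation interval; `NULL` = device default.
#' @param colony_buffer_km at-sea filter radius.
#' @param resolution_km UD grid resolution.
#' @param max_fraction assumed maximum fraction of the colony using the
#'   site, for the abundance maximum.
#' @param seed integer seed for the representativeness bootstrap.
#' @param out_dir if non-`NULL`, write the site GeoJSON, an assessment CSV
#'   and a JSON provenance report there.
#' @return list of class `pengiba_run`: `site` ([delineate()] result),
#'   `assessment` ([assess_criteria()] result), `estimate`, `params`
#'   (resolved h/UD%/PT), `repr` (if PT was `"auto"`), `mean_maxdist_km`,
#'   `files`.
#' @export
run_pipeline <- function(dataset, h_km = 7, ud_percent = "auto", pt = 20,
                         interval_hours = NULL, colony_buffer_km = 0.5,
                         resolution_km = 1, max_fraction = 1, seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  ds <- filter_at_sea(project_to_colony_plane(dataset), colony_buffer_km)
  tracks <- interpolate_dataset(ds, interval_hours)
  maxdist <- mean_max_distance(ds)

  if (identical(ud_percent, "auto")) {
    cal <- fit_ud_distance_calibration(penguin_parameter_tests())
    ud_percent <- ud_from_maxdist(maxdist, cal)
  }
  repr <- NULL
  if (identical(pt, "auto")) {
    repr <- bootstrap_inclusion_curve(tracks, h_km, ud_percent,
                                      n_iterations = 100, seed = seed,
                                      resolution_km = resolution_km)
    pt <- repr$recommended_pt
  }
  uds <- lapply(tracks, estimate_ud, h_km = h_km,
                resolution_km = resolution_km)
  cores <- lapply(uds, core_area, ud_percent = ud_percent)
  raster <- usage_raster(cores)
  site <- delineate(raster, pt,
                    provenance = list(colony = ds$colony$name,
                                      species = ds$colony$species,
                                      stage = ds$colony$stage,
                                      device = ds$device,
                                      h_km = h_km, ud_percent = ud_percent))
  est <- estimate_population(pt / 100, max_fraction, ds$colony$size_pairs,
                             species = ds$colony$species,
                             site = ds$colony$name, stage = ds$colony$stage)
  assessment <- assess_criteria(list(est))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gj <- file.path(out_dir, "candidate_site.geojson")
    write_geojson(site, ds$colony, gj,
                  properties = site$provenance)
    acsv <- file.path(out_dir, "assessment.csv")
    utils::write.csv(assessment$estimates, acsv, row.names = FALSE)
    rep_js <- file.path(out_dir, "run_report.json")
    params <- list(h_km = h_km, ud_percent = ud_percent, pt = pt,
                   interval_hours = interval_hours,
                   colony_buffer_km = colony_buffer_km,
                   resolution_km = resolution_km, seed = seed)
    tf <- tempfile(); writeLines(jsonlite::toJSON(params, auto_unbox = TRUE), tf)
    jsonlite::write_json(list(
      params = params, config_md5 = unname(tools::md5sum(tf)),
      colony = ds$colony$name, species = ds$colony$species,
      stage = ds$colony$stage, n_birds = length(ds$tracks),
      mean_maxdist_km = maxdist, area_km2 = site$area_km2,
      triggered = assessment$triggered,
      package_version = as.character(utils::packageVersion("pengiba"))),
      rep_js, auto_unbox = TRUE)
    unlink(tf)
    files <- c(site_geojson = gj, assessment_csv = acsv, report_json = rep_js)
  }
  structure(list(site = site, assessment = assessment, estimate = est,
                 params = list(h_km = h_km, ud_percent = ud_percent, pt = pt),
                 repr = repr, mean_maxdist_km = maxdist, files = files),
            class = "pengiba_run")
}

#' @export
print.pengiba_run <- function(x, ...) {
  cat("<pengiba_run>\n")
  cat(sprintf("  params: h = %g km, UD%% = %.1f, PT = %g%%\n",
              x$params$h_km, x$params$ud_percent, x$params$pt))
  cat(sprintf("  site area %g km2; mean max distance %.1f km\n",
              x$site$area_km2, x$mean_maxdist_km))
  cat("  criteria:", if (length(x$assessment$triggered))
    paste(x$assessment$triggered, collapse = ", ") else "none", "\n")
  invisible(x)
}
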