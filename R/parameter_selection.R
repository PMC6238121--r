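# Test/validation splitting, the (h x UD% x PT) grid search, asymptote-based
# optimum selection, the UD%~distance calibration, and the stage comparison
# statistics.

#' Split a dataset into test birds and validation positions
#'
#' The split is at the individual level: a bird's fixes are wholly on one
#' side. The test side keeps full tracks (for interpolation and UD
#' estimation); the validation side is returned as bare positions, the
#' protocol's hold-out for the inclusion metric.
#'
#' @param dataset a projected, filtered [tracking_dataset()] with >= 4 birds.
#' @param fraction fraction of birds assigned to the test side (0 < f < 1),
#'   default 0.5.
#' @param seed integer seed; the partition is reproducible.
#' @return list with `test` (a `tracking_dataset`) and
#'   `validation_positions` (data frame `bird_id`, `x`, `y`).
#' @export
split_test_validation <- function(dataset, fraction = 0.5, seed = 1) {
  stopifnot(inherits(dataset, "tracking_dataset"), isTRUE(dataset$projected))
  n <- length(dataset$tracks)
  if (n < 4) stop("need at least 4 birds to split, got ", n)
  n_test <- round(n * fraction)
  if (n_test < 1 || n_test > n - 1)
    stop("fraction ", fraction, " leaves an empty test or validation side")
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  test <- dataset
  test$tracks <- dataset$tracks[test_idx]
  vp <- do.call(rbind, lapply(dataset$tracks[-test_idx], function(t)
    data.frame(bird_id = t$bird_id, x = t$x, y = t$y)))
  rownames(vp) <- NULL
  list(test = test, validation_positions = vp)
}

#' Full parameter grid search over (h, UD%, PT)
#'
#' For every combination: per-bird kernel UD at `h`, core at `UD%`, usage
#' raster, delineation at `PT`, then site area and inclusion of the
#' validation positions. A failing combination is marked `failed` rather
#' than aborting the grid. The default grids (h = 1..10 km, UD% = 50..80 by
#' 5, PT in {10, 12.5, 20}) give 210 combinations.
#'
#' @param test_tracks named list of `interp_track` objects (the test birds,
#'   already interpolated).
#' @param validation_positions data frame with `x`, `y` (km).
#' @param h_values,ud_values,pt_values parameter grids; duplicates are
#'   dropped with a warning.
#' @param resolution_km UD grid resolution.
#' @return a data frame of class `param_grid` with columns `h_km`,
#'   `ud_percent`, `pt`, `area_km2`, `inclusion`, `failed`.
#' @export
grid_search <- function(test_tracks, validation_positions,
                        h_values = 1:10, ud_values = seq(50, 80, 5),
                        pt_values = c(10, 12.5, 20), resolution_km = 1) {
  dedup <- function(v, nm) {
    if (anyDuplicated(v)) warning("duplicate ", nm, " values dropped")
    sort(unique(v))
  }
  h_values <- dedup(h_values, "h"); ud_values <- dedup(ud_values, "UD%")
  pt_values <- dedup(pt_values, "PT")
  stopifnot(length(h_values) >= 1, length(ud_values) >= 1,
            length(pt_values) >= 1, length(test_tracks) >= 1)
  out <- vector("list", length(h_values) * length(ud_values) * length(pt_values))
  r <- 0L
  for (h in h_values) {
    uds <- tryCatch(lapply(test_tracks, estimate_ud, h_km = h,
                           resolution_km = resolution_km),
                    error = identity)
    for (ud in ud_values) {
      raster <- tryCatch({
        if (inherits(uds, "error")) stop(uds)
        usage_raster(lapply(uds, core_area, ud_percent = ud))
      }, error = identity)
      for (pt in pt_values) {
        r <- r + 1L
        res1 <- tryCatch({
          if (inherits(raster, "error")) stop(raster)
          site <- suppressWarnings(delineate(raster, pt))
          data.frame(h_km = h, ud_percent = ud, pt = pt,
                     area_km2 = site$area_km2,
                     inclusion = inclusion(site, validation_positions),
                     failed = FALSE)
        }, error = function(e)
          data.frame(h_km = h, ud_percent = ud, pt = pt, area_km2 = NA_real_,
                     inclusion = NA_real_, failed = TRUE))
        out[[r]] <- res1
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("param_grid", "data.frame")
  res
}

#' Select the optimum parameter combination from grid results
#'
#' Results are ordered by site area (ascending; ties by smaller h then
#' smaller UD%). The optimum is the first combination from which every
#' successive relative change in inclusion along the area-ordered curve
#' stays below 5% - the point where the inclusion-area curve reaches its
#' asymptote, minimizing site area at near-maximal inclusion. If no
#' combination satisfies the rule the maximum-inclusion result is returned
#' with a warning.
#'
#' @param results a [grid_search()] data frame.
#' @param tol_pct asymptote tolerance on successive relative inclusion
#'   change, percent (default 5).
#' @return the selected row (single-row data frame) with attribute
#'   `asymptote_reached`.
#' @export
select_optimum <- function(results, tol_pct = 5) {
  ok <- results[!results$failed & is.finite(results$area_km2), , drop = FALSE]
  if (nrow(ok) < 2) stop("need at least 2 non-failed grid results")
  ok <- ok[order(ok$area_km2, ok$h_km, ok$ud_percent), , drop = FALSE]
  m <- nrow(ok)
  incl <- ok$inclusion
  prev <- incl[-m]; nxt <- incl[-1]
  rel <- ifelse(prev > 0, abs(nxt - prev) / prev, ifelse(nxt == 0, 0, Inf))
  below <- rel < tol_pct / 100
  # largest suffix of all-below changes; candidate starts there
  bad <- which(!below)
  k <- if (length(bad)) max(bad) + 1L else 1L
  if (k > m - 1) {
    warning("inclusion never reaches a <", tol_pct,
            "% asymptote; returning the maximum-inclusion result")
    pick <- ok[which.max(ok$inclusion), , drop = FALSE]
    attr(pick, "asymptote_reached") <- FALSE
    return(pick)
  }
  pick <- ok[k, , drop = FALSE]
  attr(pick, "asymptote_reached") <- TRUE
  rownames(pick) <- NULL
  pick
}

#' Re-run the pipeline around an optimum to gauge sensitivity
#'
#' Perturbs the optimum by +/- `dh` km in bandwidth and +/- `dud` in UD% and
#' reports the percent change in site area and inclusion relative to the
#' optimum, at the optimum's PT.
#'
#' @param test_tracks,validation_positions as in [grid_search()].
#' @param optimum a row from [select_optimum()].
#' @param dh,dud perturbation sizes (default 1 km and 5 UD points).
#' @param resolution_km UD grid resolution.
#' @return data frame of perturbed runs with `d_area_pct`, `d_inclusion_pct`.
#' @export
sensitivity_around_optimum <- function(test_tracks, validation_positions,
                                       optimum, dh = 1, dud = 5,
                                       resolution_km = 1) {
  hs <- unique(pmax(optimum$h_km + c(-dh, 0, dh), 0.5))
  uds <- unique(pmin(99, pmax(1, optimum$ud_percent + c(-dud, 0, dud))))
  g <- grid_search(test_tracks, validation_positions, h_values = hs,
                   ud_values = uds, pt_values = optimum$pt,
                   resolution_km = resolution_km)
  ref <- g[g$h_km == optimum$h_km & g$ud_percent == optimum$ud_percent, ]
  g$d_area_pct <- 100 * (g$area_km2 - ref$area_km2) / ref$area_km2
  g$d_inclusion_pct <- 100 * (g$inclusion - ref$inclusion) /
    ifelse(ref$inclusion > 0, ref$inclusion, NA)
  g
}

#' Calibrate core UD% against trip range
#'
#' Ordinary least squares of the per-dataset optimum UD% on the mean maximum
#' distance travelled from the colony, with the Pearson correlation test.
#' On the ten GPS chinstrap test datasets this yields
#' `UD% = 0.18773 * dist + 53.21025` with r = 0.89.
#'
#' @param summaries data frame with columns `mean_max_distance_km` and
#'   `best_ud_percent` (one row per dataset; >= 3 rows).
#' @return an object of class `calibration_fit` with `slope`, `intercept`,
#'   `pearson_r`, `p_value`, `n`. Methods: `print`, `coef`, `predict`.
#' @export
fit_ud_distance_calibration <- function(summaries) {
  d <- summaries$mean_max_distance_km
  u <- summaries$best_ud_percent
  if (length(d) < 3) stop("calibration needs at least 3 datasets")
  if (stats::var(d) == 0) stop("zero variance in mean max distance")
  f <- stats::lm(u ~ d)
  ct <- stats::cor.test(d, u)
  structure(list(slope = unname(stats::coef(f)[2]),
                 intercept = unname(stats::coef(f)[1]),
                 pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(d)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> UD%% = %.5f * maxdist_km + %.5f\n",
              x$slope, x$intercept))
  cat(sprintf("  Pearson r = %.2f, p = %.4g, n = %d\n",
              x$pearson_r, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.calibration_fit <- function(object, newdata, ...) {
  d <- if (is.data.frame(newdata)) newdata$mean_max_distance_km else newdata
  ud_from_maxdist(d, object)
}

#' Core UD% from mean maximum trip distance
#'
#' Evaluates the linear calibration and clamps to the tested range
#' \[50, 80\] (extrapolation beyond tested UD percentages is unsupported).
#'
#' @param mean_maxdist_km mean (over birds) maximum distance from the colony,
#'   km (>= 0).
#' @param fit a [fit_ud_distance_calibration()] result.
#' @return UD percentage in \[50, 80\].
#' @export
ud_from_maxdist <- function(mean_maxdist_km, fit) {
  stopifnot(all(mean_maxdist_km >= 0))
  pmin(80, pmax(50, fit$slope * mean_maxdist_km + fit$intercept))
}

#' Welch t-test of inclusion between breeding stages
#'
#' Compares per-dataset inclusion values between brood and incubation (other
#' stages are excluded) with the unequal-variance two-sample t-test and
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param summaries data frame with columns `stage` and `inclusion`.
#' @param stages the two stages compared, first minus second.
#' @return list with `t`, `df`, `p_value` and `means` (named by stage).
#' @export
compare_stage_inclusion <- function(summaries,
                                    stages = c("brood", "incubation")) {
  stopifnot(length(stages) == 2)
  g1 <- summaries$inclusion[summaries$stage == stages[1]]
  g2 <- summaries$inclusion[summaries$stage == stages[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each compared stage needs at least 2 datasets")
  if (stats::var(g1) == 0 && stats::var(g2) == 0)
    stop("zero variance in both stages; t statistic undefined")
  tt <- stats::t.test(g1, g2)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       means = stats::setNames(c(mean(g1), mean(g2)), stages))
}

#' Correlation of the optimum bandwidth with trip range
#'
#' Pearson correlation (with the two-sided t-transform p-value) between the
#' per-dataset best h and mean maximum distance from the colony.
#'
#' @param summaries data frame with columns `best_h_km` and
#'   `mean_max_distance_km` (>= 3 rows).
#' @return list with `r`, `p_value`, `n`.
#' @export
correlate_h_distance <- function(summaries) {
  h <- summaries$best_h_km; d <- summaries$mean_max_distance_km
  if (length(h) < 3) stop("need at least 3 datasets")
  if (stats::var(d) == 0 || stats::var(h) == 0) stop("zero variance")
  ct <- stats::cor.test(d, h)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(h))
}

#' Mean maximum distance from the colony over birds
#'
#' @param dataset a projected [tracking_dataset()].
#' @return mean over birds of each bird's maximum distance (km) from (0, 0).
#' @export
mean_max_distance <- function(dataset) {
  stopifnot(isTRUE(dataset$projected))
  mean(vapply(dataset$tracks, function(t) max(sqrt(t$x^2 + t$y^2)), 0))
}
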