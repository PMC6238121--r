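# Bootstrap assessment of how representative the tracked sample is of the
# colony: inclusion of held-out birds in the pooled core area as a function
# of subsample size, fitted to a saturating curve, mapped to the population
# threshold (PT).

.PT_BANDS <- c(high = 90, mid = 80)   # representativeness >= 90 -> PT 10; 80-90 -> 12.5; else 20

#' Bootstrap inclusion curve and representativeness of a tracked sample
#'
#' For each subsample size `i` in `1..n-1`, repeatedly draws `i` birds
#' without replacement, pools their interpolated positions into one kernel UD
#' (bandwidth `h_km`), takes the `ud_percent` core, and measures the
#' percentage of the left-out birds' positions inside it. Mean inclusion
#' versus `i` is fitted with the single-saturation curve `y = a i / (b + i)`;
#' representativeness is `100 * fitted(n) / a = 100 n / (b + n)`. The
#' recommended PT is 10% when representativeness is at least 90%, 12.5%
#' between 80 and 90%, and the precautionary 20% below 80% (also used when
#' the saturating fit fails).
#'
#' @param tracks named list of `interp_track` objects (>= 4 birds).
#' @param h_km kernel bandwidth (km).
#' @param ud_percent core UD percentage.
#' @param n_iterations bootstrap iterations per subsample size (>= 50).
#' @param seed integer seed; results are a deterministic function of the
#'   inputs and this seed.
#' @param resolution_km UD grid resolution.
#' @return an object of class `repr_result`: `curve` (mean inclusion per
#'   subsample size), `fit` (`a`, `b`, or `NULL` on failure),
#'   `representativeness` (percent), `recommended_pt`, `flagged`.
#' @export
bootstrap_inclusion_curve <- function(tracks, h_km, ud_percent,
                                      n_iterations = 100, seed = 1,
                                      resolution_km = 1) {
  n <- length(tracks)
  if (n < 4) stop("representativeness needs at least 4 birds, got ", n)
  if (n_iterations < 50) stop("n_iterations must be at least 50")
  set.seed(seed)
  pos <- lapply(tracks, function(t) cbind(t$x, t$y))
  sizes <- seq_len(n - 1)
  mean_incl <- numeric(length(sizes))
  for (i in sizes) {
    acc <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      take <- sample.int(n, i)
      pooled <- do.call(rbind, pos[take])
      ud <- estimate_ud(data.frame(x = pooled[, 1], y = pooled[, 2]),
                        h_km, resolution_km)
      core <- core_area(ud, ud_percent)
      held <- do.call(rbind, pos[-take])
      acc[it] <- 100 * mean(.points_in_cells(held[, 1], held[, 2],
                                             core$cells, core$res))
    }
    mean_incl[i] <- mean(acc)
  }
  curve <- data.frame(n_sampled = sizes, mean_inclusion = mean_incl)

  fit <- tryCatch({
    a0 <- max(mean_incl)
    b0 <- max(0.5, sizes[which(mean_incl >= a0 / 2)[1]])
    f <- tryCatch(
      stats::nls(mean_inclusion ~ a * n_sampled / (b + n_sampled),
                 data = curve, start = list(a = a0, b = b0),
                 algorithm = "port", lower = c(a = 1e-6, b = 1e-6)),
      error = function(e)
        minpack.lm::nlsLM(mean_inclusion ~ a * n_sampled / (b + n_sampled),
                          data = curve, start = list(a = a0, b = b0),
                          lower = c(1e-6, 1e-6)))
    as.list(stats::coef(f))
  }, error = function(e) NULL)

  if (is.null(fit)) {
    repr <- NA_real_; pt <- 20; flagged <- TRUE
  } else {
    repr <- min(100, 100 * n / (fit$b + n))
    pt <- if (repr >= .PT_BANDS["high"]) 10
          else if (repr >= .PT_BANDS["mid"]) 12.5 else 20
    flagged <- FALSE
  }
  structure(list(curve = curve, fit = fit, representativeness = repr,
                 recommended_pt = pt, n = n, h_km = h_km,
                 ud_percent = ud_percent, flagged = flagged),
            class = "repr_result")
}

#' @export
print.repr_result <- function(x, ...) {
  cat("<repr_result>", x$n, "birds, UD", x$ud_percent, "%, h =", x$h_km, "km\n")
  if (x$flagged)
    cat("  saturating fit failed; precautionary PT 20%\n")
  else
    cat(sprintf("  representativeness %.1f%% -> recommended PT %g%%\n",
                x$representativeness, x$recommended_pt))
  invisible(x)
}

#' @export
plot.repr_result <- function(x, ...) {
  graphics::plot(x$curve$n_sampled, x$curve$mean_inclusion, pch = 16,
                 xlab = "birds sampled", ylab = "mean inclusion (%)",
                 ylim = c(0, 100), ...)
  if (!is.null(x$fit))
    graphics::curve(x$fit$a * t / (x$fit$b + t), xname = "t", add = TRUE)
  invisible(x)
}
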