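# At-sea abundance estimates, the global A4ii / A4iii congregation criteria,
# and merging of overlapping candidate sites into final marine IBAs.

#' Global criteria thresholds for the three Pygoscelis species
#'
#' 1%-of-global-population thresholds (breeding pairs) used by criterion
#' A4ii, and the 10,000-pair multi-species threshold of A4iii.
#'
#' @param one_percent_pairs named vector of 1% thresholds per species.
#' @param a4iii_pairs the A4iii threshold.
#' @return a list of class `criteria_thresholds`.
#' @export
iba_thresholds <- function(one_percent_pairs = c(adelie = 37900,
                                                 chinstrap = 27000,
                                                 gentoo = 3900),
                           a4iii_pairs = 10000) {
  stopifnot(all(one_percent_pairs > 0), a4iii_pairs > 0)
  structure(list(one_percent_pairs = one_percent_pairs,
                 a4iii_pairs = a4iii_pairs),
            class = "criteria_thresholds")
}

# round half away from zero (so 6,666.6 -> 6,667)
.round_half_up <- function(x) trunc(x + 0.5 * sign(x))

#' At-sea population estimate for a candidate site
#'
#' Minimum and maximum numbers of pairs using the site: the PT fraction (the
#' assumed minimum share of the colony using the site) and the maximum
#' share, each multiplied by the colony size and rounded half away from
#' zero.
#'
#' @param pt_fraction minimum fraction of birds using the site (0, 1];
#'   the protocol's precautionary value is 0.20.
#' @param max_fraction maximum fraction (>= `pt_fraction`, <= 1).
#' @param colony_pairs colony size in breeding pairs.
#' @param species,site optional labels carried through to
#'   [assess_criteria()].
#' @param stage optional breeding-stage label.
#' @return an object of class `population_estimate` with `min_pairs` and
#'   `max_pairs`.
#' @export
estimate_population <- function(pt_fraction, max_fraction = 1, colony_pairs,
                                species = NA_character_, site = NA_character_,
                                stage = NA_character_) {
  if (!(pt_fraction > 0 && pt_fraction <= max_fraction && max_fraction <= 1))
    stop("need 0 < pt_fraction <= max_fraction <= 1")
  stopifnot(colony_pairs > 0)
  structure(list(species = species, site = site, stage = stage,
                 min_pairs = .round_half_up(pt_fraction * colony_pairs),
                 max_pairs = .round_half_up(max_fraction * colony_pairs),
                 pt_fraction = pt_fraction, max_fraction = max_fraction,
                 colony_pairs = colony_pairs),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("<population_estimate> %s @ %s: %s-%s pairs (of %s)\n",
              x$species, x$site, format(x$min_pairs, big.mark = ","),
              format(x$max_pairs, big.mark = ","),
              format(x$colony_pairs, big.mark = ",")))
  invisible(x)
}

#' Assess the A4 congregation criteria for a (merged) site
#'
#' A4ii triggers when any single species' maximum estimate exceeds its 1%
#' global threshold (strict `>`); A4iii when the maxima summed over species
#' (each species counted once, at its largest estimate across stages) exceed
#' 10,000 pairs. Criteria are assessed on the maximum estimates.
#'
#' @param estimates list of [estimate_population()] objects for one site.
#' @param thresholds an [iba_thresholds()] object.
#' @param site_id optional site label.
#' @return an object of class `iba_assessment`: `triggered` (character
#'   subset of `c("A4ii", "A4iii")`), `per_species_max`, and the estimates
#'   table.
#' @export
assess_criteria <- function(estimates, thresholds = iba_thresholds(),
                            site_id = NULL) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, TRUE, "population_estimate")))
  sp <- vapply(estimates, function(e) e$species, "")
  unknown <- setdiff(unique(sp), names(thresholds$one_percent_pairs))
  if (length(unknown))
    stop("no 1% threshold for species: ", paste(unknown, collapse = ", "))
  mx <- vapply(estimates, function(e) e$max_pairs, 0)
  per_species <- tapply(mx, sp, max)
  a4ii <- any(per_species > thresholds$one_percent_pairs[names(per_species)])
  a4iii <- sum(per_species) > thresholds$a4iii_pairs
  tab <- do.call(rbind, lapply(estimates, function(e)
    data.frame(site = e$site, species = e$species, stage = e$stage,
               min_pairs = e$min_pairs, max_pairs = e$max_pairs)))
  structure(list(site_id = site_id %||% tab$site[1],
                 triggered = c("A4ii", "A4iii")[c(a4ii, a4iii)],
                 per_species_max = per_species, estimates = tab,
                 thresholds = thresholds),
            class = "iba_assessment")
}

#' @export
print.iba_assessment <- function(x, ...) {
  cat("<iba_assessment>", x$site_id, "-",
      if (length(x$triggered)) paste(x$triggered, collapse = ", ")
      else "no criteria met", "\n")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Merge overlapping candidate sites into one marine IBA polygon
#'
#' Geometric union of candidate sites sharing a colony grid (equal
#' resolution); provenance lists every contributing candidate. Areas are
#' additive exactly when the candidates are pairwise disjoint.
#'
#' @param candidates list of [delineate()] results (>= 1).
#' @return an object of class `candidate_site` (the merged site) whose
#'   `provenance` is the concatenated list of the inputs' provenance.
#' @export
merge_candidates <- function(candidates) {
  stopifnot(length(candidates) >= 1,
            all(vapply(candidates, inherits, TRUE, "candidate_site")))
  res <- candidates[[1]]$res
  if (!all(vapply(candidates, function(c) c$res, 0) == res))
    stop("candidates must share one grid resolution")
  allc <- do.call(rbind, lapply(candidates, function(c) c$cells))
  cells <- allc[!duplicated(.cell_key(allc)), , drop = FALSE]
  structure(list(cells = cells, res = res,
                 rings = cells_to_rings(cells, res),
                 area_km2 = nrow(cells) * res^2,
                 pt = unique(vapply(candidates, function(c) c$pt, 0)),
                 n_individuals = NA_integer_,
                 provenance = lapply(candidates, function(c) c$provenance)),
            class = "candidate_site")
}
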