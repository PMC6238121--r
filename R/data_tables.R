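# Bundled reference tables: colony sizes, the per-dataset parameter-test
# summaries used for the UD%~distance calibration and stage statistics, and
# the published site population table used to replay the criteria checks.

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "pengiba")
  if (p == "") stop("bundled table ", f, " not found; is pengiba installed?")
  p
}

#' Colony summary table
#'
#' One row per tracking dataset: species, site group, colony, breeding
#' stage, device, number of tracked birds, whether the dataset was in the
#' parameter-test subsample, and colony size in breeding pairs.
#' @return data frame.
#' @export
penguin_colony_table <- function() {
  utils::read.csv(.extdata("colony_sizes.csv"), stringsAsFactors = FALSE)
}

#' Parameter-test summary per GPS chinstrap dataset
#'
#' One row per tested dataset: sample size, mean maximum distance from the
#' colony, the first-passage-time (ARS) bandwidth, the grid-search optimum
#' bandwidth and UD%, the resulting candidate-site area and the validation
#' inclusion. This is the input to [fit_ud_distance_calibration()],
#' [compare_stage_inclusion()] and [correlate_h_distance()].
#' @return data frame.
#' @export
penguin_parameter_tests <- function() {
  utils::read.csv(.extdata("param_tests.csv"), stringsAsFactors = FALSE)
}

#' Published site population table
#'
#' Per (site, species) minimum/maximum at-sea population estimates with the
#' matching colony size, used to replay the abundance and criteria
#' calculations.
#' @return data frame.
#' @export
penguin_iba_table <- function() {
  utils::read.csv(.extdata("iba_populations.csv"), stringsAsFactors = FALSE)
}
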