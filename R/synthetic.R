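# Synthetic inputs: everything the model needs that is not a published
# number — the simulated patient population, a stand-in all-cause mortality
# life table, post-fracture excess-mortality multipliers, and small DRG cost
# tables exercising the weighted-average costing method.

#' Specification of the simulated patient population
#'
#' Ages are drawn from a normal distribution truncated to
#' `[age_min, age_max]`; prior-fracture status is an independent Bernoulli
#' flag. Defaults match the published cohort: mean age 70.5 years,
#' SD 9.7 years, truncation to \[50, 100\] (fracture risks are undefined
#' below 50), prior-fracture prevalence 59.7\%.
#'
#' @param age_mean Mean age in years.
#' @param age_sd Standard deviation of age in years.
#' @param age_min,age_max Truncation bounds in years.
#' @param prior_fracture_prev Prevalence of a prior fracture at baseline.
#' @return An object of class `bp_population_spec`.
#' @export
population_spec <- function(age_mean = 70.5, age_sd = 9.7,
                            age_min = 50, age_max = 100,
                            prior_fracture_prev = 0.597) {
  if (age_sd <= 0) stop("age_sd: must be > 0")
  if (age_mean < age_min || age_mean > age_max)
    stop("age_mean: must lie within [age_min, age_max]")
  if (prior_fracture_prev < 0 || prior_fracture_prev > 1)
    stop("prior_fracture_prev: must be in [0, 1]")
  structure(list(age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 prior_fracture_prev = prior_fracture_prev),
            class = "bp_population_spec")
}

#' Generate a baseline patient population
#'
#' Draws `n` women with truncated-normal ages and independent Bernoulli
#' prior-fracture flags. Reproducible: the same seed yields the identical
#' population.
#'
#' @param spec A [population_spec()].
#' @param n Number of patients (>= 1).
#' @param seed Integer seed for the draws.
#' @return Data frame with columns `id`, `age` (years, continuous),
#'   `prior_fracture` (logical).
#' @export
#' @examples
#' pop <- generate_population(population_spec(), n = 1000, seed = 1)
#' mean(pop$age); mean(pop$prior_fracture)
generate_population <- function(spec = population_spec(), n, seed) {
  if (!inherits(spec, "bp_population_spec"))
    stop("spec must be a bp_population_spec")
  if (n < 1) stop("n: must be >= 1")
  set.seed(seed)
  plo <- stats::pnorm((spec$age_min - spec$age_mean) / spec$age_sd)
  phi <- stats::pnorm((spec$age_max - spec$age_mean) / spec$age_sd)
  u <- stats::runif(n, plo, phi)
  age <- spec$age_mean + spec$age_sd * stats::qnorm(u)
  age <- pmin(pmax(age, spec$age_min), spec$age_max)  # guard fp round-off
  prior <- stats::runif(n) < spec$prior_fracture_prev
  data.frame(id = seq_len(n), age = age, prior_fracture = prior)
}

#' Synthetic Gompertz life table
#'
#' Stand-in for an unpublished national all-cause female mortality table:
#' annual death probability `q(age) = min(1, scale * exp(shape * age))` on
#' integer ages 50..110, with the terminal age forced to `q = 1`. The
#' defaults are a documented synthetic assumption — q(70) = 0.012 and a
#' doubling of mortality every 8 years — not published values.
#'
#' @param shape Gompertz shape (per year of age), > 0.
#' @param scale Gompertz scale (baseline hazard), > 0.
#' @return A data frame of class `bp_life_table` with columns `age`, `qx`.
#' @export
#' @examples
#' lt <- synthetic_life_table()
#' lt$qx[lt$age == 70] / lt$qx[lt$age == 62]  # ~2: doubling every 8 years
synthetic_life_table <- function(shape = log(2) / 8,
                                 scale = 0.012 * exp(-70 * log(2) / 8)) {
  if (shape <= 0) stop("shape: must be > 0")
  if (scale <= 0) stop("scale: must be > 0")
  age <- 50:110
  qx <- pmin(1, scale * exp(shape * age))
  qx[length(qx)] <- 1
  structure(data.frame(age = age, qx = qx),
            class = c("bp_life_table", "data.frame"))
}

#' Annual death probability from a life table
#'
#' Ages are floored to whole years and clamped to the table's range.
#'
#' @param life_table A `bp_life_table` (or any data frame with `age`, `qx`).
#' @param age Numeric vector of ages in years.
#' @return Annual death probabilities.
#' @export
life_table_q <- function(life_table, age) {
  a <- pmin(pmax(floor(age), min(life_table$age)), max(life_table$age))
  life_table$qx[match(a, life_table$age)]
}

#' Post-fracture excess-mortality multipliers
#'
#' First-year all-cause mortality hazard multipliers after a hip fracture
#' and after a clinically diagnosed (symptomatic) vertebral fracture. The
#' source values behind the model are not published; these defaults are
#' synthetic stand-ins and are fully configurable. No excess mortality is
#' applied after a wrist fracture.
#'
#' @param hip Multiplier applied within `window_years` of a hip fracture.
#' @param vertebral Multiplier within `window_years` of a symptomatic
#'   vertebral fracture.
#' @param window_years Length of the excess window in whole years.
#' @return An object of class `bp_excess`.
#' @export
excess_mortality <- function(hip = 2.5, vertebral = 2.0, window_years = 1) {
  if (hip < 1) stop("hip: multiplier must be >= 1")
  if (vertebral < 1) stop("vertebral: multiplier must be >= 1")
  if (window_years < 1) stop("window_years: must be >= 1")
  structure(list(hip = hip, vertebral = vertebral,
                 window_years = window_years, synthetic = TRUE),
            class = "bp_excess")
}

#' DRG cost table fixtures
#'
#' Small disease-related-group (DRG) hospital-stay cost tables for the
#' weighted-average fracture-costing method. The site presets are synthetic
#' decompositions into a few DRG rows whose stay counts and aggregate cost
#' (sum of count x unit cost) reproduce the published national totals:
#' vertebra 26,490 stays / 93,325,278 EUR; hip 53,376 / 372,849,923 EUR;
#' wrist 10,394 / 18,775,427 EUR. The row split itself is synthetic. The
#' `"toy"` preset is a 2-row table for unit tests.
#'
#' @param preset One of `"vertebra"`, `"hip"`, `"wrist"`, `"toy"`.
#' @return Data frame with columns `drg_id`, `count`, `unit_cost`.
#' @export
#' @examples
#' t <- fixture_drg_table("vertebra")
#' sum(t$count)                   # 26490
#' weighted_average_drg_cost(t)   # 3523
fixture_drg_table <- function(preset = c("vertebra", "hip", "wrist", "toy")) {
  preset <- match.arg(preset)
  tab <- switch(preset,
    vertebra = .drg_split("V", total_count = 26490, total_cost = 93325278,
                          counts = c(15000, 8000), costs = c(2085, 4000)),
    hip = .drg_split("H", total_count = 53376, total_cost = 372849923,
                     counts = c(30000, 15000), costs = c(7170, 5000)),
    wrist = .drg_split("W", total_count = 10394, total_cost = 18775427,
                       counts = c(6000), costs = c(2615)),
    toy = data.frame(drg_id = c("T01", "T02"), count = c(1, 3),
                     unit_cost = c(100, 200))
  )
  if (any(tab$count < 0) || any(tab$unit_cost < 0) || !any(tab$count > 0))
    stop("invalid DRG table fixture")
  tab
}

# Split a national (count, aggregate cost) pair into fixed rows plus one
# balancing row so that both totals are reproduced.
.drg_split <- function(prefix, total_count, total_cost, counts, costs) {
  n_last <- total_count - sum(counts)
  c_last <- (total_cost - sum(counts * costs)) / n_last
  data.frame(
    drg_id = paste0(prefix, sprintf("%02d", seq_len(length(counts) + 1))),
    count = c(counts, n_last),
    unit_cost = c(costs, c_last)
  )
}

#' Write or read a population CSV
#'
#' Columns `id`, `age`, `prior_fracture`; full double precision is kept so
#' the round trip is exact.
#'
#' @param population Data frame as produced by [generate_population()].
#' @param path CSV file path.
#' @return `write_population_csv()` returns `path` invisibly;
#'   `read_population_csv()` returns the population data frame.
#' @export
write_population_csv <- function(population, path) {
  df <- population
  df$age <- sprintf("%.17g", df$age)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  df$prior_fracture <- as.logical(df$prior_fracture)
  df
}

#' Record a run manifest
#'
#' Writes a JSON manifest carrying the seed, the simulation settings and the
#' complete parameter bundle alongside an analysis output, so that any run
#' can be reproduced from its manifest alone.
#'
#' @param path JSON file path.
#' @param seed Integer seed used for the run.
#' @param params The `bp_params` bundle used.
#' @param settings Optional [simulation_settings()] used.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, params, settings = NULL) {
  man <- list(
    package = "persistcea",
    version = as.character(utils::packageVersion("persistcea")),
    seed = seed,
    settings = if (!is.null(settings)) unclass(settings),
    parameters = jsonlite::fromJSON(.params_json(params))
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.params_json <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  paste(readLines(tmp), collapse = "\n")
}
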