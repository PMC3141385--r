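# Cost-effectiveness reporting: pairwise ICERs with dominance detection,
# the Student comparison of mean costs, the persistence-to-cost sweep, the
# national budget extrapolation and the fracture-cost distribution.

#' Incremental cost-effectiveness from two arm summaries
#'
#' Core ICER arithmetic on mean per-patient costs and bad-outcome
#' proportions (fractured women or premature deaths). `b` is the
#' intervention compared against `a`. The intervention *dominates* when it
#' is both cheaper (`delta_cost < 0`) and has fewer bad outcomes
#' (`delta_effect < 0`); the ratio reported is the magnitude
#' `|delta_cost / delta_effect|` — euros per case avoided — and is undefined
#' (`NA`) when the effect difference is zero.
#'
#' @param cost_a,cost_b Mean cost per patient in euros.
#' @param effect_a,effect_b Proportion with the bad outcome.
#' @param labels Character vector of length 2 naming `a` and `b`.
#' @param effect Name of the effectiveness criterion.
#' @param discounted Logical flag recorded in the result.
#' @return An object of class `bp_icer` with `delta_cost`, `delta_effect`,
#'   `ratio`, `dominant`, plus the labels and flags.
#' @export
#' @examples
#' icer_from_means(3110, 2833, 0.600, 0.491)  # dominant, ~2542 EUR/case
icer_from_means <- function(cost_a, cost_b, effect_a, effect_b,
                            labels = c("a", "b"),
                            effect = "fractured_women", discounted = TRUE) {
  delta_cost <- cost_b - cost_a
  delta_effect <- effect_b - effect_a
  ratio <- if (delta_effect == 0) NA_real_ else abs(delta_cost / delta_effect)
  structure(list(
    comparator = labels[1], intervention = labels[2], effect = effect,
    discounted = discounted,
    delta_cost = delta_cost, delta_effect = delta_effect,
    ratio = ratio,
    dominant = delta_cost < 0 && delta_effect < 0
  ), class = "bp_icer")
}

#' Incremental cost-effectiveness ratio between two simulated arms
#'
#' Compares two [run_alternative()] results: incremental mean total cost
#' per patient (discounted or undiscounted) against the incremental
#' proportion of fractured women or of premature (fracture-related) deaths,
#' both measured over all simulated patients. See [icer_from_means()] for
#' the dominance convention.
#'
#' @param a Comparator arm (`bp_arm_result`).
#' @param b Intervention arm (`bp_arm_result`).
#' @param effect `"fractured_women"` or `"premature_deaths"`.
#' @param discounted Use discounted costs (default) or undiscounted.
#' @return A `bp_icer`.
#' @export
icer <- function(a, b, effect = c("fractured_women", "premature_deaths"),
                 discounted = TRUE) {
  effect <- match.arg(effect)
  stopifnot(inherits(a, "bp_arm_result"), inherits(b, "bp_arm_result"))
  if (a$n != b$n || a$cycles != b$cycles)
    stop("arms must share the same population size and horizon")
  key <- if (discounted) "total_disc" else "total_undisc"
  prop <- function(x) switch(effect,
    fractured_women = x$fractured_women_prop,
    premature_deaths = x$premature_deaths_prop)
  icer_from_means(mean(a$costs[[key]]), mean(b$costs[[key]]),
                  prop(a), prop(b),
                  labels = c(a$alternative, b$alternative),
                  effect = effect, discounted = discounted)
}

#' @export
print.bp_icer <- function(x, ...) {
  cat(sprintf("<bp_icer> %s vs %s (%s, %s)\n", x$intervention, x$comparator,
              x$effect, if (x$discounted) "discounted" else "undiscounted"))
  cat(sprintf("  incremental cost %.0f EUR; incremental effect %+.3f\n",
              x$delta_cost, x$delta_effect))
  if (isTRUE(x$dominant))
    cat(sprintf("  dominant (cheaper, fewer cases): %.0f EUR per case avoided\n",
                x$ratio))
  else cat(sprintf("  ratio: %s EUR per case\n",
                   if (is.na(x$ratio)) "undefined" else sprintf("%.0f", x$ratio)))
  invisible(x)
}

#' Student t comparison of per-patient costs
#'
#' Two-sample Student t-test (equal variances) of mean per-patient costs
#' between two arms, at the 0.05 significance threshold.
#'
#' @param costs_a,costs_b Numeric vectors of per-patient costs (length >= 2).
#' @return List with `statistic`, `p_value`, `significant` and the means.
#' @export
compare_mean_costs <- function(costs_a, costs_b) {
  if (length(costs_a) < 2 || length(costs_b) < 2)
    stop("each cost vector must have length >= 2")
  if (stats::sd(costs_a) == 0 && stats::sd(costs_b) == 0)
    stop("zero variance in both arms: t-test undefined")
  tt <- stats::t.test(costs_a, costs_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < 0.05,
       mean_a = mean(costs_a), mean_b = mean(costs_b))
}

#' Persistence-to-cost sweep
#'
#' Re-runs the engine over a grid of persistence improvements: at mixing
#' weight `lambda` the persistence curve becomes
#' `P_lambda(T) = P(T) + lambda (1 - P(T))`, so `lambda = 0` is the
#' real-world curve and `lambda = 1` ideal persistence. Every level uses
#' the same seed and population (common random numbers). The sweep's
#' x-axis is the one-year persistence `100 * P_lambda(12)` in percent, and
#' the reported slope is the least-squares change in mean total discounted
#' cost per ten percentage points of one-year persistence.
#'
#' @param params Model parameters.
#' @param levels Vector of mixing weights in \[0, 1\] (non-empty).
#' @param settings [simulation_settings()] with
#'   `alternative = "real_world"`.
#' @param population,life_table,excess As for [run_alternative()].
#' @return An object of class `bp_sweep`: `grid` (data frame with `lambda`,
#'   `persistence_1y_pct` and mean per-patient drug, fracture and total
#'   discounted costs) and `slope_per_10pts` (euros per patient per ten
#'   points of persistence; negative means saving).
#' @export
persistence_sweep <- function(params, levels, settings, population,
                              life_table = synthetic_life_table(),
                              excess = excess_mortality()) {
  if (length(levels) == 0) stop("levels must be non-empty")
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (settings$alternative != "real_world")
    stop("sweep settings must use the real_world alternative")
  p12 <- persistence_at(12, params)
  rows <- lapply(levels, function(lam) {
    arm <- run_alternative(params, settings, population, life_table, excess,
                           lambda = lam)
    data.frame(
      lambda = lam,
      persistence_1y_pct = 100 * (lam + (1 - lam) * p12),
      mean_drug_disc = mean(arm$costs$drug_disc),
      mean_fracture_disc = mean(arm$costs$fracture_disc),
      mean_total_disc = mean(arm$costs$total_disc)
    )
  })
  grid <- do.call(rbind, rows)
  slope <- if (nrow(grid) >= 2) {
    fit <- stats::lm(mean_total_disc ~ persistence_1y_pct, data = grid)
    10 * unname(stats::coef(fit)[2])
  } else NA_real_
  structure(list(grid = grid, slope_per_10pts = slope,
                 seed = settings$seed, n = settings$n_patients),
            class = "bp_sweep")
}

#' @export
print.bp_sweep <- function(x, ...) {
  cat(sprintf("<bp_sweep> %d levels, n = %d per level\n", nrow(x$grid), x$n))
  print(x$grid, row.names = FALSE)
  cat(sprintf("  slope: %+.1f EUR per patient per 10 points of 1-year persistence\n",
              x$slope_per_10pts))
  invisible(x)
}

#' National annual budget extrapolation
#'
#' Scales a per-patient cost difference over the model horizon to the
#' national population of diagnosed osteoporotic women, expressed per year:
#' `difference * population / horizon`.
#'
#' @param per_patient_diff Per-patient cost difference over the horizon,
#'   in euros (>= 0).
#' @param population Number of women (> 0), default 1.13 million.
#' @param horizon Horizon in years (> 0), default 10.
#' @return Euros per year.
#' @export
#' @examples
#' national_extrapolation(270)  # 30,510,000 EUR/year
national_extrapolation <- function(per_patient_diff, population = 1130000,
                                   horizon = 10) {
  if (per_patient_diff < 0) stop("per_patient_diff must be >= 0")
  if (population <= 0) stop("population must be > 0")
  if (horizon <= 0) stop("horizon must be > 0")
  per_patient_diff * population / horizon
}

#' Distribution of fracture-management costs among fractured women
#'
#' Mean, SD and histogram bins of per-patient fracture costs restricted to
#' women with at least one cost-incurring (clinical) fracture.
#'
#' @param costs Numeric vector of per-patient fracture costs among
#'   fractured women (non-empty, non-negative).
#' @param binwidth Histogram bin width in euros.
#' @return List with `n`, `mean`, `sd` and `bins` (data frame `lower`,
#'   `upper`, `count`).
#' @export
#' @examples
#' cost_distribution(c(11419, 3305))
cost_distribution <- function(costs, binwidth = 1000) {
  if (length(costs) == 0) stop("costs must be non-empty")
  if (any(costs < 0)) stop("costs must be non-negative")
  upper <- max(ceiling(max(costs) / binwidth), 1) * binwidth
  h <- graphics::hist(costs, breaks = seq(0, upper, by = binwidth),
                      plot = FALSE, right = FALSE)
  list(
    n = length(costs), mean = mean(costs),
    sd = if (length(costs) > 1) stats::sd(costs) else 0,
    bins = data.frame(lower = h$breaks[-length(h$breaks)],
                      upper = h$breaks[-1], count = h$counts)
  )
}
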