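# Cost rewards: discounting, drug-cost accrual, fracture management costs
# and the DRG weighted-average costing method.

#' Discount an amount to present value
#'
#' End-of-cycle discounting at a fixed annual rate:
#' `amount / (1 + rate)^cycle`. A rate of 0 reproduces undiscounted values
#' exactly.
#'
#' @param amount Amount in euros (>= 0).
#' @param cycle Year index, 1-based.
#' @param rate Annual discount rate in \[0, 1).
#' @return Discounted amount in euros.
#' @export
#' @examples
#' discount(105, 1, 0.05)  # 100
discount <- function(amount, cycle, rate) {
  if (any(amount < 0)) stop("amount must be non-negative")
  if (any(cycle < 1)) stop("cycle must be >= 1")
  if (rate < 0) stop("rate must be >= 0")
  amount / (1 + rate)^cycle
}

#' Annual drug cost from a 12-week pack price
#'
#' Converts a price per 12 weeks of treatment into a cost per one-year
#' cycle: `price * weeks_per_year / 12`. The year is treated as 52 weeks by
#' default; a calendar-year convention (365.25 / 7 weeks) differs by less
#' than 0.4\% and can be selected via `weeks_per_year`.
#'
#' In the ideal alternative the full annual amount accrues each cycle while
#' alive; in the real-world alternative it is multiplied by the cycle's
#' drug-exposure fraction ([cycle_drug_exposure()]); in the no-treatment
#' alternative drug cost is zero.
#'
#' @param price_per_12wk Price in euros for 12 weeks of treatment (>= 0).
#' @param weeks_per_year Weeks counted per year (default 52).
#' @return Cost in euros per cycle-year.
#' @export
#' @examples
#' annual_drug_cost(52.23)  # generic: 226.33
#' annual_drug_cost(87.46)  # branded: 379.0
annual_drug_cost <- function(price_per_12wk, weeks_per_year = 52) {
  if (any(price_per_12wk < 0)) stop("price_per_12wk must be >= 0")
  price_per_12wk * weeks_per_year / 12
}

#' Management cost of a fracture event
#'
#' Full direct management cost (hospitalisation plus rehabilitation),
#' charged once at the cycle of the event: hip 11,419 EUR; wrist 3,305 EUR;
#' symptomatic vertebral fracture 5,872 EUR. Morphometric-only
#' (asymptomatic) vertebral fractures consume no resources and cost 0.
#'
#' @param site Fracture site(s): `"vertebra"`, `"hip"` or `"wrist"`.
#' @param symptomatic Logical, recycled; only meaningful for vertebral
#'   events.
#' @param params Model parameters; only `params$costs$management` is used.
#' @return Cost(s) in euros.
#' @export
#' @examples
#' fracture_event_cost("hip")
#' fracture_event_cost("vertebra", symptomatic = FALSE)  # 0
fracture_event_cost <- function(site, symptomatic = TRUE,
                                params = default_parameters()) {
  if (!all(site %in% .SITES))
    stop("unknown fracture site: ",
         paste(setdiff(site, .SITES), collapse = ", "))
  cost <- unname(params$costs$management[site])
  cost[site == "vertebra" & !symptomatic] <- 0
  cost
}

#' Weighted-average cost per hospital stay from a DRG table
#'
#' The national fracture-hospitalisation costing method: the aggregate cost
#' over all disease-related groups divided by the total number of stays,
#' `sum(count * unit_cost) / sum(count)`, reported to the nearest euro.
#'
#' @param table Data frame with columns `count` and `unit_cost` (one row
#'   per DRG), e.g. from [fixture_drg_table()].
#' @return Weighted average cost per stay, in whole euros.
#' @export
#' @examples
#' weighted_average_drg_cost(fixture_drg_table("vertebra"))  # 3523
weighted_average_drg_cost <- function(table) {
  if (!all(c("count", "unit_cost") %in% names(table)))
    stop("DRG table must have columns count and unit_cost")
  if (nrow(table) == 0 || sum(table$count) <= 0)
    stop("DRG table must contain at least one stay")
  if (any(table$count < 0) || any(table$unit_cost < 0))
    stop("DRG counts and unit costs must be non-negative")
  round(sum(table$count * table$unit_cost) / sum(table$count))
}
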