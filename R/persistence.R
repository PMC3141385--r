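# Persistence with weekly oral bisphosphonates and the residual (offset)
# protection remaining after discontinuation. The two curves combine into
# the proportion of an initiating cohort still protected at any month, and
# invert into per-patient discontinuation-time sampling for the
# microsimulation.

#' Proportion of women still on treatment after T months
#'
#' The fitted logarithmic persistence curve `P(T) = 1 - b ln(T)` with
#' `b = 0.196`, clamped to 1 for treatment durations of one month or less
#' (the formula exceeds 1 below T = 1) and held at the floor (20\%) from the
#' floor-onset time (60 months) to the end of the simulation.
#'
#' @param T Months since treatment initiation (vector, >= 0).
#' @param params Model parameters; only `params$persistence` is used.
#' @return Proportion still persistent, in `[floor, 1]`.
#' @export
#' @examples
#' round(100 * persistence_at(c(12, 24, 60)))  # 51 38 20
persistence_at <- function(T, params = default_parameters()) {
  if (any(T < 0)) stop("treatment duration T must be non-negative")
  pp <- params$persistence
  p <- 1 - pp$b * log(pmax(T, 1))
  p <- pmin(pmax(p, pp$floor), 1)
  p[T >= pp$floor_onset] <- pp$floor
  p
}

#' Total protected duration for a given treatment duration
#'
#' Residual-effect model: a woman treated for `T` months is protected
#' against fracture for `y(T) = a exp(k T)` months from initiation
#' (`a = 13.5` months, `k = 0.048` per month), so protection outlasts the
#' treatment itself and about four years of continued treatment protect for
#' the full ten-year horizon. `y(0) = 0`: a woman who never starts gains
#' nothing.
#'
#' @param T Months of treatment (vector, >= 0; `Inf` for never
#'   discontinued).
#' @param params Model parameters; only `params$residual` is used.
#' @return Total protected months since initiation.
#' @export
#' @examples
#' round(protection_duration(c(12, 24)))  # 24 43
protection_duration <- function(T, params = default_parameters()) {
  if (any(T < 0)) stop("treatment duration T must be non-negative")
  y <- params$residual$a * exp(params$residual$k * T)
  y[T == 0] <- 0
  y
}

#' Proportion of an initiating cohort protected at month m
#'
#' Combines persistence and residual protection: a woman is protected at
#' month `m` if she is still on treatment, or discontinued after `T` months
#' with `y(T) >= m`. Since `y` is increasing and persistence decreasing,
#' the protected proportion equals `persistence_at(min(m, T*(m)))` where
#' `T*(m) = ln(m / a) / k` is the shortest treatment duration whose residual
#' protection covers month `m`; for `m <= a` every initiator is protected.
#' The ideal alternative forces 1 and the no-treatment alternative forces 0.
#'
#' @param m Months since initiation (vector, >= 0).
#' @param params Model parameters.
#' @param alternative `"real_world"` (default), `"ideal"` or
#'   `"no_treatment"`.
#' @return Protected proportion in \[0, 1\], non-increasing beyond month `a`.
#' @export
#' @examples
#' protected_proportion(c(0, 12, 120))
protected_proportion <- function(m, params = default_parameters(),
                                 alternative = c("real_world", "ideal",
                                                 "no_treatment")) {
  alternative <- match.arg(alternative)
  if (any(m < 0)) stop("months m must be non-negative")
  if (alternative == "ideal") return(rep(1, length(m)))
  if (alternative == "no_treatment") return(rep(0, length(m)))
  a <- params$residual$a
  k <- params$residual$k
  tstar <- ifelse(m <= a, 0, log(pmax(m, a) / a) / k)  # 0 => persistence 1
  persistence_at(pmin(m, tstar), params)
}

#' Sample a discontinuation time by inverse transform
#'
#' Inverts the persistence curve, treating it as the survival function of
#' time on treatment: a uniform draw below the floor maps to "never
#' discontinued within the horizon" (`Inf`); otherwise
#' `T = exp((1 - u) / b)`, clamped to at least one month. The optional
#' mixing weight `lambda` samples from the improved-persistence curve
#' `P_lambda(T) = P(T) + lambda (1 - P(T))` used by the persistence sweep
#' (`lambda = 0` real world, `lambda = 1` ideal).
#'
#' @param u Uniform(0, 1) draws (strictly inside the interval).
#' @param params Model parameters.
#' @param lambda Mixing weight towards ideal persistence, in \[0, 1\].
#' @return Months to discontinuation; `Inf` for never within the horizon.
#' @export
#' @examples
#' sample_discontinuation(0.5)   # ~12.8 months
#' sample_discontinuation(0.1)   # Inf (below the 20% floor)
sample_discontinuation <- function(u, params = default_parameters(),
                                   lambda = 0) {
  if (any(u <= 0) || any(u >= 1)) stop("u must lie strictly in (0, 1)")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (lambda >= 1) return(rep(Inf, length(u)))
  pp <- params$persistence
  s <- (u - lambda) / (1 - lambda)
  T <- pmax(exp((1 - s) / pp$b), 1)
  T[u < lambda + (1 - lambda) * pp$floor] <- Inf
  T
}

#' Fraction of a cycle-year spent on drug
#'
#' Cohort form (default): the mean of the persistence curve over the 12
#' months of the cycle — the multiplier applied to a full year of drug cost
#' in the real-world alternative. Individual form (when `T_disc` is given):
#' months on drug within the cycle divided by 12, from that woman's
#' discontinuation time. No-treatment is always 0. Cycles beyond the
#' horizon are an error.
#'
#' Drug cost accrues only within the first `params$costs$drug_cost_months_cap`
#' months of treatment (default 48): by then the residual effect already
#' protects for the entire horizon, so in the ideal alternative drug is
#' charged in full for the first four cycles and not thereafter, and a
#' real-world persistent woman stops accruing cost at the cap even if she
#' remains on drug. Set the cap to `Inf` to charge drug over the whole
#' horizon instead.
#'
#' @param cycle Year index, 1-based scalar.
#' @param params Model parameters.
#' @param alternative `"real_world"`, `"ideal"` or `"no_treatment"`.
#' @param T_disc Optional vector of individual discontinuation times in
#'   months (`Inf` = never); switches to the individual form.
#' @return Fraction(s) of the year on drug, in \[0, 1\].
#' @export
cycle_drug_exposure <- function(cycle, params = default_parameters(),
                                alternative = c("real_world", "ideal",
                                                "no_treatment"),
                                T_disc = NULL) {
  alternative <- match.arg(alternative)
  if (cycle < 1) stop("cycle must be >= 1")
  if (cycle > params$costs$horizon_years)
    stop("cycle beyond the simulation horizon of ",
         params$costs$horizon_years, " years")
  if (alternative == "no_treatment") return(0)
  cap <- params$costs$drug_cost_months_cap
  if (alternative == "ideal")
    return(pmin(pmax(cap - 12 * (cycle - 1), 0), 12) / 12)
  if (is.null(T_disc)) {
    months <- 12 * (cycle - 1) + seq_len(12)
    mean(persistence_at(months, params) * (months <= cap))
  } else {
    pmin(pmax(pmin(T_disc, cap) - 12 * (cycle - 1), 0), 12) / 12
  }
}

#' Month-by-month protection schedule of an alternative
#'
#' Tabulates the protected proportion per month over the horizon together
#' with the per-cycle cohort drug-exposure fraction.
#'
#' @param params Model parameters.
#' @param alternative Simulation alternative label.
#' @return A list of class `bp_protection_schedule` with `protection`
#'   (data frame `month`, `protected_proportion`) and `exposure`
#'   (data frame `cycle`, `drug_exposure`).
#' @export
protection_schedule <- function(params = default_parameters(),
                                alternative = c("real_world", "ideal",
                                                "no_treatment")) {
  alternative <- match.arg(alternative)
  horizon <- params$costs$horizon_years
  months <- 0:(12 * horizon)
  prot <- data.frame(
    month = months,
    protected_proportion = protected_proportion(months, params, alternative)
  )
  expo <- data.frame(
    cycle = seq_len(horizon),
    drug_exposure = vapply(seq_len(horizon), cycle_drug_exposure,
                           numeric(1), params = params,
                           alternative = alternative)
  )
  structure(list(alternative = alternative, protection = prot,
                 exposure = expo),
            class = "bp_protection_schedule")
}

#' Export a protection schedule as CSV
#'
#' One row per month with the protected proportion and the drug-exposure
#' fraction of the cycle containing that month.
#'
#' @param schedule A [protection_schedule()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_protection_schedule_csv <- function(schedule, path) {
  pr <- schedule$protection
  cyc <- pmax(ceiling(pr$month / 12), 1)
  pr$drug_exposure <- schedule$exposure$drug_exposure[
    pmin(cyc, nrow(schedule$exposure))]
  utils::write.csv(pr, path, row.names = FALSE)
  invisible(path)
}
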