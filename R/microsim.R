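# The Markov engine: annual-cycle, individual-level (first-order Monte
# Carlo) simulation of fractures, health-state transitions, loss of drug
# protection, mortality and cost accrual over the ten-year horizon.
#
# Event order within a cycle: protection status -> fracture draws (one per
# site, independent) -> state update to the most severe new fracture
# (hip > vertebral > wrist) -> death draw (baseline q times the excess
# multiplier if within the window of a hip or symptomatic vertebral
# fracture) -> ageing. Costs accrue at end of cycle and are discounted with
# the cycle index.

#' Simulation settings for one alternative
#'
#' @param n_patients Number of simulated women (>= 1).
#' @param alternative One of `"no_treatment"`, `"real_world"`, `"ideal"`.
#' @param seed Integer seed; together with the parameters it fully
#'   determines the run. Running two alternatives with the same seed and
#'   population uses common random numbers, so paired comparisons are
#'   low-variance.
#' @param cycles Number of one-year cycles (default 10).
#' @return An object of class `bp_sim_settings`.
#' @export
simulation_settings <- function(n_patients,
                                alternative = c("no_treatment", "real_world",
                                                "ideal"),
                                seed = 1, cycles = 10) {
  alternative <- match.arg(alternative)
  if (n_patients < 1) stop("n_patients: must be >= 1")
  if (cycles < 1) stop("cycles: must be >= 1")
  structure(list(n_patients = as.integer(n_patients),
                 alternative = alternative,
                 seed = as.integer(seed), cycles = as.integer(cycles)),
            class = "bp_sim_settings")
}

#' Annual fracture probability for one site
#'
#' `p = base(age, site) * RR * (treatment multiplier if protected)`, capped
#' at 1. The relative-risk modifier is the post-fracture-state RR when the
#' woman is in a post-fracture state; otherwise the prior-fracture RR if she
#' entered the model with a fracture history; otherwise 1. The treatment
#' multipliers (< 1, protective) apply only while protected.
#'
#' Matrix cells with no published value (`NA`) are resolved by
#' `params$na_policy`: `"nearest"` (default) falls back to the baseline
#' prior-fracture RR for risks and to the baseline (pmo-state) multiplier
#' for efficacy; `"one"` uses 1 (no effect).
#'
#' @param age Age(s) in years (>= 50).
#' @param site `"vertebra"`, `"hip"` or `"wrist"`.
#' @param state Health state(s): `"pmo"`, `"post_vertebral"`, `"post_hip"`,
#'   `"post_wrist"`. `"dead"` is an error.
#' @param prior Logical: prior fracture at baseline (only acts in `"pmo"`).
#' @param protected Logical: under bisphosphonate protection this cycle.
#' @param params Model parameters.
#' @return Annual fracture probability, vectorised over patients.
#' @export
#' @examples
#' annual_fracture_probability(72, "hip")                          # 0.0065
#' annual_fracture_probability(72, "hip", state = "post_vertebral")
#' annual_fracture_probability(72, "hip", protected = TRUE)
annual_fracture_probability <- function(age, site, state = "pmo",
                                        prior = FALSE, protected = FALSE,
                                        params = default_parameters()) {
  site <- match.arg(site, .SITES)
  n <- length(age)
  state <- rep_len(state, n)
  prior <- rep_len(prior, n)
  protected <- rep_len(protected, n)
  if (any(state == "dead")) stop("state 'dead' has no fracture risk")
  if (!all(state %in% .STATES)) stop("unknown health state")
  base <- lookup_absolute_risk(params$risk_table, age, site)
  eff <- .effective_matrices(params)
  rr <- rep(1, n)
  post <- state != "pmo"
  if (any(post)) rr[post] <- eff$rr[state[post], site]
  rr[!post & prior] <- params$rr_prior[[site]]
  tm <- rep(1, n)
  if (any(protected)) tm[protected] <- eff$tm[state[protected], site]
  pmin(base * rr * tm, 1)
}

# Resolve NA cells of the state-RR and treatment-multiplier matrices once
# per call site, per the configured policy.
.effective_matrices <- function(params) {
  rr <- params$rr_state
  tm <- params$treat_mult
  if (identical(params$na_policy, "one")) {
    rr[is.na(rr)] <- 1
    tm[is.na(tm)] <- 1
  } else {
    for (s in .SITES) {
      rr[is.na(rr[, s]), s] <- params$rr_prior[[s]]
      tm[is.na(tm[, s]), s] <- tm["pmo", s]
    }
  }
  list(rr = rr, tm = tm)
}

# Vectorised one-cycle transition kernel over a set of living patients.
# u_* are uniform draws consumed positionally (vertebra, hip, wrist,
# symptomatic flag, death) so that runs with equal seeds are aligned across
# alternatives. hip_recent / sym_recent mark an excess-mortality window
# still open from an earlier cycle.
.cycle_events <- function(age, state, prior, protected,
                          u_v, u_h, u_w, u_sym, u_death,
                          q_base, params, excess,
                          hip_recent = FALSE, sym_recent = FALSE) {
  n <- length(age)
  p_v <- annual_fracture_probability(age, "vertebra", state, prior, protected, params)
  p_h <- annual_fracture_probability(age, "hip", state, prior, protected, params)
  p_w <- annual_fracture_probability(age, "wrist", state, prior, protected, params)
  ev_v <- u_v < p_v
  ev_h <- u_h < p_h
  ev_w <- u_w < p_w
  sym <- ev_v & (u_sym < params$costs$symptomatic_fraction)
  new_state <- state
  new_state[ev_w] <- "post_wrist"
  new_state[ev_v] <- "post_vertebral"
  new_state[ev_h] <- "post_hip"   # assignment order encodes severity
  hip_active <- ev_h | rep_len(hip_recent, n)
  sym_active <- sym | rep_len(sym_recent, n)
  mult <- pmax(ifelse(hip_active, excess$hip, 1),
               ifelse(sym_active, excess$vertebral, 1))
  q_d <- pmin(1, q_base * mult)
  dies <- u_death < q_d
  list(ev_v = ev_v, ev_h = ev_h, ev_w = ev_w, sym = sym,
       new_state = new_state, dies = dies,
       fracture_death = dies & mult > 1)
}

#' Advance a single patient by one cycle
#'
#' One-patient form of the engine's cycle kernel, drawing its five uniforms
#' from the current RNG stream (vertebral, hip, wrist event draws, the
#' symptomatic flag and the death draw, in that fixed order). Useful for
#' traces and order-of-operations tests; [run_alternative()] applies the
#' identical transition law to whole populations.
#'
#' @param patient A list or one-row data frame with fields `age`, `state`,
#'   `prior_fracture`, and `disc_months` (months to discontinuation, `Inf`
#'   for never; ignored outside the real-world alternative).
#' @param cycle Year index, 1-based.
#' @param alternative Simulation alternative label.
#' @param params Model parameters.
#' @param life_table Life table for the baseline death probability.
#' @param excess Excess-mortality multipliers ([excess_mortality()]).
#' @return The updated patient list with `age + 1`, the new `state`
#'   (`"dead"` is absorbing), and an `events` list: the site events, the
#'   symptomatic flag, whether the patient died and whether the death was
#'   fracture-related, plus that cycle's undiscounted `fracture_cost` and
#'   `drug_cost`.
#' @export
step_cycle <- function(patient, cycle,
                       alternative = c("no_treatment", "real_world", "ideal"),
                       params = default_parameters(),
                       life_table = synthetic_life_table(),
                       excess = excess_mortality()) {
  alternative <- match.arg(alternative)
  patient <- as.list(patient)
  if (identical(patient$state, "dead")) stop("patient is dead: absorbing state")
  disc <- if (is.null(patient$disc_months)) Inf else patient$disc_months
  protected <- switch(alternative,
    ideal = TRUE,
    no_treatment = FALSE,
    real_world = 12 * (cycle - 1) < protection_duration(disc, params)
  )
  u <- stats::runif(5)
  ev <- .cycle_events(patient$age, patient$state, isTRUE(patient$prior_fracture),
                      protected, u[1], u[2], u[3], u[4], u[5],
                      life_table_q(life_table, patient$age), params, excess)
  expo <- switch(alternative,
    ideal = cycle_drug_exposure(cycle, params, "ideal"),
    no_treatment = 0,
    real_world = cycle_drug_exposure(cycle, params, "real_world",
                                     T_disc = disc)
  )
  drug_cost <- annual_drug_cost(params$costs$drug_price_12wk,
                                params$costs$weeks_per_year) * expo
  fracture_cost <-
    ev$ev_h * fracture_event_cost("hip", params = params) +
    ev$ev_w * fracture_event_cost("wrist", params = params) +
    ev$sym * fracture_event_cost("vertebra", TRUE, params)
  patient$state <- if (ev$dies) "dead" else ev$new_state
  patient$age <- patient$age + 1
  patient$events <- list(
    vertebra = ev$ev_v, hip = ev$ev_h, wrist = ev$ev_w,
    symptomatic_vertebra = ev$sym, died = ev$dies,
    fracture_related_death = ev$fracture_death,
    protected = protected,
    fracture_cost = fracture_cost, drug_cost = drug_cost
  )
  patient
}

#' Run one simulation alternative
#'
#' Simulates every woman of the population over the horizon under one
#' persistence alternative and aggregates the outcomes. All randomness
#' derives from `settings$seed`: discontinuation-time draws first, then the
#' per-cycle event draws, pre-drawn in a fixed layout so that two
#' alternatives run with the same seed and population share common random
#' numbers. The run is fully deterministic given (seed, parameters,
#' population).
#'
#' @param params Model parameters.
#' @param settings A [simulation_settings()]; `n_patients` must equal
#'   `nrow(population)`.
#' @param population Baseline population data frame
#'   ([generate_population()]).
#' @param life_table Life table ([synthetic_life_table()]).
#' @param excess Excess-mortality multipliers ([excess_mortality()]).
#' @param lambda Optional mixing weight towards ideal persistence for the
#'   real-world alternative (see [sample_discontinuation()]); `NULL` means
#'   the unmodified persistence curve.
#' @return An object of class `bp_arm_result`: fracture tallies (per site,
#'   with all-vertebral and symptomatic-vertebral reported separately),
#'   clinical fracture counts, fractured-women and death counts with
#'   proportions, per-patient cost vectors (drug / fracture / total,
#'   discounted and undiscounted) and a per-patient outcome table.
#' @export
run_alternative <- function(params, settings, population,
                            life_table = synthetic_life_table(),
                            excess = excess_mortality(),
                            lambda = NULL) {
  stopifnot(inherits(settings, "bp_sim_settings"))
  n <- nrow(population)
  if (n != settings$n_patients)
    stop("population size (", n, ") must equal settings$n_patients (",
         settings$n_patients, ")")
  alt <- settings$alternative
  cycles <- settings$cycles
  if (cycles > params$costs$horizon_years)
    stop("settings$cycles exceeds the parameter horizon")

  set.seed(settings$seed)
  u_disc <- stats::runif(n)
  u_v <- matrix(stats::runif(n * cycles), n, cycles)
  u_h <- matrix(stats::runif(n * cycles), n, cycles)
  u_w <- matrix(stats::runif(n * cycles), n, cycles)
  u_sym <- matrix(stats::runif(n * cycles), n, cycles)
  u_death <- matrix(stats::runif(n * cycles), n, cycles)

  T_disc <- switch(alt,
    no_treatment = rep(0, n),
    ideal = rep(Inf, n),
    real_world = sample_discontinuation(u_disc, params,
                                        lambda = if (is.null(lambda)) 0 else lambda)
  )
  y_disc <- protection_duration(T_disc, params)
  annual_price <- annual_drug_cost(params$costs$drug_price_12wk,
                                   params$costs$weeks_per_year)
  rate <- params$costs$discount_rate
  c_hip <- fracture_event_cost("hip", params = params)
  c_wrist <- fracture_event_cost("wrist", params = params)
  c_vert <- fracture_event_cost("vertebra", TRUE, params)

  age <- population$age
  prior <- population$prior_fracture
  state <- rep("pmo", n)
  fr_v <- fr_vs <- fr_h <- fr_w <- integer(n)
  death_cycle <- rep(NA_integer_, n)
  premature <- rep(FALSE, n)
  last_hip <- rep(-Inf, n)    # cycle of last hip fracture
  last_sym <- rep(-Inf, n)    # cycle of last symptomatic vertebral fracture
  drug_u <- drug_d <- frac_u <- frac_d <- numeric(n)

  for (cy in seq_len(cycles)) {
    idx <- which(state != "dead")
    if (!length(idx)) break
    prot <- switch(alt,
      ideal = rep(TRUE, length(idx)),
      no_treatment = rep(FALSE, length(idx)),
      real_world = 12 * (cy - 1) < y_disc[idx]
    )
    hip_recent <- (cy - last_hip[idx]) < excess$window_years
    sym_recent <- (cy - last_sym[idx]) < excess$window_years
    ev <- .cycle_events(age[idx], state[idx], prior[idx], prot,
                        u_v[idx, cy], u_h[idx, cy], u_w[idx, cy],
                        u_sym[idx, cy], u_death[idx, cy],
                        life_table_q(life_table, age[idx]),
                        params, excess, hip_recent, sym_recent)

    cap <- params$costs$drug_cost_months_cap
    expo <- switch(alt,
      ideal = rep(pmin(pmax(cap - 12 * (cy - 1), 0), 12) / 12, length(idx)),
      no_treatment = rep(0, length(idx)),
      real_world = pmin(pmax(pmin(T_disc[idx], cap) - 12 * (cy - 1), 0), 12) / 12
    )
    dc <- annual_price * expo
    fc <- ev$ev_h * c_hip + ev$ev_w * c_wrist + ev$sym * c_vert
    df <- 1 / (1 + rate)^cy
    drug_u[idx] <- drug_u[idx] + dc
    drug_d[idx] <- drug_d[idx] + dc * df
    frac_u[idx] <- frac_u[idx] + fc
    frac_d[idx] <- frac_d[idx] + fc * df

    fr_v[idx] <- fr_v[idx] + ev$ev_v
    fr_vs[idx] <- fr_vs[idx] + ev$sym
    fr_h[idx] <- fr_h[idx] + ev$ev_h
    fr_w[idx] <- fr_w[idx] + ev$ev_w
    last_hip[idx[ev$ev_h]] <- cy
    last_sym[idx[ev$sym]] <- cy

    state[idx] <- ev$new_state
    dead_now <- idx[ev$dies]
    state[dead_now] <- "dead"
    death_cycle[dead_now] <- cy
    premature[dead_now] <- ev$fracture_death[ev$dies]
    age[idx] <- age[idx] + 1
  }

  clinical <- fr_vs + fr_h + fr_w
  per_patient <- data.frame(
    id = population$id, age0 = population$age,
    prior_fracture = prior, disc_months = T_disc,
    n_vertebra = fr_v, n_vertebra_symptomatic = fr_vs,
    n_hip = fr_h, n_wrist = fr_w,
    final_state = state, death_cycle = death_cycle, premature = premature,
    cost_drug_disc = drug_d, cost_drug_undisc = drug_u,
    cost_fracture_disc = frac_d, cost_fracture_undisc = frac_u,
    cost_total_disc = drug_d + frac_d, cost_total_undisc = drug_u + frac_u
  )
  fractures <- c(vertebra = sum(fr_v), hip = sum(fr_h), wrist = sum(fr_w))
  clin <- c(vertebra = sum(fr_vs), hip = sum(fr_h), wrist = sum(fr_w))
  res <- list(
    alternative = alt, n = n, seed = settings$seed, cycles = cycles,
    lambda = lambda,
    fractures = c(fractures, total = sum(fractures)),
    clinical_fractures = c(clin, total = sum(clin)),
    fractured_women = sum(clinical > 0),
    fractured_women_prop = mean(clinical > 0),
    deaths = sum(!is.na(death_cycle)),
    premature_deaths = sum(premature),
    premature_deaths_prop = mean(premature),
    costs = list(
      drug_disc = drug_d, drug_undisc = drug_u,
      fracture_disc = frac_d, fracture_undisc = frac_u,
      total_disc = drug_d + frac_d, total_undisc = drug_u + frac_u
    ),
    per_patient = per_patient
  )
  class(res) <- "bp_arm_result"
  res
}

#' @export
print.bp_arm_result <- function(x, ...) {
  cat(sprintf("<bp_arm_result> %s: n = %d, %d cycles, seed %d\n",
              x$alternative, x$n, x$cycles, x$seed))
  cat("  clinical fractures:",
      paste(names(x$clinical_fractures), x$clinical_fractures,
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  fractured women: %d (%.1f%%); deaths: %d; fracture-related: %d (%.1f%%)\n",
              x$fractured_women, 100 * x$fractured_women_prop, x$deaths,
              x$premature_deaths, 100 * x$premature_deaths_prop))
  cat(sprintf("  mean cost/patient (disc.): total %.0f = drug %.0f + fracture %.0f EUR\n",
              mean(x$costs$total_disc), mean(x$costs$drug_disc),
              mean(x$costs$fracture_disc)))
  invisible(x)
}

#' Summarise an alternative's per-patient costs
#'
#' @param result A `bp_arm_result`.
#' @param discounted Use discounted (default) or undiscounted costs.
#' @return Data frame with mean and SD of drug, fracture and total cost per
#'   patient.
#' @export
arm_cost_summary <- function(result, discounted = TRUE) {
  sfx <- if (discounted) "_disc" else "_undisc"
  comp <- c("drug", "fracture", "total")
  data.frame(
    component = comp,
    mean = vapply(comp, function(k) mean(result$costs[[paste0(k, sfx)]]),
                  numeric(1)),
    sd = vapply(comp, function(k) stats::sd(result$costs[[paste0(k, sfx)]]),
                numeric(1)),
    row.names = NULL
  )
}

#' Deterministic cohort expectation on a reduced instance
#'
#' Exact forward propagation of state-occupancy probabilities under the
#' same transition law as the microsimulation, for a cohort starting at a
#' single age, over a small number of cycles. Serves as the analytic oracle
#' the stochastic engine must converge to. Protection uses the cohort
#' protected proportion of the cycle; over the first two cycles this is
#' exactly 0 or 1 for every alternative, making the oracle exact there.
#'
#' @param params Model parameters.
#' @param alternative Simulation alternative label.
#' @param age Single starting age in years.
#' @param cycles Number of cycles; refused above `max_cycles`, since the
#'   independence approximation of per-cycle protection only holds early.
#' @param prior_prevalence Probability of a baseline prior fracture.
#' @param life_table,excess As for [run_alternative()]; the window must be
#'   one year.
#' @param max_cycles Largest admissible instance (default 5).
#' @return A list with `per_cycle` (expected per-patient fracture events by
#'   site — all-vertebral and symptomatic separately — deaths and
#'   fracture-related deaths, and end-of-cycle occupancy) and `totals`
#'   (expected cumulative per-patient event counts).
#' @export
#' @examples
#' cohort_expectation(default_parameters(), "no_treatment", age = 72,
#'                    cycles = 1, prior_prevalence = 0)
cohort_expectation <- function(params, alternative, age, cycles,
                               prior_prevalence = 0.597,
                               life_table = synthetic_life_table(),
                               excess = excess_mortality(),
                               max_cycles = 5) {
  alternative <- match.arg(alternative,
                           c("no_treatment", "real_world", "ideal"))
  if (cycles > max_cycles)
    stop("instance too large for exact enumeration (cycles > ", max_cycles, ")")
  if (excess$window_years != 1)
    stop("cohort oracle requires a one-year excess-mortality window")
  live <- c("pmo_noprior", "pmo_prior", "post_vertebral", "post_hip",
            "post_wrist")
  all_states <- c(live, "dead_other", "dead_fracture")
  mass <- stats::setNames(numeric(length(all_states)), all_states)
  mass["pmo_noprior"] <- 1 - prior_prevalence
  mass["pmo_prior"] <- prior_prevalence
  psym <- params$costs$symptomatic_fraction
  combos <- expand.grid(v = c("none", "morph", "sym"),
                        h = c(FALSE, TRUE), w = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  age_c <- age
  rows <- list()
  for (cy in seq_len(cycles)) {
    p_prot <- protected_proportion(12 * (cy - 1), params, alternative)
    qb <- life_table_q(life_table, age_c)
    new_mass <- stats::setNames(numeric(length(all_states)), all_states)
    new_mass[c("dead_other", "dead_fracture")] <-
      mass[c("dead_other", "dead_fracture")]
    E <- c(vertebra = 0, vertebra_symptomatic = 0, hip = 0, wrist = 0,
           deaths = 0, fracture_deaths = 0)
    for (st in live) {
      if (mass[st] == 0) next
      eng_state <- if (startsWith(st, "pmo")) "pmo" else st
      prior <- st == "pmo_prior"
      for (prot in c(TRUE, FALSE)) {
        w_prot <- if (prot) p_prot else 1 - p_prot
        if (w_prot == 0) next
        pv <- annual_fracture_probability(age_c, "vertebra", eng_state,
                                          prior, prot, params)
        ph <- annual_fracture_probability(age_c, "hip", eng_state,
                                          prior, prot, params)
        pw <- annual_fracture_probability(age_c, "wrist", eng_state,
                                          prior, prot, params)
        pv_part <- c(none = 1 - pv, morph = pv * (1 - psym), sym = pv * psym)
        for (i in seq_len(nrow(combos))) {
          cb <- combos[i, ]
          pr <- mass[st] * w_prot * pv_part[[cb$v]] *
            (if (cb$h) ph else 1 - ph) * (if (cb$w) pw else 1 - pw)
          if (pr == 0) next
          ns <- if (cb$h) "post_hip"
                else if (cb$v != "none") "post_vertebral"
                else if (cb$w) "post_wrist"
                else st
          mult <- max(if (cb$h) excess$hip else 1,
                      if (cb$v == "sym") excess$vertebral else 1)
          qd <- min(1, qb * mult)
          E["vertebra"] <- E["vertebra"] + pr * (cb$v != "none")
          E["vertebra_symptomatic"] <- E["vertebra_symptomatic"] +
            pr * (cb$v == "sym")
          E["hip"] <- E["hip"] + pr * cb$h
          E["wrist"] <- E["wrist"] + pr * cb$w
          E["deaths"] <- E["deaths"] + pr * qd
          dead_to <- if (mult > 1) "dead_fracture" else "dead_other"
          if (mult > 1) E["fracture_deaths"] <- E["fracture_deaths"] + pr * qd
          new_mass[dead_to] <- new_mass[dead_to] + pr * qd
          new_mass[ns] <- new_mass[ns] + pr * (1 - qd)
        }
      }
    }
    mass <- new_mass
    stopifnot(abs(sum(mass) - 1) < 1e-12)
    rows[[cy]] <- data.frame(cycle = cy, t(E), t(mass))
    age_c <- age_c + 1
  }
  per_cycle <- do.call(rbind, rows)
  ev_cols <- c("vertebra", "vertebra_symptomatic", "hip", "wrist",
               "deaths", "fracture_deaths")
  list(per_cycle = per_cycle,
       totals = colSums(per_cycle[, ev_cols, drop = FALSE]),
       occupancy = mass)
}
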