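test_that("annual fracture probability multiplies base risk, RR and efficacy", {
  p <- default_parameters()
  expect_equal(annual_fracture_probability(72, "hip", params = p), 0.0065)
  expect_equal(annual_fracture_probability(72, "hip", state = "post_vertebral",
                                           params = p), 0.0065 * 2.3)
  expect_equal(annual_fracture_probability(72, "hip", protected = TRUE,
                                           params = p), 0.0065 * 0.672)
  # prior-fracture RR acts only in the pmo state
  expect_equal(annual_fracture_probability(72, "vertebra", prior = TRUE,
                                           params = p), 0.0556 * 2.0)
  expect_equal(annual_fracture_probability(72, "vertebra",
                                           state = "post_hip", prior = TRUE,
                                           params = p), 0.0556 * 2.5)
  expect_error(annual_fracture_probability(72, "hip", state = "dead",
                                           params = p), "dead")
})

test_that("unpublished matrix cells fall back per the NA policy", {
  p <- default_parameters()
  # post-hip wrist RR is unpublished: nearest printed value is the baseline
  # prior-fracture RR (1.9)
  expect_equal(annual_fracture_probability(72, "wrist", state = "post_hip",
                                           params = p), 0.0197 * 1.9)
  # post-hip vertebral efficacy is unpublished: baseline multiplier 0.526
  expect_equal(annual_fracture_probability(72, "vertebra", state = "post_hip",
                                           protected = TRUE, params = p),
               0.0556 * 2.5 * 0.526)
  p$na_policy <- "one"
  expect_equal(annual_fracture_probability(72, "wrist", state = "post_hip",
                                           params = p), 0.0197)
  expect_equal(annual_fracture_probability(72, "vertebra", state = "post_hip",
                                           protected = TRUE, params = p),
               0.0556 * 2.5)
})

test_that("a cycle with zero risks and zero mortality changes only age", {
  p <- zero_risk_params()
  lt <- flat_life_table(0)
  pat <- list(id = 1, age = 70, state = "pmo", prior_fracture = FALSE,
              disc_months = Inf)
  set.seed(1)
  out <- step_cycle(pat, 1, "real_world", p, lt)
  expect_equal(out$state, "pmo")
  expect_equal(out$age, 71)
  expect_false(out$events$died)
  expect_equal(out$events$fracture_cost, 0)
})

test_that("certain death ends the simulation, after the fracture draws", {
  p <- default_parameters()
  p$risk_table$hip <- rep(1, nrow(p$risk_table))  # certain hip fracture
  lt <- flat_life_table(1)
  pop <- data.frame(id = 1, age = 72, prior_fracture = FALSE)
  arm <- run_alternative(p, simulation_settings(1, "no_treatment", seed = 2),
                         pop, lt)
  expect_equal(arm$deaths, 1)
  expect_equal(arm$per_patient$death_cycle, 1)
  # the fracture preceded the death within the cycle and was recorded
  expect_equal(unname(arm$fractures[["hip"]]), 1)
  expect_true(arm$per_patient$premature)  # died under the hip excess window
})

test_that("dead is absorbing: no events accrue after the death cycle", {
  p <- default_parameters()
  lt <- flat_life_table(1)  # everyone dies in cycle 1
  pop <- generate_population(n = 400, seed = 9)
  arm <- run_alternative(p, simulation_settings(400, "no_treatment", seed = 9),
                         pop, lt)
  expect_true(all(arm$per_patient$death_cycle == 1))
  # at most one event per site can have occurred (single live cycle)
  expect_true(all(arm$per_patient$n_hip <= 1))
  expect_true(all(arm$per_patient$n_vertebra <= 1))
  expect_true(all(arm$per_patient$n_wrist <= 1))
  expect_true(all(arm$per_patient$cost_drug_undisc == 0))
})

test_that("null efficacy makes the ideal arm match no-treatment event-wise", {
  p <- default_parameters()
  p$treat_mult[!is.na(p$treat_mult)] <- 1
  pop <- generate_population(n = 500, seed = 12)
  lt <- synthetic_life_table()
  a <- run_alternative(p, simulation_settings(500, "no_treatment", seed = 12),
                       pop, lt)
  b <- run_alternative(p, simulation_settings(500, "ideal", seed = 12),
                       pop, lt)
  expect_identical(a$fractures, b$fractures)
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$per_patient$final_state, b$per_patient$final_state)
})

test_that("runs are deterministic given seed, parameters and population", {
  p <- default_parameters()
  pop <- generate_population(n = 600, seed = 21)
  lt <- synthetic_life_table()
  st <- simulation_settings(600, "real_world", seed = 33)
  a <- run_alternative(p, st, pop, lt)
  b <- run_alternative(p, st, pop, lt)
  expect_identical(a$fractures, b$fractures)
  expect_identical(a$costs, b$costs)
  c2 <- run_alternative(p, simulation_settings(600, "real_world", seed = 34),
                        pop, lt)
  expect_false(identical(a$fractures, c2$fractures))
})

test_that("aggregate tallies are internally consistent", {
  p <- default_parameters()
  pop <- generate_population(n = 1000, seed = 4)
  arm <- run_alternative(p, simulation_settings(1000, "real_world", seed = 4),
                         pop, synthetic_life_table())
  expect_equal(unname(arm$fractures[["total"]]),
               sum(arm$fractures[c("vertebra", "hip", "wrist")]))
  expect_equal(unname(arm$clinical_fractures[["total"]]),
               sum(arm$clinical_fractures[c("vertebra", "hip", "wrist")]))
  expect_lte(arm$fractured_women, arm$clinical_fractures[["total"]])
  expect_equal(arm$fractured_women_prop, arm$fractured_women / arm$n)
  expect_equal(arm$premature_deaths_prop, arm$premature_deaths / arm$n)
  expect_lte(arm$premature_deaths, arm$deaths)
  pp <- arm$per_patient
  expect_equal(sum(pp$n_hip), unname(arm$fractures[["hip"]]))
  expect_equal(sum(pp$n_vertebra_symptomatic),
               unname(arm$clinical_fractures[["vertebra"]]))
  expect_true(all(pp$n_vertebra_symptomatic <= pp$n_vertebra))
})

test_that("more persistence means fewer fractures, arm by arm", {
  p <- default_parameters()
  lt <- synthetic_life_table()
  for (seed in c(101, 202, 303)) {
    pop <- generate_population(n = 2000, seed = seed)
    tot <- vapply(c("no_treatment", "real_world", "ideal"), function(alt) {
      arm <- run_alternative(p, simulation_settings(2000, alt, seed = seed),
                             pop, lt)
      unname(arm$clinical_fractures[["total"]])
    }, numeric(1))
    expect_gt(tot[["no_treatment"]], tot[["real_world"]])
    expect_gt(tot[["real_world"]], tot[["ideal"]])
  }
})

test_that("cohort oracle reproduces single-cycle transition probabilities", {
  p <- default_parameters()
  lt <- synthetic_life_table()
  co <- cohort_expectation(p, "no_treatment", age = 72, cycles = 1,
                           prior_prevalence = 0, life_table = lt)
  expect_equal(unname(co$totals[["hip"]]), 0.0065)
  expect_equal(unname(co$totals[["vertebra"]]), 0.0556)
  expect_equal(unname(co$totals[["vertebra_symptomatic"]]), 0.0556 * 0.23)
  # occupancy stays in pmo when nothing can happen
  z <- cohort_expectation(zero_risk_params(), "no_treatment", age = 72,
                          cycles = 3, prior_prevalence = 0.3,
                          life_table = flat_life_table(0))
  expect_equal(unname(z$occupancy[["pmo_noprior"]] +
                        z$occupancy[["pmo_prior"]]), 1)
  expect_equal(unname(z$totals[["deaths"]]), 0)
  expect_error(cohort_expectation(p, "no_treatment", 72, cycles = 9),
               "too large")
})

test_that("cohort oracle occupancy masses stay normalised", {
  p <- default_parameters()
  co <- cohort_expectation(p, "real_world", age = 80, cycles = 4,
                           prior_prevalence = 0.597)
  occ_cols <- c("pmo_noprior", "pmo_prior", "post_vertebral", "post_hip",
                "post_wrist", "dead_other", "dead_fracture")
  sums <- rowSums(co$per_cycle[, occ_cols])
  expect_true(all(abs(sums - 1) < 1e-12))
})
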