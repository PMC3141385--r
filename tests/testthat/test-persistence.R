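test_that("persistence curve reproduces the fitted column", {
  p <- default_parameters()
  expect_equal(persistence_at(1, p), 1)
  expect_equal(persistence_at(0, p), 1)
  expect_equal(round(100 * persistence_at(12, p)), 51)
  expect_equal(persistence_at(60, p), 0.20)
  expect_equal(persistence_at(200, p), 0.20)  # held at the floor
  # fitted rows within one percentage point (the 24-month source datum 41
  # is a known misfit of the log curve and is not asserted)
  fitted <- 100 * persistence_at(c(6, 12, 36, 48, 60), p)
  expect_true(all(abs(fitted - c(65, 51, 30, 24, 20)) <= 1))
  expect_error(persistence_at(-1, p), "non-negative")
})

test_that("persistence is non-increasing and bounded by floor and 1", {
  p <- default_parameters()
  T <- seq(0, 150, by = 0.5)
  v <- persistence_at(T, p)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= p$persistence$floor & v <= 1))
})

test_that("residual protection duration follows the exponential model", {
  p <- default_parameters()
  expect_equal(protection_duration(0, p), 0)  # never started, never protected
  expect_equal(round(protection_duration(12, p)), 24)
  expect_equal(round(protection_duration(24, p)), 43)
  expect_equal(protection_duration(12, p), 13.5 * exp(0.048 * 12))
  # four years of treatment protect for the full ten-year horizon
  expect_gte(protection_duration(48, p), 120)
  expect_equal(protection_duration(Inf, p), Inf)
  expect_error(protection_duration(-3, p), "non-negative")
})

test_that("protected proportion combines persistence with residual effect", {
  p <- default_parameters()
  expect_equal(protected_proportion(0, p), 1)
  # y(T) >= 13.5 for every initiator, so months up to 13.5 are fully covered
  expect_equal(protected_proportion(12, p), 1)
  expect_equal(protected_proportion(13.5, p), 1)
  # closed form at the horizon end: persistence_at(T*) with T* = ln(m/a)/k
  m <- 120
  tstar <- log(m / 13.5) / 0.048
  expect_equal(protected_proportion(120, p), persistence_at(tstar, p))
  expect_equal(round(protected_proportion(120, p), 3), 0.252)
  # alternatives force the extremes
  expect_equal(protected_proportion(c(0, 60, 120), p, "ideal"), rep(1, 3))
  expect_equal(protected_proportion(c(0, 60, 120), p, "no_treatment"),
               rep(0, 3))
})

test_that("protected proportion is non-increasing beyond the residual scale", {
  p <- default_parameters()
  m <- seq(13.5, 120, by = 0.5)
  v <- protected_proportion(m, p)
  expect_true(all(diff(v) <= 1e-12))
})

test_that("protected proportion matches the discontinuation-sampling oracle", {
  p <- default_parameters()
  set.seed(301)
  u <- runif(1e5)
  T <- sample_discontinuation(u, p)
  y <- protection_duration(T, p)
  for (m in c(12, 36, 60, 120)) {
    emp <- mean(y > m)
    ref <- protected_proportion(m, p)
    se <- sqrt(ref * (1 - ref) / 1e5)
    expect_lt(abs(emp - ref), max(3 * se, 1e-12))
  }
  # never-discontinuers fraction reproduces the floor
  emp_never <- mean(is.infinite(T))
  se <- sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(emp_never - p$persistence$floor), 3 * se)
})

test_that("discontinuation sampling inverts the persistence curve", {
  p <- default_parameters()
  T <- sample_discontinuation(0.5, p)
  expect_equal(T, exp(0.5 / 0.196))
  expect_equal(persistence_at(T, p), 0.5)
  expect_equal(sample_discontinuation(0.10, p), Inf)  # below the floor
  expect_equal(sample_discontinuation(1 - 1e-12, p), 1)  # clamped to 1 month
  expect_error(sample_discontinuation(0, p), "\\(0, 1\\)")
  expect_error(sample_discontinuation(1, p), "\\(0, 1\\)")
  # lambda mixes towards ideal persistence
  expect_equal(sample_discontinuation(0.5, p, lambda = 1), Inf)
  expect_equal(sample_discontinuation(0.6, p, lambda = 0.2),
               exp((1 - 0.5) / 0.196))  # (0.6-0.2)/0.8 = 0.5
})

test_that("cycle drug exposure follows the persistence curve and cap", {
  p <- default_parameters()
  expect_equal(cycle_drug_exposure(1, p, "ideal"), 1)
  expect_equal(cycle_drug_exposure(5, p, "ideal"), 0)  # beyond 48-month cap
  expect_equal(cycle_drug_exposure(3, p, "no_treatment"), 0)
  # cohort form: direct 12-point average of the closed form
  ref <- mean(1 - 0.196 * log(1:12))
  expect_equal(cycle_drug_exposure(1, p, "real_world"), ref)
  # individual form: months on drug within the cycle
  expect_equal(cycle_drug_exposure(1, p, "real_world", T_disc = 6), 0.5)
  expect_equal(cycle_drug_exposure(2, p, "real_world", T_disc = 6), 0)
  expect_equal(cycle_drug_exposure(1, p, "real_world", T_disc = Inf), 1)
  expect_equal(cycle_drug_exposure(5, p, "real_world", T_disc = Inf), 0)
  expect_error(cycle_drug_exposure(11, p, "real_world"), "horizon")
  expect_error(cycle_drug_exposure(0, p, "real_world"), "cycle")
  # uncapped accrual restores exposure over the whole horizon
  p$costs$drug_cost_months_cap <- Inf
  expect_equal(cycle_drug_exposure(5, p, "ideal"), 1)
  expect_equal(cycle_drug_exposure(5, p, "real_world", T_disc = Inf), 1)
})

test_that("protection schedules tabulate and export consistently", {
  p <- default_parameters()
  sch <- protection_schedule(p, "real_world")
  expect_equal(nrow(sch$protection), 121)
  expect_true(all(sch$protection$protected_proportion >= 0 &
                    sch$protection$protected_proportion <= 1))
  expect_true(all(sch$exposure$drug_exposure >= 0 &
                    sch$exposure$drug_exposure <= 1))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_protection_schedule_csv(sch, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back$protected_proportion,
               sch$protection$protected_proportion)
})
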