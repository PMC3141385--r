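#!/usr/bin/env Rscript
# Pairwise cost-effectiveness analysis: real-world vs no treatment and
# ideal vs real-world, on both effectiveness criteria (proportion of
# fractured women, proportion of premature deaths), discounted and
# undiscounted; Student comparison of mean costs; and the distribution of
# 10-year fracture-management costs among fractured women.
#
# Arms are re-run deterministically from the recorded seed rather than read
# from disk: the engine is seed-exact, so this reproduces script 02's runs.

suppressPackageStartupMessages(library(persistcea))

seed <- 2026
params <- load_parameters("results/parameters.json")
pop <- read_population_csv("results/population.csv")
lt <- structure(utils::read.csv("results/life_table.csv"),
                class = c("bp_life_table", "data.frame"))

arms <- lapply(c("no_treatment", "real_world", "ideal"), function(alt)
  run_alternative(params, simulation_settings(nrow(pop), alt, seed = seed),
                  pop, lt))
names(arms) <- c("no_treatment", "real_world", "ideal")

pairs <- list(c("no_treatment", "real_world"), c("real_world", "ideal"))
rows <- list()
for (pr in pairs) {
  for (eff in c("fractured_women", "premature_deaths")) {
    for (disc in c(TRUE, FALSE)) {
      r <- icer(arms[[pr[1]]], arms[[pr[2]]], eff, discounted = disc)
      print(r)
      rows[[length(rows) + 1]] <- data.frame(
        comparator = r$comparator, intervention = r$intervention,
        effect = eff, discounted = disc,
        delta_cost = round(r$delta_cost),
        delta_effect = round(r$delta_effect, 3),
        ratio = round(r$ratio), dominant = r$dominant
      )
    }
  }
}
utils::write.csv(do.call(rbind, rows), "results/cea_table.csv",
                 row.names = FALSE)

# Student t comparison of mean discounted total costs between arms
tt <- combn(names(arms), 2, simplify = FALSE)
for (pr in tt) {
  ct <- compare_mean_costs(arms[[pr[1]]]$costs$total_disc,
                           arms[[pr[2]]]$costs$total_disc)
  cat(sprintf("t-test %s vs %s: t = %.2f, p = %.3g (%s)\n",
              pr[1], pr[2], ct$statistic, ct$p_value,
              if (ct$significant) "significant at 0.05" else "ns"))
}

# Fracture-cost distribution among fractured women, per arm
dist_rows <- lapply(names(arms), function(alt) {
  pp <- arms[[alt]]$per_patient
  frac <- pp$n_hip + pp$n_wrist + pp$n_vertebra_symptomatic > 0
  d <- cost_distribution(pp$cost_fracture_undisc[frac])
  cat(sprintf("%s: fractured women n = %d, mean fracture cost %d EUR (SD %d)\n",
              alt, d$n, round(d$mean), round(d$sd)))
  bins <- d$bins
  bins$alternative <- alt
  bins
})
utils::write.csv(do.call(rbind, dist_rows), "results/cost_distribution.csv",
                 row.names = FALSE)
cat("CEA table and cost distribution written under results/\n")
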