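# Shared fixtures: built in code, tiny, deterministic.

# A population of n women all at the same age (single risk band), with the
# given prior-fracture prevalence drawn reproducibly.
uniform_age_population <- function(n, age, prior_prev, seed) {
  set.seed(seed)
  data.frame(id = seq_len(n), age = rep(age, n),
             prior_fracture = stats::runif(n) < prior_prev)
}

# Parameters with all fracture risks set to zero.
zero_risk_params <- function() {
  p <- default_parameters()
  for (s in c("vertebra", "hip", "wrist")) p$risk_table[[s]] <- 0
  p
}

# A life table with constant annual death probability q at every age.
flat_life_table <- function(q) {
  lt <- synthetic_life_table()
  lt$qx <- rep(q, nrow(lt))
  if (q < 1) lt$qx[nrow(lt)] <- 1
  lt
}
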