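# persistcea

Half of the women who start weekly oral bisphosphonates for post-menopausal
osteoporosis discontinue within a year. Stopping early forfeits fracture
protection but also saves drug cost — so is poor persistence expensive or
cheap for a health system? `persistcea` answers this with an
individual-level (first-order Monte Carlo) Markov microsimulation of
osteoporotic fractures, for health economists and outcomes researchers
studying medication adherence.

## The model

Each simulated woman moves yearly between four mutually exclusive health
states — diagnosed post-menopausal osteoporosis, post-vertebral,
post-hip and post-wrist fracture — with death absorbing, over a 10-year
horizon. Annual fracture probabilities are

    p(site) = base(age, site) × RR(state | prior fracture) × RRR(site)  [while protected]

with age-band base risks, prior-/post-fracture relative risks and
protective treatment multipliers (RRR < 1). Persistence follows the fitted
curve *P*(T) = 1 − 0.196 ln *T* (floor 20 % from month 60), and protection
outlasts discontinuation through the residual effect
*y*(T) = 13.5 e^(0.048 T): a woman treated *T* months is protected for
*y*(T) months from initiation. Three alternatives are compared — no
treatment, real-world persistence, ideal persistence — on mean per-patient
cost (fracture management: hip €11,419, wrist €3,305, symptomatic vertebral
€5,872; generic drug €52.23 per 12 weeks; 5 % annual discounting) against
the proportions of fractured women and of premature (fracture-related)
deaths, as incremental cost-effectiveness ratios with dominance detection.
A persistence→cost sweep and a national budget extrapolation (1.13 M
diagnosed women) complete the analysis.

Inputs the original model cited but never published — the national life
table and post-fracture excess mortality — are generated as clearly
labelled synthetic stand-ins (Gompertz mortality, configurable
multipliers), so absolute counts are illustrative while the persistence,
risk and costing arithmetic and the comparative findings are exactly
reproducible.

## Worked example

```r
library(persistcea)

params <- default_parameters()          # all published inputs
pop    <- generate_population(n = 30000, seed = 2026)
lt     <- synthetic_life_table()

ideal <- run_alternative(params, simulation_settings(30000, "ideal", seed = 2026), pop, lt)
real  <- run_alternative(params, simulation_settings(30000, "real_world", seed = 2026), pop, lt)
ideal
#> <bp_arm_result> ideal: n = 30000, 10 cycles, seed 2026
#>   clinical fractures: vertebra=4439, hip=3443, wrist=6164, total=14046
#>   fractured women: 10680 (35.6%); deaths: 6622; fracture-related: 587 (2.0%)
#>   mean cost/patient (disc.): total 2966 = drug 781 + fracture 2186 EUR

icer(real, ideal, effect = "fractured_women")
#> <bp_icer> ideal vs real_world (fractured_women, discounted)
#>   incremental cost -400 EUR; incremental effect -0.074
#>   dominant (cheaper, fewer cases): 5377 EUR per case avoided
```

Ideal persistence *dominates* real-world persistence: it costs less per
patient (the extra drug spending is more than offset by avoided fracture
management) while fracturing fewer women — and real-world persistence in
turn dominates no treatment. Sweeping persistence from its real-world level
to 100 % shows total cost falling quasi-linearly (here −€81 per patient per
ten percentage points of one-year persistence), and extrapolating the
per-patient difference nationally:

```r
national_extrapolation(400, population = 1130000, horizon = 10) / 1e6
#> [1] 45.2   # million EUR per year
```

The `analysis/` scripts run this workflow end to end
(`01_build_inputs.R` → `04_persistence_sweep.R`), writing tables under
`results/`; `vignettes/persistence-cost-model.Rmd` documents the model,
its assumptions and its limitations.

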