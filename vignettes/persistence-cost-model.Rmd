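---
title: "A Markov microsimulation of the cost of non-persistence with oral bisphosphonates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov microsimulation of the cost of non-persistence with oral bisphosphonates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Half of the women who start a weekly oral bisphosphonate for post-menopausal
osteoporosis have stopped taking it within a year. Poor persistence forfeits
fracture protection, but it also saves drug cost, so the net budget effect of
non-persistence is not obvious. `persistcea` quantifies it with an
individual-level (first-order Monte Carlo) Markov model that simulates
fractures, deaths and costs over a ten-year horizon under three alternatives:

* **no treatment** — the natural history of diagnosed post-menopausal
  osteoporosis;
* **real-world persistence** — all women initiate therapy, discontinuation
  follows the observed persistence curve;
* **ideal persistence** — no woman discontinues prematurely.

The *cost of non-persistence* is the difference in mean total cost per
patient between the ideal and real-world alternatives, extrapolated to the
1.13 million French women with diagnosed osteoporosis.

## Model structure

Each simulated woman occupies one of four mutually exclusive health states —
diagnosed post-menopausal osteoporosis (`pmo`), post-vertebral-fracture,
post-hip-fracture, post-wrist-fracture — with death as an absorbing state.
Cycles last one year; the horizon is ten cycles. Within a cycle the order of
events is fixed:

1. **protection** — is the woman protected by the drug this cycle?
2. **fracture draws** — one independent Bernoulli draw per site; a vertebral
   event is flagged *symptomatic* with probability 0.23 (the remainder are
   morphometric-only);
3. **state update** — the state becomes the most severe new fracture of the
   cycle, hip > vertebral > wrist (any vertebral event, symptomatic or not,
   moves the woman to the post-vertebral state: radiographic fractures still
   raise subsequent risk); otherwise it is unchanged;
4. **death draw** — baseline annual probability from the life table, times
   an excess multiplier if within one year of a hip or symptomatic vertebral
   fracture; such deaths are recorded as *premature* (fracture-related);
5. **ageing** — age advances one year; costs accrue at end of cycle.

The annual fracture probability is the product

```
p(site) = base(age, site) x RR x treatment multiplier (while protected)
```

where `base` is a piecewise-constant age-band table (five-year bands from 50,
open-ended above 84), `RR` is the post-fracture-state relative risk when the
woman has fractured, otherwise the prior-fracture relative risk if she
entered the model with a fracture history (the prior-fracture RR acts only in
the `pmo` state — the post-state RRs replace it rather than multiply it), and
the treatment multipliers (0.526 vertebra / 0.672 hip / 0.833 wrist at
baseline, state-specific thereafter) are applied as multiplicative risk
ratios while protected. Although the source table labels this block a
"relative risk reduction", the values behave as risk multipliers from pooled
trial efficacy, and that is how they are applied.

Three cells of the RR and efficacy matrices have no published value. Setting
them to 1 would create implausible discontinuities (a hip-fractured woman
suddenly at baseline wrist risk), so the default `na_policy = "nearest"`
falls back to the nearest published value: the baseline prior-fracture RR for
risks, the baseline treatment multiplier for efficacy. `na_policy = "one"`
restores the neutral choice for sensitivity analysis.

## Persistence and residual protection

Persistence with weekly bisphosphonates follows the fitted logarithmic curve

```
P(T) = 1 - 0.196 ln(T)      (T in months)
```

clamped to 1 for T <= 1 month and held at its 20 % floor from month 60
onward. The fit passes within one point of the source data at 6, 12, 36, 48
and 60 months; the 24-month source datum (41 %) is a known misfit of the
logarithmic form (fit: 37.7 %) and the fit is used throughout.

Protection does not stop at discontinuation. A woman treated for `T` months
is protected for

```
y(T) = 13.5 exp(0.048 T)    months from initiation,  y(0) = 0
```

so twelve months of treatment protect for two years, and about four years of
treatment protect for the entire ten-year horizon. `y(0) = 0` is imposed
piecewise because the raw formula would grant 13.5 protected months to a
woman who never started.

The two curves combine into the cohort protected proportion at month `m`:
a woman is protected if still on drug or if her residual effect covers `m`,
which gives `protected(m) = P(min(m, T*(m)))` with `T*(m) = ln(m/13.5)/0.048`
the shortest treatment duration whose residual effect reaches `m` (every
initiator is protected through month 13.5). The microsimulation does not use
this cohort curve directly: each woman draws one discontinuation time at
baseline by inverse transform (`u < 0.20` maps to "never within the
horizon"), and is protected in cycle `c` iff `12(c-1) < y(T)`. The cohort
closed form is retained as the deterministic oracle that the sampling must
match, and the test suite verifies the two against each other at months 12,
36, 60 and 120 with 10^5 draws.

## Costs

All costs are 2010 euros, discounted at 5 % per year with the end-of-cycle
factor `1/(1+r)^cycle`; an undiscounted ledger is kept in parallel. Fracture
management costs are charged once, in full, at the cycle of the event —
11,419 EUR (hip), 3,305 EUR (wrist), 5,872 EUR (symptomatic vertebral),
0 for morphometric-only vertebral events — since the unit costs already
bundle hospitalisation and rehabilitation. The hospitalisation component of
these costs comes from the DRG weighted-average method,
`sum(count x unit cost) / sum(count)` over the disease-related groups of a
fracture site; the package reproduces the vertebral case (26,490 stays,
93,325,278 EUR, 3,523 EUR per stay) from synthetic DRG decompositions of the
published totals. The published hip and wrist unit costs are not consistent
with their own aggregate/count ratios, so only the method and the vertebral
case are verified.

Drug cost converts the 12-week pack price (generic 52.23 EUR by default;
branded 87.46 EUR as a sensitivity switch) to an annual cost with a 52-week
year (`x 52/12`; a calendar-year convention is selectable and differs by
< 0.4 %). A woman alive at the start of a cycle accrues that cycle's drug
cost in full — death does not interrupt accrual mid-cycle.

**Drug accrual cap.** Drug cost accrues only while on treatment *and within
the first 48 months* (`drug_cost_months_cap`, configurable; `Inf` disables
the cap). The rationale: 48 months of treatment already confer protection
for the entire ten-year horizon, so within this model later packs buy
nothing, and — decisively — the source model's own cost accounting behaves
this way: its no-treatment arm's undiscounted cost equals its clinical
fracture counts times the unit costs, which fixes the implied drug outlays
at roughly the integral of the persistence curve up to ~48 months
(real-world) and ~4 years of drug (ideal). Charging the ideal arm a full ten
years of drug would roughly double its drug bill and reverse the model's
central dominance finding. With the cap, the ideal arm charges four full
cycles of drug and nothing after; a real-world never-discontinuer stops
accruing at the cap too.

## Cost-effectiveness analyses

Pairwise comparisons (real-world vs no treatment; ideal vs real-world) use
mean total cost per patient against two effectiveness criteria measured over
all simulated patients: the proportion of fractured women (at least one
clinical fracture — hip, wrist or symptomatic vertebral) and the proportion
of premature deaths (deaths drawn under an active excess-mortality window).
An intervention *dominates* when it is both cheaper and has fewer bad
outcomes; the ratio reported alongside is the magnitude `|Δcost/Δeffect|`,
euros per case avoided. Mean costs are compared with the two-sample Student
t-test (equal variances) at the 0.05 threshold.

The persistence sweep re-runs the engine over mixing weights `λ` of the
improved curve `P_λ(T) = P(T) + λ(1 - P(T))`, from real-world (`λ = 0`) to
ideal (`λ = 1`), all levels sharing one seed and population (common random
numbers, so the endpoints reproduce the real-world and ideal arms exactly).
Because the published sweep axis is unlabelled, the x-axis here is the
one-year persistence `100 P_λ(12)` in percent, and the reported slope is the
least-squares change in mean total discounted cost per ten percentage
points. The national budget impact divides the per-patient 10-year cost
difference by the horizon and multiplies by the diagnosed population
(default 1.13 million women); the difference is an explicit input, since the
source's own rounding of it (270 vs 277 EUR) is ambiguous.

## Synthetic inputs

The published model rests on three inputs that were cited but never printed.
They are generated, clearly labelled as synthetic:

* **Population** — ages from a normal distribution, mean 70.5, SD 9.7,
  truncated to [50, 100] (risks are undefined below 50); prior-fracture
  prevalence 59.7 %. Truncation pulls the realised mean to ≈ 70.9, between
  the source's two inconsistent figures (70.5 cohort mean, 71.1 start age);
  the generator targets the cohort values and the discrepancy is left as
  is.
* **Life table** — a Gompertz stand-in `q(age) = min(1, a e^{b age})` on
  ages 50–110, calibrated so q(70) = 0.012 with mortality doubling every 8
  years, terminal age forced to q = 1. This is a synthetic assumption, not
  a national statistic, and it is lighter at very old ages than real
  schedules.
* **Excess mortality** — first-year multipliers 2.5 after hip and 2.0 after
  symptomatic vertebral fracture, one-year window, none after wrist.

Consequences: absolute fracture counts, death counts and arm-level mean
costs depend on these stand-ins and are *not* expected to reproduce the
published tables numerically. What the tests do assert is everything
upstream of them (persistence, residual protection, risk products, costing
arithmetic, DRG method), the engine's exact agreement with an enumerated
cohort oracle, and the qualitative economic findings — dominance of more
persistent alternatives on cost, fractured women and premature deaths, and
a negative cost-per-persistence slope — which hold across seeds with the
synthetic inputs.

## Numerical choices and degenerate inputs

* Percent inputs are converted to probabilities once, at construction.
* Fracture probabilities are capped at 1 after the risk product.
* Certain death (`q = 1`) still allows the cycle's fracture draws first, so
  a fracture and a fracture-related death can share a cycle.
* The engine pre-draws all uniforms in a fixed layout (discontinuation,
  then per-cycle site/symptomatic/death matrices), making runs bit
  reproducible given (seed, parameters, population) and aligning draws
  across alternatives run with the same seed.
* `sample_discontinuation` clamps to >= 1 month; `u` exactly 0 or 1 is
  rejected.
* Empty DRG tables, zero-variance t-tests, mismatched arm sizes and cycles
  beyond the horizon are errors, not silent results.
* The cohort oracle refuses instances above 5 cycles: from cycle 3 onward
  real-world protection is no longer deterministic and the oracle's
  per-cycle independence approximation would silently degrade.

## Problem sizes

The package's own test runs use 30,000 women per arm (the published
simulation size) for the dominance checks over five seeds, 200,000 women for
the oracle-equivalence check (one age band, two cycles, agreement within
three Monte Carlo standard errors), 10^5 draws for the sampling-vs-closed-form
persistence checks, and 10,000 women per level for the sweep-slope sign
check. A full three-arm run at n = 30,000 takes under a second.

## Limitations

* No half-cycle correction; all events and costs land at cycle ends.
* No treatment switching, no monthly-regimen persistence, no QALYs
  (deliberately: the effectiveness criteria are clinical proportions).
* Only the three canonical fracture sites; no multiple fractures of the
  same site within one cycle.
* Indirect and transport costs are excluded; euros are fixed at 2010 with
  no inflation adjustment.
* The life table and excess-mortality inputs are synthetic stand-ins, so
  absolute counts and costs carry no external validity; comparative and
  methodological results are the package's reproducible surface.
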