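Package: persistcea
Title: Cost of Non-Persistence with Oral Bisphosphonates by Markov Microsimulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level (first-order Monte Carlo) Markov microsimulation
    of osteoporotic fractures (vertebra, hip, wrist) in post-menopausal women
    over a ten-year horizon, under three bisphosphonate persistence
    alternatives: no treatment, real-world persistence and ideal persistence.
    Implements the fitted logarithmic persistence curve, the exponential
    residual-protection (offset) effect and their convolution into a protected
    proportion; age-band fracture risks with prior-fracture and post-fracture
    relative risks and treatment risk multipliers; fracture-management and
    drug cost accrual with annual discounting; DRG weighted-average fracture
    costing; pairwise cost-effectiveness ratios with dominance detection; a
    persistence-to-cost sweep; and national budget extrapolation. Includes a
    synthetic-input generator for the simulated population, a Gompertz
    stand-in life table and DRG cost fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
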