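# Model parameters: every clinical and economic input of the fracture
# microsimulation, as one validated bundle that can be written to and read
# from a JSON parameter file.

.SITES <- c("vertebra", "hip", "wrist")
.STATES <- c("pmo", "post_vertebral", "post_hip", "post_wrist")

#' Default model parameters
#'
#' Builds the complete parameter bundle of the model with its published
#' default values: age-band absolute fracture risks (stored as annual
#' probabilities, not percentages), relative risks associated with a prior
#' fracture and with each post-fracture health state, treatment risk
#' multipliers while protected by a bisphosphonate, the logarithmic
#' persistence curve and exponential residual-protection coefficients,
#' fracture management costs, drug prices per 12 weeks (generic base case
#' and branded alternative), the 5\% annual discount rate, the symptomatic
#' fraction of vertebral fractures, the size of the national diagnosed
#' population and the 10-year horizon.
#'
#' Cells of the relative-risk and treatment-multiplier matrices that have no
#' published value are stored as `NA` and resolved at use time according to
#' `na_policy` (see [annual_fracture_probability()]).
#'
#' @return An object of class `bp_params`: a named list with components
#'   `risk_table`, `rr_prior`, `rr_state`, `treat_mult`, `persistence`,
#'   `residual`, `costs` and `na_policy`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$costs$management[["hip"]]
#' lookup_absolute_risk(p$risk_table, 72, "hip")
default_parameters <- function() {
  rr_state <- matrix(
    c(4.4, 2.3, 1.4,
      2.5, 2.3, NA,
      1.7, 1.9, 3.3),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("post_vertebral", "post_hip", "post_wrist"), .SITES)
  )
  treat_mult <- matrix(
    c(0.526, 0.672, 0.833,
      0.575, 0.620, NA,
      NA,    0.620, NA,
      0.575, 0.620, 0.566),
    nrow = 4, byrow = TRUE,
    dimnames = list(.STATES, .SITES)
  )
  p <- list(
    risk_table = default_risk_table(),
    rr_prior = c(vertebra = 2.0, hip = 2.0, wrist = 1.9),
    rr_state = rr_state,
    treat_mult = treat_mult,
    persistence = list(b = 0.196, floor = 0.20, floor_onset = 60,
                       min_duration = 1),
    residual = list(a = 13.5, k = 0.048),
    costs = list(
      management = c(vertebra = 5872, hip = 11419, wrist = 3305),
      drug_price_12wk = 52.23,
      drug_price_12wk_branded = 87.46,
      weeks_per_year = 52,
      drug_cost_months_cap = 48,
      discount_rate = 0.05,
      symptomatic_fraction = 0.23,
      national_population = 1130000,
      horizon_years = 10
    ),
    na_policy = "nearest"
  )
  class(p) <- "bp_params"
  validate_parameters(p)
}

#' Default age-band absolute fracture risk table
#'
#' Annual absolute fracture probabilities per site for women aged 50 and
#' over, in contiguous five-year bands up to an open-ended band above 84.
#' Published percent-per-year values are converted to probabilities once,
#' here.
#'
#' @return A data frame with columns `age_lo`, `age_hi` (exclusive upper
#'   bound, `Inf` for the last band), `vertebra`, `hip`, `wrist`.
#' @export
default_risk_table <- function() {
  data.frame(
    age_lo = c(50, 55, 60, 65, 70, 75, 80, 85),
    age_hi = c(55, 60, 65, 70, 75, 80, 85, Inf),
    vertebra = c(3.10, 3.59, 4.15, 4.81, 5.56, 6.44, 7.45, 8.62) / 100,
    hip     = c(0.00, 0.06, 0.20, 0.34, 0.65, 1.04, 1.62, 3.52) / 100,
    wrist   = c(2.99, 3.20, 3.18, 2.06, 1.97, 1.17, 0.92, 0.92) / 100
  )
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the model inputs and fails with an
#' error naming the offending field: risk-table bands must be contiguous
#' from age 50 with all probabilities in \[0, 1\] and all three sites
#' present; relative risks must be finite and positive where present;
#' treatment multipliers must lie in (0, 1\] (protective); persistence and
#' residual coefficients positive with the floor in \[0, 1\]; costs
#' non-negative; discount rate in \[0, 1); symptomatic fraction in \[0, 1\].
#'
#' @param params A `bp_params` bundle as produced by [default_parameters()]
#'   or [load_parameters()].
#' @return `params`, invisibly usable, returned unchanged on success.
#' @export
validate_parameters <- function(params) {
  rt <- params$risk_table
  need <- c("age_lo", "age_hi", .SITES)
  if (!all(need %in% names(rt)))
    stop("risk_table: missing column(s): ",
         paste(setdiff(need, names(rt)), collapse = ", "))
  if (rt$age_lo[1] != 50)
    stop("risk_table$age_lo: bands must start at age 50")
  if (nrow(rt) > 1 && any(rt$age_lo[-1] != rt$age_hi[-nrow(rt)]))
    stop("risk_table: age bands must be contiguous")
  if (!is.infinite(rt$age_hi[nrow(rt)]))
    stop("risk_table$age_hi: last band must be open-ended (Inf)")
  for (s in .SITES) {
    v <- rt[[s]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("risk_table$", s, ": probabilities must be finite and in [0, 1]")
  }
  rp <- params$rr_prior
  if (!all(.SITES %in% names(rp)) || any(!is.finite(rp)) || any(rp <= 0))
    stop("rr_prior: all three sites required, finite and > 0")
  .check_mat <- function(m, nm, upper = Inf) {
    if (!all(colnames(m) == .SITES)) stop(nm, ": columns must be ", paste(.SITES, collapse = "/"))
    v <- m[!is.na(m)]
    if (any(!is.finite(v)) || any(v <= 0) || any(v > upper))
      stop(nm, ": non-NA entries must be finite, > 0",
           if (is.finite(upper)) paste0(" and <= ", upper))
  }
  .check_mat(params$rr_state, "rr_state")
  .check_mat(params$treat_mult, "treat_mult", upper = 1)
  pp <- params$persistence
  if (!(pp$b > 0 && pp$b < 1)) stop("persistence$b: must be in (0, 1)")
  if (pp$floor < 0 || pp$floor > 1) stop("persistence$floor: must be in [0, 1]")
  if (pp$floor_onset <= 0) stop("persistence$floor_onset: must be > 0")
  rs <- params$residual
  if (rs$a <= 0) stop("residual$a: must be > 0")
  if (rs$k <= 0) stop("residual$k: must be > 0")
  co <- params$costs
  co_need <- c("management", "drug_price_12wk", "weeks_per_year",
               "drug_cost_months_cap", "discount_rate",
               "symptomatic_fraction", "national_population", "horizon_years")
  if (!all(co_need %in% names(co)))
    stop("costs: missing field(s): ",
         paste(setdiff(co_need, names(co)), collapse = ", "))
  if (!all(.SITES %in% names(co$management)) || any(co$management < 0))
    stop("costs$management: one non-negative cost per site required")
  if (co$drug_price_12wk < 0) stop("costs$drug_price_12wk: must be >= 0")
  if (co$drug_cost_months_cap <= 0)
    stop("costs$drug_cost_months_cap: must be > 0 (Inf for uncapped accrual)")
  if (co$discount_rate < 0 || co$discount_rate >= 1)
    stop("costs$discount_rate: must be in [0, 1)")
  if (co$symptomatic_fraction < 0 || co$symptomatic_fraction > 1)
    stop("costs$symptomatic_fraction: must be in [0, 1]")
  if (co$national_population <= 0) stop("costs$national_population: must be > 0")
  if (co$horizon_years < 1) stop("costs$horizon_years: must be >= 1")
  if (!params$na_policy %in% c("nearest", "one"))
    stop("na_policy: must be 'nearest' or 'one'")
  params
}

#' Look up the annual absolute fracture risk for an age and site
#'
#' Piecewise-constant lookup in the age-band risk table; ages at or above
#' the last band's lower bound use the open-ended band. Total over all ages
#' of at least 50 years.
#'
#' @param table Risk table data frame (see [default_risk_table()]).
#' @param age Numeric vector of ages in years, all >= 50.
#' @param site One of `"vertebra"`, `"hip"`, `"wrist"`.
#' @return Annual fracture probability, same length as `age`.
#' @export
#' @examples
#' lookup_absolute_risk(default_risk_table(), 72, "hip")   # 0.0065
#' lookup_absolute_risk(default_risk_table(), 90, "vertebra")
lookup_absolute_risk <- function(table, age, site) {
  site <- match.arg(site, .SITES)
  if (any(age < 50)) stop("age must be >= 50: risks are undefined below 50")
  table[[site]][findInterval(age, table$age_lo)]
}

#' Write a parameter bundle to a JSON file
#'
#' Full double precision is retained so that a write/load round trip
#' reproduces the bundle exactly. The open-ended upper age bound is stored
#' as `null` and restored as `Inf` on load.
#'
#' @param params A validated `bp_params` bundle.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  out <- unclass(params)
  rt <- out$risk_table
  rt$age_hi[is.infinite(rt$age_hi)] <- NA_real_
  out$risk_table <- rt
  out$rr_state <- .mat_to_df(out$rr_state)
  out$treat_mult <- .mat_to_df(out$treat_mult)
  out$rr_prior <- as.list(out$rr_prior)
  out$costs$management <- as.list(out$costs$management)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load and validate a parameter bundle from a JSON file
#'
#' @param path Path to a JSON parameter file as written by
#'   [write_parameters()]. The file shipped at
#'   `system.file("extdata", "default-parameters.json", package = "persistcea")`
#'   holds the published default values.
#' @return A validated `bp_params` bundle.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("risk_table", "rr_prior", "rr_state", "treat_mult",
            "persistence", "residual", "costs", "na_policy")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("parameter file: missing field(s): ",
                         paste(miss, collapse = ", "))
  rt <- as.data.frame(raw$risk_table)
  rt$age_hi[is.na(rt$age_hi)] <- Inf
  raw$risk_table <- rt
  raw$rr_state <- .df_to_mat(raw$rr_state)
  raw$treat_mult <- .df_to_mat(raw$treat_mult)
  raw$rr_prior <- unlist(raw$rr_prior)
  raw$costs$management <- unlist(raw$costs$management)
  class(raw) <- "bp_params"
  validate_parameters(raw)
}

.mat_to_df <- function(m) {
  data.frame(state = rownames(m), as.data.frame(m, check.names = FALSE),
             check.names = FALSE)
}

.df_to_mat <- function(df) {
  df <- as.data.frame(df)
  m <- as.matrix(df[, .SITES, drop = FALSE])
  rownames(m) <- df$state
  m
}

#' Read an age-band risk table from CSV
#'
#' Expects columns `age_lo`, `age_hi`, `vertebra`, `hip`, `wrist`. Values
#' are annual probabilities unless `percent = TRUE`, in which case they are
#' divided by 100 once, on import. A missing upper bound on the last band is
#' read as open-ended.
#'
#' @param path CSV file path.
#' @param percent Are the site columns expressed in percent per year?
#' @return A risk table data frame.
#' @export
read_risk_table_csv <- function(path, percent = FALSE) {
  rt <- utils::read.csv(path)
  need <- c("age_lo", "age_hi", .SITES)
  if (!all(need %in% names(rt)))
    stop("risk table CSV must have columns: ", paste(need, collapse = ", "))
  rt <- rt[need]
  rt$age_hi[is.na(rt$age_hi)] <- Inf
  if (percent) for (s in .SITES) rt[[s]] <- rt[[s]] / 100
  rt
}

#' @export
print.bp_params <- function(x, ...) {
  cat("<bp_params> fracture microsimulation inputs\n")
  cat("  risk bands:", nrow(x$risk_table), "(ages 50+)\n")
  cat(sprintf("  persistence: P(T) = 1 - %g ln(T), floor %g from %g months\n",
              x$persistence$b, x$persistence$floor, x$persistence$floor_onset))
  cat(sprintf("  residual protection: y(T) = %g exp(%g T) months\n",
              x$residual$a, x$residual$k))
  cat(sprintf("  costs: hip %g / wrist %g / symptomatic vertebra %g EUR; drug %g EUR per 12 wk; discount %g\n",
              x$costs$management[["hip"]], x$costs$management[["wrist"]],
              x$costs$management[["vertebra"]], x$costs$drug_price_12wk,
              x$costs$discount_rate))
  invisible(x)
}
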