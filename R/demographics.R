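# Age-indexed background inputs: mortality (life table), background
# healthcare cost, and baseline health-related quality-of-life utility.
# Shipped as synthetic US-male-style fixtures with level-calibration hooks.

#' Load the packaged synthetic life table
#'
#' The fixture is an abridged (pivot-age) table; annual death probabilities
#' are log-linearly interpolated to single years of age 0-110. The terminal
#' age is absorbing (q = 1).
#'
#' @param path Path to a tab-separated file with columns `age`, `q_annual`.
#' @return A data frame of class `life_table` with columns `age` (0-110) and
#'   `q_annual`.
#' @export
load_life_table <- function(path = system.file("extdata",
    "life_table_us_male_synthetic.tsv", package = "appendcea",
    mustWork = TRUE)) {
  raw <- read.delim(path, comment.char = "#")
  ages <- 0:110
  # log-linear interpolation of hazards between pivot ages
  q <- exp(stats::approx(raw$age, log(raw$q_annual), xout = ages,
                         rule = 2)$y)
  q[ages >= max(raw$age)] <- 1
  out <- data.frame(age = ages, q_annual = pmin(q, 1))
  class(out) <- c("life_table", "data.frame")
  out
}

#' Load the packaged background cost and baseline utility schedule
#'
#' @param path Path to a tab-separated file with columns `age`,
#'   `annual_cost`, `baseline_utility` at pivot ages.
#' @return A data frame of class `background_schedule` with one row per year
#'   of age 0-110.
#' @export
load_background_schedule <- function(path = system.file("extdata",
    "background_schedule_synthetic.tsv", package = "appendcea",
    mustWork = TRUE)) {
  raw <- read.delim(path, comment.char = "#")
  ages <- 0:110
  out <- data.frame(
    age = ages,
    annual_cost = stats::approx(raw$age, raw$annual_cost, xout = ages,
                                rule = 2)$y,
    baseline_utility = stats::approx(raw$age, raw$baseline_utility,
                                     xout = ages, rule = 2)$y
  )
  class(out) <- c("background_schedule", "data.frame")
  out
}

#' Bundle the demographic inputs
#'
#' @param life_table A `life_table` (default: packaged fixture).
#' @param background A `background_schedule` (default: packaged fixture).
#' @return A list of class `demographics`.
#' @export
load_demographics <- function(life_table = load_life_table(),
                              background = load_background_schedule()) {
  structure(list(life_table = life_table, background = background),
            class = "demographics")
}

#' Monthly background mortality at a given age in months
#'
#' Converts the annual death probability of the integer age containing
#' `age_months` to a constant monthly probability,
#' 1 - (1 - q_annual)^(1/12). Ages beyond the table return 1.
#'
#' @param table A `life_table`.
#' @param age_months Age in months (integer).
#' @return Monthly death probability.
#' @export
monthly_mortality <- function(table, age_months) {
  age <- age_months %/% 12L
  q <- ifelse(age > max(table$age), 1,
              table$q_annual[pmin(age, max(table$age)) + 1L])
  1 - (1 - q)^(1 / 12)
}

#' Undiscounted remaining life expectancy
#'
#' Sums monthly survival from `start_age_years` with a half-month (trapezoid)
#' convention, in years. Used to sanity-check the packaged table and to
#' spread the lifetime tail recurrence risk over remaining lifespan.
#'
#' @param table A `life_table`.
#' @param start_age_years Integer starting age within the table.
#' @return Expected remaining years.
#' @export
life_expectancy <- function(table, start_age_years) {
  if (start_age_years > max(table$age)) stop("start age beyond life table")
  months <- (start_age_years * 12L):(max(table$age) * 12L + 11L)
  qm <- monthly_mortality(table, months)
  surv <- cumprod(1 - qm)
  # trapezoid: people dying in a month live half of it on average
  sum((c(1, surv[-length(surv)]) + surv) / 2) / 12
}

# Monthly survival-curve helper (internal): survival to each month m >= 1
# from start_age for T months.
.monthly_survival <- function(table, start_age, n_months) {
  months <- start_age * 12L + seq_len(n_months) - 1L
  cumprod(1 - monthly_mortality(table, months))
}

#' Level-calibrate the background schedules against lifetime anchors
#'
#' Adjusts two scalar multipliers - one on the background annual cost, one
#' on the baseline utility - so that the full model (outpatient nonoperative
#' management strategy at the anchor start age, base-case parameters)
#' reproduces target lifetime discounted cost and QALY totals. Both totals
#' are affine in their respective multiplier, so each is solved exactly from
#' two model evaluations. The age gradient (shape) of the schedules is never
#' altered, only their level.
#'
#' @param demographics A `demographics` bundle.
#' @param params A `parameter_set`.
#' @param targets List with elements `cost` and `qaly`: lifetime discounted
#'   totals for the outpatient-NOM arm at `config$start_age`.
#' @param config A `model_config`; its `start_age` anchors the calibration.
#' @param tolerance Relative tolerance on the reproduced targets.
#' @return A list of class `calibration`: the calibrated
#'   `background_schedule`, `cost_multiplier`, `utility_multiplier`, and the
#'   relative `residuals` achieved. Multipliers outside \[0.25, 4\] raise a
#'   calibration-failure error.
#' @export
calibrate_background <- function(demographics, params,
                                 targets = list(cost = 233700, qaly = 24.9270),
                                 config = model_config(),
                                 tolerance = 0.005) {
  eval_at <- function(cost_mult, util_mult) {
    d <- demographics
    d$background$annual_cost <- d$background$annual_cost * cost_mult
    d$background$baseline_utility <-
      pmin(d$background$baseline_utility * util_mult, 1)
    summary(run_strategy("OUTPATIENT_NOM", params, d, config))
  }
  base0 <- eval_at(0, 1)    # cost with background stripped out
  base1 <- eval_at(1, 1)
  cost_mult <- (targets$cost - base0[["cost"]]) /
    (base1[["cost"]] - base0[["cost"]])

  # QALYs are affine in the utility multiplier while no interpolated value
  # hits the cap of 1; solve linearly, then verify.
  q1 <- base1[["qaly"]]
  q0 <- eval_at(1, 0.5)[["qaly"]]
  slope <- (q1 - q0) / 0.5
  util_mult <- 1 + (targets$qaly - q1) / slope

  if (cost_mult < 0.25 || cost_mult > 4 || util_mult < 0.25 || util_mult > 4) {
    stop("calibration failure: required multipliers (cost ",
         round(cost_mult, 3), ", utility ", round(util_mult, 3),
         ") outside [0.25, 4]")
  }
  achieved <- eval_at(cost_mult, util_mult)
  residuals <- c(cost = achieved[["cost"]] / targets$cost - 1,
                 qaly = achieved[["qaly"]] / targets$qaly - 1)
  if (any(abs(residuals) > tolerance)) {
    stop("calibration failure: residuals ",
         paste(sprintf("%s=%.4f", names(residuals), residuals),
               collapse = ", "), " exceed tolerance ", tolerance)
  }
  out <- demographics$background
  out$annual_cost <- out$annual_cost * cost_mult
  out$baseline_utility <- pmin(out$baseline_utility * util_mult, 1)
  structure(list(schedule = out, cost_multiplier = cost_mult,
                 utility_multiplier = util_mult, residuals = residuals),
            class = "calibration")
}
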