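# Lifetime monthly-cycle Markov cohort model. Health states: POST_SURGERY
# (appendix removed), POST_NOM (appendix in situ), single-cycle event
# tunnel states (late recurrence, long-term postoperative complication),
# appendiceal cancer states (adenocarcinoma / carcinoid, tracked by month in
# state for the year-indexed mortality schedules, with a chronic state for
# patients not in remission after year 5), CANCER_REMISSION (behaves as
# POST_SURGERY), and absorbing DEAD. Cycle propagation runs in compiled
# code (src/engine.cpp); this file builds its per-cycle inputs.

#' Convert an annual probability to a monthly probability
#'
#' Constant-hazard conversion 1 - (1 - p)^(1/12).
#'
#' @param p_annual Annual probability in \[0,1\].
#' @return Monthly probability.
#' @export
annual_to_monthly <- function(p_annual) {
  stopifnot(all(p_annual >= 0 & p_annual <= 1))
  1 - (1 - p_annual)^(1 / 12)
}

#' Monthly hazards from a cumulative year-indexed schedule
#'
#' For year k with cumulative incidence C_k (C_0 = 0), the constant monthly
#' conditional probability within that year is
#' 1 - ((1 - C_k) / (1 - C_{k-1}))^(1/12).
#'
#' @param s A `schedule` with `cumulative = TRUE`.
#' @return Numeric vector of monthly probabilities, one per schedule year.
#' @export
schedule_to_monthly_hazards <- function(s) {
  if (!isTRUE(s$cumulative)) {
    stop("schedule '", s$name, "' is not cumulative")
  }
  cum <- c(0, s$values)
  if (any(diff(cum) < 0)) stop("cumulative schedule '", s$name,
                               "' is decreasing")
  surv_ratio <- (1 - cum[-1]) / (1 - cum[-length(cum)])
  1 - surv_ratio^(1 / 12)
}

# Assemble every per-cycle vector and scalar the compiled cohort/microsim
# engines need. `flags` supports the structural scenario switches.
.engine_inputs <- function(params, demographics, config,
                           flags = character()) {
  p <- function(n) base_value(params, n)
  lt <- demographics$life_table
  bg <- demographics$background
  T <- (config$age_cap - config$start_age) * 12L

  months <- config$start_age * 12L + 0:T           # age in months at cycle m
  ages <- pmin(months %/% 12L, max(bg$age))
  q_bg <- c(0, monthly_mortality(lt, months[2:(T + 1)] - 1L))
  bg_cost_m <- bg$annual_cost[ages + 1L] / 12
  u_base <- bg$baseline_utility[ages + 1L]
  disc <- (1 + config$discount_rate)^(-(0:T) / 12)

  # recurrence hazard: year-specific within the 5-year schedule, then the
  # lifetime-mass tail spread over remaining life expectancy at year 5
  rec <- params$schedules$recurrence_after_NOM
  h_year <- schedule_to_monthly_hazards(rec)
  n_sched <- 12L * length(h_year)
  le_tail_months <- max(12, round(12 * life_expectancy(
    lt, min(config$start_age + length(h_year), max(lt$age)))))
  h_tail <- 1 - (1 - p("p_recurrence_tail_lifetime"))^(1 / le_tail_months)
  h_rec <- c(0, ifelse(1:T <= n_sched,
                       h_year[pmin((1:T - 1L) %/% 12L + 1L, length(h_year))],
                       h_tail))
  if ("no_failure_or_recurrence" %in% flags) h_rec[] <- 0

  # cancer presentation: the lifetime malignancy mass spread as a constant
  # monthly hazard over the 10 years after index presentation, POST_NOM only
  h_can <- c(0, ifelse(1:T <= 120L,
                       1 - (1 - p("p_appendiceal_malignancy"))^(1 / 120),
                       0))
  if ("no_cancer_after_NOM" %in% flags) h_can[] <- 0

  tunnel_hazards <- function(mort_name) {
    hz <- schedule_to_monthly_hazards(params$schedules[[mort_name]])
    list(monthly = rep(hz, each = 12L), chronic = hz[length(hz)])
  }
  ad <- tunnel_hazards("adeno_mortality")
  ca <- tunnel_hazards("carcinoid_mortality")
  # fraction of cancer survivors whose quality of life is back at baseline,
  # by month in state (remission series; last value carried forward)
  remfrac <- function(nm) rep(params$schedules[[nm]]$values, each = 12L)
  rem5 <- function(nm) {
    v <- params$schedules[[nm]]$values
    v[length(v)]
  }

  # blended late-recurrence event: complicated -> drain + interval
  # appendectomy; uncomplicated -> direct appendectomy (with its
  # perioperative risks); second ER visit at re-presentation
  pc <- p("p_complicated_recurrence")
  p_stc <- p("p_short_term_complication")
  p_pm <- p("p_perioperative_mortality")
  p_mca <- p("p_mortality_complicated_appendectomy")
  er <- p("cost_er_visit"); appy <- p("cost_laparoscopic_appendectomy")
  c_rec <- pc * (er + p("cost_percutaneous_drain") + appy) +
    (1 - pc) * (er + appy + p_stc * p("cost_short_term_complication"))
  d_rec <- pc * p_mca + (1 - pc) * p_pm
  u_rec_num <- pc * (1 - p_mca) * p("u_interval_appendectomy") +
    (1 - pc) * (1 - p_pm) *
      ((1 - p_stc) * p("u_recurrent_appendicitis") +
         p_stc * p("u_appendectomy_with_complication"))
  u_rec <- if (d_rec < 1) u_rec_num / (1 - d_rec) else 0

  pars <- list(
    h_ltc = annual_to_monthly(p("p_long_term_complication_annual")),
    p_death_ltc = p("p_mortality_lt_complication"),
    c_ltc = p("cost_long_term_complication"),
    u_ltc = p("u_appendectomy_with_complication"),
    ltc_window = 24L,  # months of long-term complication risk after surgery
    c_rec = c_rec, d_rec = d_rec, u_rec = u_rec,
    frac_carc = 0.7,   # 70% carcinoid / 30% adenocarcinoma split
    c_adeno = p("cost_hemicolectomy") + p("cost_folfox_chemotherapy"),
    c_carc = p("cost_hemicolectomy"),
    h_adeno = ad$monthly, h_adeno_chr = ad$chronic,
    h_carc = ca$monthly, h_carc_chr = ca$chronic,
    remfrac_adeno = remfrac("adeno_remission"),
    remfrac_carc = remfrac("carcinoid_remission"),
    r5_adeno = rem5("adeno_remission"), r5_carc = rem5("carcinoid_remission"),
    u_cancer = p("u_malignancy"),
    # microsim event-path details
    p_c_rec = pc, p_stc = p_stc, p_pm = p_pm, p_mca = p_mca,
    c_er = er, c_appy = appy, c_drain = p("cost_percutaneous_drain"),
    c_stc = p("cost_short_term_complication"),
    u_interval = p("u_interval_appendectomy"),
    u_recur = p("u_recurrent_appendicitis"),
    u_comp = p("u_appendectomy_with_complication")
  )
  list(T = T, q_bg = q_bg, bg_cost = bg_cost_m, u_base = u_base,
       disc = disc, h_rec = h_rec, h_can = h_can, pars = pars)
}

#' Run the lifetime Markov cohort model from an acute-phase entry
#'
#' Propagates the cohort monthly from the acute-tree entry distribution to
#' the age cap, with age-indexed background mortality, background cost and
#' baseline utility; time-varying recurrence and cancer-presentation
#' hazards; discounting at the configured annual rate; and half-cycle
#' correction in trapezoid form (state payoffs of consecutive cycle
#' boundaries averaged). One-time event costs are charged in full at the
#' event cycle. Acute-window cost and quality-adjusted time from `entry`
#' are added undiscounted at time 0.
#'
#' @param entry An `acute_outcome` from [evaluate_acute()].
#' @param params A `parameter_set`.
#' @param demographics A `demographics` bundle.
#' @param config A `model_config`.
#' @param flags Character vector of structural scenario flags (subset of
#'   `no_cancer_after_NOM`, `no_failure_or_recurrence`).
#' @param trace Keep the per-cycle state-occupancy matrix and accumulators?
#' @return An object of class `cohort_trace` with `totals` (discounted
#'   `cost` in US$, `qaly` and `ly` in years), undiscounted counterparts,
#'   and, when `trace = TRUE`, `occupancy` plus per-cycle accumulators.
#' @export
run_cohort <- function(entry, params, demographics, config = model_config(),
                       flags = character(), trace = FALSE) {
  stopifnot(inherits(entry, "acute_outcome"))
  inp <- .engine_inputs(params, demographics, config, flags)
  res <- cohort_engine_cpp(inp$T, inp$q_bg, inp$bg_cost, inp$u_base,
                           inp$disc, inp$h_rec, inp$h_can, inp$pars,
                           entry$entry_mass[["POST_SURGERY"]],
                           entry$entry_mass[["POST_NOM"]],
                           entry$entry_mass[["DEAD"]],
                           entry$strategy != "LAP_APPY", trace)
  out <- list(
    strategy = entry$strategy,
    totals = c(cost = entry$acute_cost + res$cost_disc,
               qaly = (entry$acute_qalm + res$qalm_disc) / 12,
               ly = (entry$acute_ly + res$ly_disc) / 12),
    undiscounted = c(cost = entry$acute_cost + res$cost_undisc,
                     qaly = (entry$acute_qalm + res$qalm_undisc) / 12,
                     ly = (entry$acute_ly + res$ly_undisc) / 12),
    entry = entry,
    start_age_months = config$start_age * 12L,
    config = config
  )
  if (trace) {
    occ <- res$occupancy
    colnames(occ) <- c("POST_SURGERY", "POST_NOM", "RECURRENCE_EVENT",
                       "LT_COMPLICATION_EVENT_MASS", "CANCER_ADENO",
                       "CANCER_CARCINOID", "CANCER_REMISSION", "DEAD")
    out$occupancy <- occ
    out$cycles <- data.frame(cycle = 0:inp$T,
                             cost = res$cycle_cost, qalm = res$cycle_qalm,
                             ly = res$cycle_ly)
  }
  class(out) <- "cohort_trace"
  out
}

#' Summarize a cohort trace into lifetime totals
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return Named numeric: discounted `cost` (US$), `qaly`, `ly` (years).
#' @export
summary.cohort_trace <- function(object, ...) object$totals

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", x$strategy, " from age ",
      x$start_age_months / 12, "\n", sep = "")
  cat(sprintf("  discounted: cost $%.0f, QALY %.4f, LY %.4f\n",
              x$totals["cost"], x$totals["qaly"], x$totals["ly"]))
  invisible(x)
}

#' Export a cohort trace as a per-cycle table
#'
#' @param trace A `cohort_trace` produced with `trace = TRUE`.
#' @param path Optional path to write a tab-separated file.
#' @return Data frame with one row per cycle: state occupancies and
#'   discounted accumulators.
#' @export
export_trace <- function(trace, path = NULL) {
  if (is.null(trace$occupancy)) stop("run_cohort() was called without trace")
  df <- cbind(trace$cycles["cycle"], as.data.frame(trace$occupancy),
              trace$cycles[c("cost", "qalm", "ly")])
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  df
}

#' Run one strategy end-to-end (acute tree + Markov cohort)
#'
#' @inheritParams run_cohort
#' @param strategy One of [strategies()].
#' @return An object of class `strategy_result` with fields `strategy`,
#'   `cost`, `qaly`, `ly` (discounted lifetime totals).
#' @export
run_strategy <- function(strategy, params, demographics,
                         config = model_config(), flags = character()) {
  entry <- evaluate_acute(strategy, params)
  tr <- run_cohort(entry, params, demographics, config, flags)
  structure(list(strategy = strategy,
                 cost = unname(tr$totals["cost"]),
                 qaly = unname(tr$totals["qaly"]),
                 ly = unname(tr$totals["ly"])),
            class = "strategy_result")
}

#' @export
summary.strategy_result <- function(object, ...) {
  c(cost = object$cost, qaly = object$qaly, ly = object$ly)
}

#' Run all three strategies
#'
#' @inheritParams run_strategy
#' @return Data frame with columns `strategy`, `cost`, `qaly`, `ly`.
#' @export
run_model <- function(params, demographics, config = model_config(),
                      flags = character()) {
  rows <- lapply(strategies(), function(s) {
    r <- run_strategy(s, params, demographics, config, flags)
    data.frame(strategy = r$strategy, cost = r$cost, qaly = r$qaly,
               ly = r$ly)
  })
  do.call(rbind, rows)
}
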