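test_that("probability conversions have their closed forms", {
  expect_equal(annual_to_monthly(0), 0)
  expect_equal(annual_to_monthly(1), 1)
  expect_equal(annual_to_monthly(0.005), 4.17624589193e-4, tolerance = 1e-8)
  expect_error(annual_to_monthly(1.2))
})

test_that("cumulative schedules convert to within-year monthly hazards", {
  rec <- tp$schedules$recurrence_after_NOM
  hz <- schedule_to_monthly_hazards(rec)
  expect_length(hz, 5)
  expect_equal(hz[1], 1 - 0.727^(1 / 12), tolerance = 1e-12)
  expect_equal(hz[1], 0.0262192143976, tolerance = 1e-8)
  expect_equal(hz[5], 1 - (0.609 / 0.629)^(1 / 12), tolerance = 1e-12)
  expect_equal(hz[5], 2.68912688569e-3, tolerance = 1e-8)
  # flat cumulative schedule: no conditional hazard after year 1
  flat <- rec; flat$values <- rep(0.2, 5)
  expect_equal(schedule_to_monthly_hazards(flat)[2:5], rep(0, 4))
  # decreasing series are rejected as cumulative
  expect_error(schedule_to_monthly_hazards(tp$schedules$adeno_remission),
               "not cumulative")
  dec <- rec; dec$values <- c(0.3, 0.2, 0.2, 0.2, 0.2)
  bad <- tp; bad$schedules$recurrence_after_NOM <- dec
  expect_error(validate_parameters(bad), "non-decreasing")
})

test_that("the recurrence hazard seen by the engine matches the schedule", {
  inp <- appendcea:::.engine_inputs(tp, td, tcfg)
  hz <- schedule_to_monthly_hazards(tp$schedules$recurrence_after_NOM)
  # month 6 lies in year 1; month 13 in year 2
  expect_equal(inp$h_rec[6 + 1], hz[1])
  expect_equal(inp$h_rec[13 + 1], hz[2])
  # beyond year 5 the lifetime-mass tail applies, spread over remaining life
  le_m <- round(12 * life_expectancy(td$life_table, 25))
  expect_equal(inp$h_rec[61 + 1], 1 - (1 - 0.086)^(1 / le_m))
  # cancer presentation consumes the malignancy mass over 10 years
  expect_equal(prod(1 - inp$h_can[2:121]), 1 - 0.008, tolerance = 1e-12)
  expect_equal(inp$h_can[122 + 1], 0)
})

test_that("occupancy is conserved and death is monotone every cycle", {
  for (s in strategies()) {
    tr <- run_cohort(evaluate_acute(s, tp), tp, td, tcfg, trace = TRUE)
    occ <- tr$occupancy
    live_cols <- setdiff(colnames(occ), "LT_COMPLICATION_EVENT_MASS")
    expect_true(all(abs(rowSums(occ[, live_cols]) - 1) < 1e-9))
    expect_true(all(diff(occ[, "DEAD"]) >= -1e-12))
  }
})

test_that("with no risks, no discounting and full utility, QALYs equal life expectancy", {
  d0 <- flat_demographics(q = 0.02)
  cfg0 <- model_config(start_age = 20, discount_rate = 0)
  p0 <- tp
  for (nm in c("p_perioperative_mortality", "p_short_term_complication",
               "p_long_term_complication_annual")) {
    p0 <- with_value(p0, nm, 0)
  }
  p0 <- with_value(p0, "u_laparoscopic_appendectomy", 1)
  tr <- run_cohort(evaluate_acute("LAP_APPY", p0), p0, d0, cfg0)
  le <- life_expectancy(d0$life_table, 20)
  expect_equal(unname(tr$totals["ly"]), le, tolerance = 0.005)
  expect_equal(unname(tr$totals["qaly"]), unname(tr$totals["ly"]),
               tolerance = 1e-9)
})

test_that("an all-dead entry accrues only the acute phase", {
  entry <- evaluate_acute("LAP_APPY", tp)
  entry$entry_mass[] <- c(0, 0, 1)
  entry$acute_ly <- 0; entry$acute_qalm <- 0
  tr <- run_cohort(entry, tp, td, tcfg)
  expect_equal(unname(tr$totals["cost"]), entry$acute_cost)
  expect_equal(unname(tr$totals["qaly"]), 0)
  expect_equal(unname(tr$totals["ly"]), 0)
})

test_that("discounting can only shrink nonnegative payoff streams", {
  for (s in strategies()) {
    tr <- run_cohort(evaluate_acute(s, tp), tp, td, tcfg)
    expect_lte(tr$totals["cost"], tr$undiscounted["cost"])
    expect_lte(tr$totals["qaly"], tr$undiscounted["qaly"])
    expect_lte(tr$totals["ly"], tr$undiscounted["ly"])
    expect_lte(tr$totals["qaly"], tr$totals["ly"])
  }
})

test_that("per-cycle accumulators sum to the reported totals", {
  entry <- evaluate_acute("OUTPATIENT_NOM", tp)
  tr <- run_cohort(entry, tp, td, tcfg, trace = TRUE)
  expect_equal(sum(tr$cycles$cost) + entry$acute_cost,
               unname(tr$totals["cost"]), tolerance = 1e-8)
  expect_equal((sum(tr$cycles$qalm) + entry$acute_qalm) / 12,
               unname(tr$totals["qaly"]), tolerance = 1e-8)
  df <- export_trace(tr)
  expect_equal(nrow(df), (tcfg$age_cap - tcfg$start_age) * 12 + 1)
})

test_that("base-case strategy ordering matches the published pattern", {
  res <- run_model(tp, td, tcfg)
  cost <- setNames(res$cost, res$strategy)
  qaly <- setNames(res$qaly, res$strategy)
  expect_lt(cost["OUTPATIENT_NOM"], cost["LAP_APPY"])
  expect_lt(cost["LAP_APPY"], cost["INPATIENT_NOM"])
  expect_lt(qaly["OUTPATIENT_NOM"], qaly["INPATIENT_NOM"])
  expect_lt(qaly["INPATIENT_NOM"], qaly["LAP_APPY"])
})
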