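test_that("packaged registry reproduces the published base-case values", {
  spec <- tp$specs$cost_laparoscopic_appendectomy
  expect_equal(spec$base, 7606)
  expect_equal(spec$low, 3803)
  expect_equal(spec$high, 11409)
  expect_equal(spec$family, "normal")
  expect_equal(base_value(tp, "p_failure_outpatient_NOM"), 0.138)
  expect_equal(tp$schedules$recurrence_after_NOM$values,
               c(0.273, 0.34, 0.352, 0.371, 0.391))
  # inventory is complete: 9 costs, 8 utilities, 14 probability rows
  roles <- vapply(tp$specs, `[[`, character(1), "role")
  expect_equal(sum(roles == "cost"), 9)
  expect_equal(sum(roles == "utility"), 8)
  expect_equal(sum(roles == "probability"), 14)
  expect_length(tp$schedules, 5)
})

test_that("a missing parameter is reported by name", {
  broken <- tp
  broken$specs$u_successful_NOM <- NULL
  expect_error(validate_parameters(broken), "u_successful_NOM")
  broken2 <- tp
  broken2$schedules$adeno_mortality <- NULL
  expect_error(validate_parameters(broken2), "adeno_mortality")
})

test_that("with_value returns an edited copy and leaves the original alone", {
  p2 <- with_value(tp, "p_perioperative_mortality", 0.004)
  expect_equal(base_value(p2, "p_perioperative_mortality"), 0.004)
  expect_equal(base_value(tp, "p_perioperative_mortality"), 0.0005)
  # identity edit reproduces the same values
  p3 <- with_value(tp, "cost_er_visit", base_value(tp, "cost_er_visit"))
  expect_equal(as.data.frame(p3), as.data.frame(tp))
  # values outside the printed range but inside the legal domain are fine
  expect_silent(with_value(tp, "p_complicated_recurrence", 0))
  expect_error(with_value(tp, "p_complicated_recurrence", 1.5), "domain")
  expect_error(with_value(tp, "no_such_parameter", 1), "unknown")
})

test_that("serialization round-trips the full parameter set", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(tp, f)
  p2 <- load_parameters(f)
  expect_equal(as.data.frame(p2), as.data.frame(tp))
  expect_equal(p2$schedules, tp$schedules)
})

test_that("PSA draws are seed-reproducible and respect domains and ranks", {
  d1 <- sample_psa(tp, seed = 11)
  d2 <- sample_psa(tp, seed = 11)
  expect_identical(d1, d2)
  expect_false(identical(as.data.frame(sample_psa(tp, seed = 12)),
                         as.data.frame(d1)))
  util_names <- grep("^u_", names(tp$specs), value = TRUE)
  base_rank <- rank(-vapply(util_names, function(n) base_value(tp, n),
                            numeric(1)), ties.method = "first")
  for (s in 1:50) {
    dr <- sample_psa(tp, seed = 100 + s)
    df <- as.data.frame(dr)
    expect_true(all(df$base[df$role %in% c("probability", "utility")] >= 0))
    expect_true(all(df$base[df$role %in% c("probability", "utility")] <= 1))
    expect_true(all(df$base[df$role == "cost"] >= 0))
    draw_rank <- rank(-vapply(util_names, function(n) base_value(dr, n),
                              numeric(1)), ties.method = "first")
    expect_equal(draw_rank, base_rank)
    # schedules stay monotone after proportional scaling
    expect_true(all(diff(dr$schedules$recurrence_after_NOM$values) >= 0))
    # parameters without a range stay fixed
    expect_equal(base_value(dr, "p_complicated_failure_inpatient_NOM"), 0)
    expect_equal(base_value(dr, "p_recurrence_tail_lifetime"), 0.086)
  }
})

test_that("PSA beta draws are centered on the base value", {
  draws <- vapply(1:1500, function(s)
    base_value(sample_psa(tp, seed = 5000 + s), "p_failure_outpatient_NOM"),
    numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.138), 3 * se)
})
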