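test_that("one-way grids span the prescribed ranges", {
  ow <- one_way(tp, td, tcfg, "cost_laparoscopic_appendectomy",
                n_points = 11)
  expect_equal(ow$value[1], 0.5 * 7606)
  expect_equal(ow$value[11], 1.5 * 7606)
  ow2 <- one_way(tp, td, tcfg, "p_perioperative_mortality", n_points = 5)
  expect_equal(range(ow2$value), c(0.0005, 0.004))
  fixed <- one_way(tp, td, tcfg, "p_recurrence_tail_lifetime")
  expect_equal(nrow(fixed), 0)
  expect_match(attr(fixed, "note"), "fixed")
})

test_that("the one-way grid at the base value reproduces the base case", {
  ow <- one_way(tp, td, tcfg, "cost_laparoscopic_appendectomy",
                n_points = 11)
  base_row <- ow[ow$value == 7606, ]
  expect_equal(nrow(base_row), 1)
  base <- run_model(tp, td, tcfg)
  expect_equal(base_row$cost_LAP_APPY,
               base$cost[base$strategy == "LAP_APPY"])
  expect_equal(base_row$qaly_OUTPATIENT_NOM,
               base$qaly[base$strategy == "OUTPATIENT_NOM"])
  expect_equal(base_row$preferred,
               preferred_strategy(incremental_analysis(base, tcfg$wtp)))
})

test_that("threshold search brackets a genuine preference switch", {
  th <- find_threshold(tp, td, tcfg, "cost_laparoscopic_appendectomy",
                       c(0.5, 1.5) * 7606, pred_preferred("OUTPATIENT_NOM"))
  expect_true(is.finite(th))
  pred <- pred_preferred("OUTPATIENT_NOM")
  eps <- 4 * 1e-4 * th
  below <- pred(run_model(with_value(tp, "cost_laparoscopic_appendectomy",
                                     th - eps), td, tcfg), tcfg)
  above <- pred(run_model(with_value(tp, "cost_laparoscopic_appendectomy",
                                     th + eps), td, tcfg), tcfg)
  expect_false(below)
  expect_true(above)
  # constant predicate: a no-threshold result, not an error
  none <- find_threshold(tp, td, tcfg, "cost_er_visit", c(800, 1000),
                         pred_preferred("OUTPATIENT_NOM"))
  expect_true(is.na(none))
  expect_match(attr(none, "note"), "constant")
})

test_that("bisection agrees with a dense grid scan", {
  for (nm in c("cost_laparoscopic_appendectomy", "p_complicated_recurrence",
               "recurrence_after_NOM", "p_appendiceal_malignancy",
               "u_successful_NOM")) {
    rng <- appendcea:::.param_range(tp, nm)
    pred <- pred_preferred("OUTPATIENT_NOM")
    grid <- seq(rng[1], rng[2], length.out = 21)
    vals <- vapply(grid, function(v)
      pred(run_model(appendcea:::.set_param(tp, nm, v), td, tcfg), tcfg),
      logical(1))
    th <- find_threshold(tp, td, tcfg, nm, rng, pred)
    chg <- which(vals[-1] != vals[-21])
    if (length(chg) == 0) {
      expect_true(is.na(th), label = paste("no-threshold for", nm))
    } else {
      spacing <- diff(grid)[1]
      expect_true(any(abs(th - grid[chg]) <= spacing),
                  label = paste("bisection within grid spacing for", nm))
    }
  }
})

test_that("two-way region map has the expected corners", {
  tw <- two_way(tp, td, tcfg, "p_failure_outpatient_NOM",
                "recurrence_after_NOM",
                x_grid = c(0, 0.138), y_grid = c(0.02, 0.391))
  expect_equal(nrow(tw), 4)
  # no failure and almost no recurrence: the cheap strategy has no downside
  low <- tw$preferred[tw$x == 0 & tw$y == 0.02]
  expect_equal(low, "OUTPATIENT_NOM")
  # a 1x1 grid reduces to the base-case preferred strategy
  tw1 <- two_way(tp, td, tcfg, "p_failure_outpatient_NOM",
                 "recurrence_after_NOM", 0.138, 0.391)
  base_pref <- preferred_strategy(
    incremental_analysis(run_model(tp, td, tcfg), tcfg$wtp))
  expect_equal(tw1$preferred, base_pref)
})

test_that("PSA is seed-reproducible and its CEAC is coherent", {
  psa1 <- run_psa(tp, td, tcfg, n = 12, seed = 3,
                  wtp_grid = c(0, 25000, 50000, 100000))
  psa2 <- run_psa(tp, td, tcfg, n = 12, seed = 3,
                  wtp_grid = c(0, 25000, 50000, 100000))
  expect_identical(psa1$ceac, psa2$ceac)
  expect_identical(psa1$draws, psa2$draws)
  # fractions lie in [0,1] and sum to 1 at every willingness-to-pay
  sums <- tapply(psa1$ceac$fraction, psa1$ceac$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(psa1$ceac$fraction >= 0 & psa1$ceac$fraction <= 1))
  # at zero willingness-to-pay the cheapest strategy wins every draw
  w0 <- psa1$ceac[psa1$ceac$wtp == 0, ]
  cheapest <- vapply(split(psa1$draws, psa1$draws$iter), function(d)
    d$strategy[which.min(d$cost)], character(1))
  top <- names(sort(table(cheapest), decreasing = TRUE))[1]
  expect_equal(w0$strategy[which.max(w0$fraction)], top)
  expect_equal(psa1$rejections, 0L)
})
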