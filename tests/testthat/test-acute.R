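# Independent oracle: closed-form path algebra for the 30-day tree, written
# separately from the package's leaf enumeration.
acute_oracle <- function(strategy, params) {
  v <- function(n) base_value(params, n)
  er <- v("cost_er_visit"); appy <- v("cost_laparoscopic_appendectomy")
  cstc <- v("cost_short_term_complication"); drain <- v("cost_percutaneous_drain")
  pm <- v("p_perioperative_mortality"); stc <- v("p_short_term_complication")
  mca <- v("p_mortality_complicated_appendectomy")
  u_ap <- v("u_laparoscopic_appendectomy")
  u_cp <- v("u_appendectomy_with_complication")
  u_iv <- v("u_interval_appendectomy"); u_fa <- v("u_failure_NOM")
  # expected payoff of the appendectomy-for-uncomplicated-failure subtree
  sub <- function(extra) list(
    cost = extra + appy + (1 - pm) * stc * cstc,
    dead = pm,
    qalm = (1 - pm) * (stc * u_cp + (1 - stc) * u_fa))
  comp <- function(extra) list(
    cost = extra + drain + appy, dead = mca, qalm = (1 - mca) * u_iv)
  mix <- function(ps, branches) {
    cost <- sum(mapply(function(w, b) w * b$cost, ps, branches))
    dead <- sum(mapply(function(w, b) w * b$dead, ps, branches))
    qalm <- sum(mapply(function(w, b) w * b$qalm, ps, branches))
    list(cost = cost, dead = dead, qalm = qalm)
  }
  if (strategy == "LAP_APPY") {
    base <- er + appy
    return(list(cost = base + (1 - pm) * stc * cstc, dead = pm,
                qalm = (1 - pm) * (stc * u_cp + (1 - stc) * u_ap),
                post_nom = 0))
  }
  if (strategy == "INPATIENT_NOM") {
    base <- er + v("cost_inpatient_NOM")
    fi <- v("p_failure_inpatient_NOM")
    cfi <- v("p_complicated_failure_inpatient_NOM")
    fo <- v("p_outpatient_failure_after_inpatient_NOM")
    cfo <- v("p_complicated_outpatient_failure_after_inpatient_NOM")
    succ <- (1 - fi) * (1 - fo)
    m <- mix(c(fi * cfi, fi * (1 - cfi), (1 - fi) * fo * cfo,
               (1 - fi) * fo * (1 - cfo)),
             list(comp(0), sub(0), comp(er), sub(er)))
    return(list(cost = base + m$cost, dead = m$dead,
                qalm = m$qalm + succ * v("u_successful_NOM"),
                post_nom = succ))
  }
  base <- er + v("cost_outpatient_NOM")
  f <- v("p_failure_outpatient_NOM")
  cf <- v("p_complicated_failure_outpatient_NOM")
  m <- mix(c(f * cf, f * (1 - cf)), list(comp(er), sub(er)))
  list(cost = base + m$cost, dead = m$dead,
       qalm = m$qalm + (1 - f) * v("u_successful_NOM"), post_nom = 1 - f)
}

test_that("tree evaluation matches the independent path-algebra oracle", {
  set.seed(401)
  for (i in 1:300) {
    p2 <- perturb_params(tp)
    for (s in strategies()) {
      got <- evaluate_acute(s, p2)
      want <- acute_oracle(s, p2)
      expect_equal(got$acute_cost, want$cost, tolerance = 1e-10)
      expect_equal(unname(got$entry_mass["DEAD"]), want$dead,
                   tolerance = 1e-12)
      expect_equal(unname(got$entry_mass["POST_NOM"]), want$post_nom,
                   tolerance = 1e-12)
      expect_equal(got$acute_qalm, want$qalm, tolerance = 1e-10)
      expect_equal(sum(got$entry_mass), 1, tolerance = 1e-12)
      expect_lte(got$acute_qalm, got$acute_ly)
    }
  }
})

test_that("degenerate trees collapse to their index costs", {
  p0 <- with_value(with_value(tp, "p_perioperative_mortality", 0),
                   "p_short_term_complication", 0)
  la <- evaluate_acute("LAP_APPY", p0)
  expect_equal(unname(la$entry_mass["POST_SURGERY"]), 1)
  expect_equal(la$acute_cost, 923 + 7606)
  p1 <- with_value(with_value(tp, "p_failure_inpatient_NOM", 0),
                   "p_outpatient_failure_after_inpatient_NOM", 0)
  inp <- evaluate_acute("INPATIENT_NOM", p1)
  expect_equal(unname(inp$entry_mass["POST_NOM"]), 1)
  expect_equal(inp$acute_cost, 923 + 7369)
  expect_equal(inp$acute_qalm, 0.93)
})

test_that("raising the outpatient failure rate raises cost, lowers QALMs", {
  grid <- seq(0.067, 0.21, length.out = 7)
  outs <- lapply(grid, function(f)
    evaluate_acute("OUTPATIENT_NOM",
                   with_value(tp, "p_failure_outpatient_NOM", f)))
  costs <- vapply(outs, `[[`, numeric(1), "acute_cost")
  qalms <- vapply(outs, `[[`, numeric(1), "acute_qalm")
  expect_true(all(diff(costs) >= 0))
  expect_true(all(diff(qalms) <= 0))
})

test_that("out-of-domain parameters are rejected before evaluation", {
  bad <- tp
  bad$specs$p_failure_outpatient_NOM$base <- 1.4
  expect_error(evaluate_acute("OUTPATIENT_NOM", bad), "domain")
  expect_error(evaluate_acute("OPEN_APPY", tp), "unknown strategy")
})
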