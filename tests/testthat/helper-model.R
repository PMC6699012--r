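# Shared fixtures: the packaged base case, loaded once per test run.
tp <- load_parameters()
td <- load_demographics()
tcfg <- model_config()

# A flat life table / background schedule for closed-form checks.
flat_life_table <- function(q, max_age = 110) {
  out <- data.frame(age = 0:max_age, q_annual = q)
  class(out) <- c("life_table", "data.frame")
  out
}
flat_background <- function(cost = 0, utility = 1) {
  out <- data.frame(age = 0:110, annual_cost = cost,
                    baseline_utility = utility)
  class(out) <- c("background_schedule", "data.frame")
  out
}
flat_demographics <- function(q = 0, cost = 0, utility = 1) {
  load_demographics(flat_life_table(q), flat_background(cost, utility))
}

# Random perturbation of the treatment-pathway probabilities, used to drive
# the tree-enumeration and property tests.
perturb_params <- function(params) {
  for (nm in c("p_short_term_complication", "p_perioperative_mortality",
               "p_failure_inpatient_NOM",
               "p_outpatient_failure_after_inpatient_NOM",
               "p_complicated_outpatient_failure_after_inpatient_NOM",
               "p_failure_outpatient_NOM",
               "p_complicated_failure_outpatient_NOM",
               "p_mortality_complicated_appendectomy")) {
    params <- with_value(params, nm, runif(1, 0, 0.4))
  }
  params
}
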