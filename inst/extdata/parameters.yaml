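# Model parameter registry: base-case values, plausible ranges and
# uncertainty distribution families for the appendicitis treatment model.
# Probabilities and utilities are dimensionless in [0,1]; costs are 2017 US$
# from the third-party-payer perspective (CMS fee schedule derived).
# family: beta | normal | log-normal | fixed. Parameters without a published
# plausible range (low = high = base) are held fixed in deterministic
# sensitivity analysis.
parameters:
  # -- probabilities -------------------------------------------------------
  # short-term perioperative complication after laparoscopic appendectomy
  # (ileus, SSI, anesthetic complication, postoperative hemorrhage)
  p_short_term_complication:
    {base: 0.072, low: 0.008, high: 0.198, family: beta, role: probability}
  # annual probability of a long-term postoperative complication
  # (trocar-site hernia, adhesive small bowel obstruction)
  p_long_term_complication_annual:
    {base: 0.005, low: 0.0014, high: 0.008, family: beta, role: probability}
  # perioperative mortality of laparoscopic appendectomy for
  # uncomplicated appendicitis
  p_perioperative_mortality:
    {base: 0.0005, low: 0.0005, high: 0.004, family: beta, role: probability}
  # mortality of the long-term postoperative complication event
  p_mortality_lt_complication:
    {base: 0.066, low: 0.023, high: 0.141, family: beta, role: probability}
  # failure of nonoperative management during the index inpatient
  # intravenous-antibiotic admission
  p_failure_inpatient_NOM:
    {base: 0.092, low: 0.058, high: 0.179, family: beta, role: probability}
  # fraction of inpatient NOM failures that are complicated (perforation
  # with abscess); no range published
  p_complicated_failure_inpatient_NOM:
    {base: 0.0, low: 0.0, high: 0.0, family: fixed, role: probability}
  # outpatient (post-discharge, <30 d) failure after inpatient NOM
  p_outpatient_failure_after_inpatient_NOM:
    {base: 0.142, low: 0.055, high: 0.228, family: beta, role: probability}
  # fraction of those outpatient failures that are complicated
  p_complicated_outpatient_failure_after_inpatient_NOM:
    {base: 0.01, low: 0.0, high: 0.061, family: beta, role: probability}
  # 30-day failure of outpatient oral-antibiotic NOM
  p_failure_outpatient_NOM:
    {base: 0.138, low: 0.067, high: 0.21, family: beta, role: probability}
  # fraction of outpatient-NOM failures that are complicated
  p_complicated_failure_outpatient_NOM:
    {base: 0.052, low: 0.02, high: 0.331, family: beta, role: probability}
  # fraction of late recurrences (>30 d) that are complicated
  p_complicated_recurrence:
    {base: 0.268, low: 0.0, high: 0.312, family: beta, role: probability}
  # mortality of appendectomy performed for complicated appendicitis
  p_mortality_complicated_appendectomy:
    {base: 0.00599, low: 0.0, high: 0.01, family: beta, role: probability}
  # probability that index appendicitis is the first presentation of an
  # unrecognized appendiceal malignancy
  p_appendiceal_malignancy:
    {base: 0.008, low: 0.0004, high: 0.036, family: beta, role: probability}
  # lifetime appendicitis risk in the general population; governs the
  # recurrence hazard beyond year 5 after successful NOM
  p_recurrence_tail_lifetime:
    {base: 0.086, low: 0.086, high: 0.086, family: fixed, role: probability}
  # -- costs (2017 US$) ----------------------------------------------------
  cost_laparoscopic_appendectomy:
    {base: 7606, low: 3803, high: 11409, family: normal, role: cost}
  # 3-day admission for IV piperacillin-tazobactam + 7-day oral completion
  cost_inpatient_NOM:
    {base: 7369, low: 3684.5, high: 11053.5, family: normal, role: cost}
  # 7 days of outpatient oral amoxicillin-clavulanate
  cost_outpatient_NOM:
    {base: 169, low: 84.5, high: 253.5, family: normal, role: cost}
  cost_percutaneous_drain:
    {base: 13323, low: 6661.5, high: 19984.5, family: normal, role: cost}
  cost_er_visit:
    {base: 923, low: 461.5, high: 1384.5, family: normal, role: cost}
  cost_short_term_complication:
    {base: 8431, low: 4215.5, high: 12646.5, family: normal, role: cost}
  cost_long_term_complication:
    {base: 11060, low: 5530, high: 16590, family: normal, role: cost}
  # right hemicolectomy for appendiceal malignancy
  cost_hemicolectomy:
    {base: 14362, low: 7181, high: 21542, family: normal, role: cost}
  # 12 cycles FOLFOX chemotherapy (stage III adenocarcinoma)
  cost_folfox_chemotherapy:
    {base: 38276, low: 19138, high: 57414, family: normal, role: cost}
  # -- utilities (quality-adjusted life-month weights for event months) ----
  u_laparoscopic_appendectomy:
    {base: 0.85, low: 0.63, high: 0.98, family: beta, role: utility}
  u_appendectomy_with_complication:
    {base: 0.76, low: 0.23, high: 0.99, family: beta, role: utility}
  u_postoperative_recovery:
    {base: 0.85, low: 0.63, high: 0.98, family: beta, role: utility}
  u_successful_NOM:
    {base: 0.93, low: 0.78, high: 0.99, family: beta, role: utility}
  u_failure_NOM:
    {base: 0.81, low: 0.76, high: 0.85, family: beta, role: utility}
  u_recurrent_appendicitis:
    {base: 0.72, low: 0.67, high: 0.76, family: beta, role: utility}
  u_interval_appendectomy:
    {base: 0.74, low: 0.71, high: 0.77, family: beta, role: utility}
  u_malignancy:
    {base: 0.78, low: 0.21, high: 0.99, family: beta, role: utility}
# Year-indexed schedules. `cumulative: true` series are cumulative incidence
# by end of year k; others are the fraction of survivors in remission at end
# of year k. low/high on the recurrence schedule bound its year-5 cumulative
# value in sensitivity analysis.
schedules:
  recurrence_after_NOM:
    years: [1, 2, 3, 4, 5]
    values: [0.273, 0.34, 0.352, 0.371, 0.391]
    cumulative: true
    tail_rule: lifetime_mass     # beyond year 5: general-population lifetime
                                 # appendicitis risk p_recurrence_tail_lifetime
    low: 0.044
    high: 0.391
  adeno_mortality:
    years: [1, 2, 3, 4, 5]
    values: [0.086, 0.13, 0.174, 0.218, 0.26]
    cumulative: true
    tail_rule: carry_last
  adeno_remission:
    years: [1, 2, 3, 4, 5]
    values: [0.90, 0.83, 0.75, 0.72, 0.69]
    cumulative: false
    tail_rule: carry_last
  carcinoid_mortality:
    years: [1, 2, 3, 4, 5]
    values: [0.033, 0.056, 0.079, 0.102, 0.126]
    cumulative: true
    tail_rule: carry_last
  carcinoid_remission:
    years: [1, 2, 3, 4, 5]
    values: [0.95, 0.92, 0.85, 0.75, 0.70]
    cumulative: false
    tail_rule: carry_last
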