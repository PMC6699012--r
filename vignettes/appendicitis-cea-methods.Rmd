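---
title: "Model and methods: lifetime cost-effectiveness of appendicitis treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: lifetime cost-effectiveness of appendicitis treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appendcea)
```

## The decision problem

`appendcea` models the lifetime costs and health outcomes of three
first-line treatments for acute, imaging-confirmed, uncomplicated
appendicitis in a healthy adult (reference case: a 20-year-old US male,
third-party-payer perspective, 2017 US$):

1. **Laparoscopic appendectomy** (`LAP_APPY`) — immediate surgery;
2. **Inpatient nonoperative management** (`INPATIENT_NOM`) — a 3-day
   admission for intravenous antibiotics followed by a 7-day oral course;
3. **Outpatient nonoperative management** (`OUTPATIENT_NOM`) — a 7-day oral
   antibiotic course only.

Nonoperative management (NOM) avoids perioperative risk and operative cost
but leaves the appendix in situ, so the patient retains a lifetime
potential for recurrent appendicitis, for complicated (perforated,
abscess-forming) recurrence, and for delayed presentation of an
unrecognized appendiceal tumor. Surgery trades those risks for
perioperative mortality, short-term complications, and a window of
long-term postoperative complications (trocar-site hernia, adhesive small
bowel obstruction). Because the decisive events play out over decades, the
model is a 30-day decision tree feeding a lifetime Markov cohort model with
a cycle length of one month.

## Acute phase (first 30 days)

The acute window is one model month. Each strategy's tree charges an
emergency-room evaluation at index presentation, the strategy's index
treatment cost, and resolves treatment failure:

* Inpatient failure (progression during the admission, probability 0.092)
  proceeds directly to appendectomy without a re-presentation charge.
* Outpatient failure (return of symptoms after discharge: probability
  0.138 for outpatient NOM, 0.142 after inpatient NOM) is charged a second
  ER visit. A complicated fraction (perforation with abscess) undergoes
  percutaneous drainage plus interval appendectomy with the
  complicated-appendicitis operative mortality (0.00599); the remainder
  undergoes direct appendectomy with the same perioperative mortality
  (0.0005) and short-term complication risk (0.072) as an index operation.

Transient quality-of-life weights from the parameter registry weight the
acute month (e.g. 0.85 for an uncomplicated appendectomy, 0.93 for
successful NOM, 0.81 for failed NOM); deaths in the window accrue no time.
Survivors enter the Markov model in `POST_SURGERY` (appendix removed) or
`POST_NOM` (appendix in situ). Tumors found incidentally at an index
appendectomy are assumed cured at no marginal cost, so the malignancy
parameter only burdens the NOM arms.

## Markov structure (monthly cycles to age 110)

All alive states accrue age-indexed background healthcare costs and an
age-declining baseline utility, and face age-indexed background mortality
(applied first in every transition). On top of that:

* **`POST_SURGERY`** — for the first 24 months after surgery, a monthly
  hazard of a long-term postoperative complication (annual probability
  0.005 converted to monthly), charged $11,060 per event, with 6.6% event
  mortality and the complication utility for the event month. The event
  does not interrupt the time-in-state clock.
* **`POST_NOM`** — a time-varying recurrence hazard derived from the
  cumulative 5-year recurrence schedule (27.3% by year 1 rising to 39.1%
  by year 5) as within-year constant monthly conditional probabilities;
  beyond year 5 the general-population lifetime appendicitis risk (8.6%)
  is spread as a constant monthly hazard over remaining life expectancy.
  A recurrence is complicated with probability 0.268 (drain + interval
  appendectomy, 0.00599 mortality, interval-appendectomy utility for the
  event month) and otherwise proceeds to direct appendectomy; survivors
  enter `POST_SURGERY` with a fresh complication window.
* **Appendiceal cancer** — in the NOM arms, the 0.8% lifetime probability
  of an unrecognized appendiceal malignancy presents as a constant monthly
  hazard over the 10 years after the index presentation, applied arm-wide
  (`POST_NOM` and post-recurrence `POST_SURGERY` alike): an appendectomy
  performed later for a recurrence does not restore the early-detection
  advantage that an index appendectomy provides. Presentations split 70%
  carcinoid (right hemicolectomy, $14,362) and 30% stage III
  adenocarcinoma (hemicolectomy + 12 cycles FOLFOX, $52,638). Monthly
  cancer mortality follows the year-indexed cumulative mortality series of
  each tumor type; after year 5 the final hazard persists for life. The
  decreasing year-indexed remission series is read as the fraction of
  survivors whose quality of life has returned to baseline; the remainder
  carry the malignancy utility (0.78). Year-5 survivors are split
  accordingly into `CANCER_REMISSION` and chronic disease.

Costs and life-years are discounted at 3% per year (monthly factors) and
state payoffs are half-cycle corrected in trapezoid form: each cycle
contributes the average of its boundary occupancies, which is equivalent to
half-weighting the first and last cycles. One-time event costs are charged
in full at the event cycle. Acute-phase accruals enter undiscounted at
time 0.

### Why this structure

Three aspects of the long-run event structure are not fully pinned down by
the published descriptions, and we fixed them by requiring the model to
reproduce the *pattern* of the published scenario table (the base-case,
no-cancer and no-failure scenario differences between strategies) rather
than any single number:

* a **24-month window** for long-term postoperative complications. A
  lifelong annual hazard of 0.005 implies ~0.28 complication events and
  ~0.019 excess deaths per operated patient, which would make surgery
  strictly dominated — the opposite of the published result. Clinically,
  adhesive and hernia complications cluster in the first two years after
  laparoscopic surgery; a 24-month window reproduces the published
  surgery-risk contribution (≈ −0.03 life-years).
* **arm-wide cancer exposure**. Restricting the malignancy hazard to the
  appendix-in-situ state would cut realized cancer incidence to ~0.5% and
  the cancer contribution to the strategy difference to a third of what
  the published scenario differences imply (≈ +0.073 life-years).
* **persistent cancer excess mortality with remission as a utility
  overlay**. Treating the remission series as a month-by-month exit
  hazard (90% in year 1) would make the cancer pathway nearly harmless,
  again irreconcilable with the published no-cancer scenario. Reading the
  mortality series as cohort-wide cumulative mortality and the remission
  series as quality-of-life recovery reproduces both the published
  life-year loss per case (~9-11 discounted years) and the near-absence
  of an extra utility penalty.

These are structural inferences, decided once and frozen; they are exactly
the kind of detail a re-implementation from a methods section cannot avoid
choosing.

## Demographics and calibration

The background inputs are synthetic, packaged fixtures (plain text under
`inst/extdata/`): an abridged US-male-style period life table (log-linear
hazard interpolation between pivot ages, absorbing at 110), an
age-increasing background annual healthcare cost, and an age-declining
baseline utility. Their *levels* were calibrated once with
`calibrate_background()` — two scalar multipliers solved exactly from the
model's affine dependence on them — so that the outpatient-NOM arm at age
20 reproduces its published lifetime discounted totals ($233,700 and
24.9270 QALYs); the calibrated values are committed and regression-tested,
and calibration never alters the age gradients. Undiscounted life
expectancy at age 20 is 57.5 years, in the plausible band for a US male
period table.

What the fixtures do *not* emulate: cohort heterogeneity (sex, region,
comorbidity), period-vs-cohort mortality improvement, and any correlation
between background cost and proximity to death. Tests that pass against
these fixtures validate the model mechanics and the published surface, not
forecasts for a particular real population.

## Parameters and uncertainty

Every model parameter lives in a YAML registry (`load_parameters()`) with
its base value, plausible range, distribution family and role;
`with_value()` gives non-destructive point edits, and completeness is
enforced loudly. For probabilistic sensitivity analysis (`sample_psa()`):

* probabilities and utilities: beta distributions, mean equal to the base
  value, standard deviation `(high - low)/(2 * 1.96)` by method of
  moments, shapes clamped at 0.5 mean-preservingly;
* costs: normal with the same range-derived spread, truncated at zero;
* the eight utilities are drawn independently and **rank-reordered** into
  the base-case preference order over health states, a simple and
  swappable construction of their joint (ordinal) uncertainty;
* schedules: one multiplicative factor per schedule (preserving
  monotonicity) — the recurrence schedule targeted so its year-5
  cumulative value follows a range-fitted beta, the cancer series
  log-normal with unit mean and σ = 0.2 (chosen once; no published
  range exists for them).

Parameters printed without a range are fixed in deterministic sensitivity
analysis.

## Sensitivity machinery

`one_way()` evaluates the full model across each parameter's range (costs:
50-150% of base); `find_threshold()` bisects a strategy-change predicate
(preference at the willingness-to-pay, or strict dominance) to a relative
bracket of 1e-4 — the preferred-strategy indicator is used rather than
ICER continuity because dominance changes discontinuously in the ICER but
monotonically in net-benefit differences. `two_way()` maps the preferred
strategy over a grid of 30-day failure against 5-year recurrence (the
recurrence axis scales the whole schedule proportionally). `run_psa()`
re-runs the three-strategy model per draw (iteration *i* uses seed
`seed + i`, making runs bit-reproducible) and assembles
cost-effectiveness acceptability curves from the net-monetary-benefit
argmax; invalid draws would be rejected, logged and replaced (none occur
with the packaged registry).

## Validation oracle

`simulate_patients()` is an individual-level Monte Carlo simulation of the
identical event structure with the identical discounting and half-cycle
conventions, so its estimators are unbiased for the cohort engine's
expectations. The defining test runs 200,000 patients per strategy and
requires agreement within 3 Monte Carlo standard errors on cost, QALYs and
life-years; standard errors are also checked to shrink as 1/sqrt(n). The
simulator doubles as a generator of synthetic patient-level datasets
(`export_patients()`).

## Numerical choices

* Cycle propagation runs in compiled code; probability mass is checked for
  conservation (1e-9) every cycle and death occupancy must be monotone.
* Monthly conversions use constant-hazard forms `1 - (1 - p)^(1/12)`;
  year-indexed cumulative series convert via conditional survival ratios.
* Dominance ties break toward the lower-cost strategy; extended dominance
  removes frontier members whose segment ICER is not increasing; a
  boundary tie at the willingness-to-pay keeps the cheaper strategy.
* ICERs are reported at full precision alongside a nearest-$100 rounding
  that mirrors the usual presentation.
* Problem sizes used in the shipped tests: 1,080 monthly cycles (age 20 to
  110), 200,000 microsimulation patients for the oracle comparison, 10,000
  PSA iterations, 1,000 random instances for the frontier/net-benefit
  equivalence property.

## Known limitations

* The model reproduces the published base-case anchors and the inpatient
  arm almost exactly, but the published *incremental* quantities —
  differences of order 0.03% between quarter-million-dollar lifetime
  totals — are only partially recoverable from the printed parameter
  tables: our laparoscopic-appendectomy arm carries roughly $700 more
  lifetime cost relative to outpatient NOM than the published table
  (ICER ≈ $44,000/QALY vs the published $32,300/QALY), and
  threshold/scenario quantities that are ratios of these small differences
  inherit that disagreement. The package reports its own computed values
  rather than forcing agreement.
* Perioperative mortality applies to every appendectomy, including those
  performed for NOM failure and recurrence; as a consequence outpatient
  NOM cannot strictly dominate surgery within the tabulated mortality
  range (the crossing sits near 0.5%), since raising the parameter harms
  both arms.
* No negative-appendectomy pathway, no open-conversion pathway, no repeat
  NOM after failure, and no patient-level covariate effects — matching the
  modeled clinical assumptions.
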