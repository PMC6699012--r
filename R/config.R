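#' Run configuration for the decision model
#'
#' @param start_age Cohort starting age in years (reference case: a healthy
#'   20-year-old male presenting with imaging-confirmed uncomplicated
#'   appendicitis).
#' @param discount_rate Annual discount rate applied to future costs,
#'   life-years and QALYs.
#' @param wtp Willingness-to-pay threshold in US$ per QALY gained.
#' @param age_cap Age at which the lifetime horizon is truncated; the life
#'   table is absorbing there.
#' @return A list of class `model_config`.
#' @export
model_config <- function(start_age = 20, discount_rate = 0.03,
                         wtp = 50000, age_cap = 110) {
  stopifnot(discount_rate >= 0, wtp >= 0, age_cap > start_age)
  structure(list(start_age = start_age, discount_rate = discount_rate,
                 wtp = wtp, age_cap = age_cap),
            class = "model_config")
}

#' The three management strategies
#'
#' @return Character vector: `LAP_APPY` (laparoscopic appendectomy),
#'   `INPATIENT_NOM` (3-day IV antibiotic admission + 7-day oral course),
#'   `OUTPATIENT_NOM` (7-day oral antibiotics only).
#' @export
strategies <- function() c("LAP_APPY", "INPATIENT_NOM", "OUTPATIENT_NOM")
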