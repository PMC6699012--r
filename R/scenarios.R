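# Scenario analyses: declarative parameter overrides and structural flags
# re-running the full three-strategy model.

.known_flags <- c("no_cancer_after_NOM", "no_failure_or_recurrence",
                  "all_recurrences_uncomplicated")

#' Define a scenario
#'
#' @param name Scenario identifier.
#' @param start_age Cohort starting age (years); age scenarios re-anchor
#'   the life table and background schedules while all treatment
#'   parameters stay at base.
#' @param overrides Named list of parameter values to override.
#' @param flags Character vector of structural flags:
#'   `no_cancer_after_NOM` zeroes the post-NOM cancer-presentation hazard
#'   (masses assumed seen on initial imaging and treated operatively;
#'   surgical arm unaffected); `no_failure_or_recurrence` zeroes all
#'   nonoperative failure probabilities and the recurrence hazard;
#'   `all_recurrences_uncomplicated` zeroes the complicated fractions of
#'   every failure/recurrence pathway so all events route through direct
#'   appendectomy.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, start_age = 20, overrides = list(),
                          flags = character()) {
  bad <- setdiff(flags, .known_flags)
  if (length(bad)) stop("unknown scenario flag(s): ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, start_age = start_age,
                 overrides = overrides, flags = flags),
            class = "scenario_spec")
}

#' Run a scenario end-to-end
#'
#' Applies the overrides and structural flags, runs all three strategies,
#' and returns the incremental analysis.
#'
#' @param spec A `scenario_spec`.
#' @param params A `parameter_set`.
#' @param demographics A `demographics` bundle.
#' @param config A `model_config`; its `start_age` is replaced by the
#'   scenario's.
#' @return A `cea_table` with attribute `scenario`.
#' @export
run_scenario <- function(spec, params, demographics,
                         config = model_config()) {
  stopifnot(inherits(spec, "scenario_spec"))
  p2 <- params
  for (nm in names(spec$overrides)) {
    p2 <- with_value(p2, nm, spec$overrides[[nm]])
  }
  engine_flags <- intersect(spec$flags,
                            c("no_cancer_after_NOM",
                              "no_failure_or_recurrence"))
  if ("no_failure_or_recurrence" %in% spec$flags) {
    for (nm in c("p_failure_inpatient_NOM",
                 "p_outpatient_failure_after_inpatient_NOM",
                 "p_failure_outpatient_NOM")) {
      p2 <- with_value(p2, nm, 0)
    }
  }
  if ("all_recurrences_uncomplicated" %in% spec$flags) {
    for (nm in c("p_complicated_recurrence",
                 "p_complicated_failure_outpatient_NOM",
                 "p_complicated_outpatient_failure_after_inpatient_NOM",
                 "p_complicated_failure_inpatient_NOM")) {
      p2 <- with_value(p2, nm, 0)
    }
  }
  cfg <- config
  cfg$start_age <- spec$start_age
  res <- run_model(p2, demographics, cfg, flags = engine_flags)
  tab <- incremental_analysis(res, cfg$wtp)
  attr(tab, "scenario") <- spec$name
  tab
}

#' The packaged scenario suite
#'
#' Base case at age 20 plus the five scenario analyses: older starting ages
#' (40, 65), no appendiceal cancer after nonoperative management, no
#' nonoperative failure or recurrence, and all failures/recurrences
#' uncomplicated.
#'
#' @return Named list of `scenario_spec` objects.
#' @export
packaged_scenarios <- function() {
  list(
    base_age20 = scenario_spec("base_age20", start_age = 20),
    base_age40 = scenario_spec("base_age40", start_age = 40),
    base_age65 = scenario_spec("base_age65", start_age = 65),
    no_cancer_after_NOM = scenario_spec(
      "no_cancer_after_NOM", flags = "no_cancer_after_NOM"),
    no_failure_or_recurrence = scenario_spec(
      "no_failure_or_recurrence", flags = "no_failure_or_recurrence"),
    all_recurrences_uncomplicated = scenario_spec(
      "all_recurrences_uncomplicated",
      flags = "all_recurrences_uncomplicated")
  )
}

#' Run every packaged scenario
#'
#' @inheritParams run_scenario
#' @return Named list of `cea_table` objects.
#' @export
run_all_scenarios <- function(params, demographics,
                              config = model_config()) {
  lapply(packaged_scenarios(), run_scenario, params = params,
         demographics = demographics, config = config)
}
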