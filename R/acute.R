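# First-30-day decision tree. The acute window is treated as exactly one
# model month: transient utility weights from the parameter registry weight
# that month, and survivors enter the Markov model in POST_SURGERY (appendix
# removed) or POST_NOM (appendix in situ). An emergency-room visit is
# charged once at index presentation for every strategy and once more at
# each outpatient failure re-presentation; inpatient failures progress
# during the index admission and are not re-charged. Appendectomy performed
# for an uncomplicated failure carries the same perioperative mortality and
# short-term complication risks as an index appendectomy; complicated
# failures undergo percutaneous drainage plus interval appendectomy with the
# complicated-appendicitis operative mortality. Malignancies discovered
# incidentally at index appendectomy are cured at no marginal cost, so the
# malignancy probability only affects the nonoperative arms (delayed,
# advanced-stage presentation, handled in the Markov model). Background
# mortality is not additionally applied inside the acute window.

#' Enumerate the acute decision-tree leaves for a strategy
#'
#' Exhaustive path enumeration: each row is one leaf with its path
#' probability, accumulated cost, utility weight for the acute month (0 for
#' deaths), Markov entry state, and whether the path involved a treatment
#' failure.
#'
#' @param strategy One of [strategies()].
#' @param params A `parameter_set`.
#' @return A data frame with columns `prob`, `cost`, `util`, `state`,
#'   `failure`.
#' @export
acute_leaves <- function(strategy, params) {
  p <- function(n) base_value(params, n)
  er <- p("cost_er_visit"); appy <- p("cost_laparoscopic_appendectomy")
  stc_cost <- p("cost_short_term_complication")
  drain <- p("cost_percutaneous_drain")
  p_pm <- p("p_perioperative_mortality")
  p_stc <- p("p_short_term_complication")
  p_mca <- p("p_mortality_complicated_appendectomy")
  u_appy <- p("u_laparoscopic_appendectomy")
  u_comp <- p("u_appendectomy_with_complication")
  u_int <- p("u_interval_appendectomy")

  leaf <- function(prob, cost, util, state, failure = FALSE) {
    data.frame(prob = prob, cost = cost, util = util, state = state,
               failure = failure)
  }
  # appendectomy for an uncomplicated NOM failure; event-month utility
  # u_base, short-term complications replace it with the complication weight
  appy_subtree <- function(prob, cost0, u_base, failure = TRUE) {
    rbind(
      leaf(prob * p_pm, cost0 + appy, 0, "DEAD", failure),
      leaf(prob * (1 - p_pm) * p_stc, cost0 + appy + stc_cost, u_comp,
           "POST_SURGERY", failure),
      leaf(prob * (1 - p_pm) * (1 - p_stc), cost0 + appy, u_base,
           "POST_SURGERY", failure)
    )
  }
  # percutaneous drain + interval appendectomy for a complicated failure
  complicated_subtree <- function(prob, cost0, failure = TRUE) {
    rbind(
      leaf(prob * p_mca, cost0 + drain + appy, 0, "DEAD", failure),
      leaf(prob * (1 - p_mca), cost0 + drain + appy, u_int,
           "POST_SURGERY", failure)
    )
  }

  leaves <- switch(strategy,
    LAP_APPY = {
      cost0 <- er + appy
      rbind(
        leaf(p_pm, cost0, 0, "DEAD"),
        leaf((1 - p_pm) * p_stc, cost0 + stc_cost, u_comp, "POST_SURGERY"),
        leaf((1 - p_pm) * (1 - p_stc), cost0, u_appy, "POST_SURGERY")
      )
    },
    INPATIENT_NOM = {
      cost0 <- er + p("cost_inpatient_NOM")
      p_fi <- p("p_failure_inpatient_NOM")
      p_cfi <- p("p_complicated_failure_inpatient_NOM")
      p_fo <- p("p_outpatient_failure_after_inpatient_NOM")
      p_cfo <- p("p_complicated_outpatient_failure_after_inpatient_NOM")
      rbind(
        # failure during the index admission (no re-presentation charge)
        complicated_subtree(p_fi * p_cfi, cost0),
        appy_subtree(p_fi * (1 - p_cfi), cost0, p("u_failure_NOM")),
        # outpatient failure after discharge: second ER visit
        complicated_subtree((1 - p_fi) * p_fo * p_cfo, cost0 + er),
        appy_subtree((1 - p_fi) * p_fo * (1 - p_cfo), cost0 + er,
                     p("u_failure_NOM")),
        leaf((1 - p_fi) * (1 - p_fo), cost0, p("u_successful_NOM"),
             "POST_NOM")
      )
    },
    OUTPATIENT_NOM = {
      cost0 <- er + p("cost_outpatient_NOM")
      p_f <- p("p_failure_outpatient_NOM")
      p_cf <- p("p_complicated_failure_outpatient_NOM")
      rbind(
        complicated_subtree(p_f * p_cf, cost0 + er),
        appy_subtree(p_f * (1 - p_cf), cost0 + er, p("u_failure_NOM")),
        leaf(1 - p_f, cost0, p("u_successful_NOM"), "POST_NOM")
      )
    },
    stop("unknown strategy '", strategy, "'")
  )
  rownames(leaves) <- NULL
  leaves
}

#' Evaluate the acute decision tree
#'
#' Aggregates the leaf enumeration into the distribution over Markov entry
#' states plus expected cost and quality-adjusted time accrued in the acute
#' 30-day window (one model month; deaths in the window accrue no time).
#'
#' @param strategy One of [strategies()].
#' @param params A `parameter_set`.
#' @return An object of class `acute_outcome` with fields `entry_mass`
#'   (named probabilities over POST_SURGERY, POST_NOM, DEAD), `acute_cost`
#'   (US$), `acute_qalm` and `acute_ly` (months).
#' @export
evaluate_acute <- function(strategy, params) {
  for (nm in names(params$specs)) {
    s <- params$specs[[nm]]
    dom <- .legal_domain(s$role)
    if (s$base < dom[1] || s$base > dom[2]) {
      stop("parameter '", nm, "' outside its legal domain")
    }
  }
  lv <- acute_leaves(strategy, params)
  entry <- c(POST_SURGERY = sum(lv$prob[lv$state == "POST_SURGERY"]),
             POST_NOM = sum(lv$prob[lv$state == "POST_NOM"]),
             DEAD = sum(lv$prob[lv$state == "DEAD"]))
  stopifnot(abs(sum(entry) - 1) < 1e-12)
  alive <- lv$state != "DEAD"
  structure(list(
    strategy = strategy,
    entry_mass = entry,
    acute_cost = sum(lv$prob * lv$cost),
    acute_qalm = sum(lv$prob * lv$util * alive),
    acute_ly = sum(lv$prob * alive)
  ), class = "acute_outcome")
}

#' @export
print.acute_outcome <- function(x, ...) {
  cat("<acute_outcome> ", x$strategy, "\n", sep = "")
  cat("  entry:", paste(sprintf("%s=%.5f", names(x$entry_mass),
                                x$entry_mass), collapse = " "), "\n")
  cat(sprintf("  acute cost $%.2f, QALM %.4f, LY %.4f months\n",
              x$acute_cost, x$acute_qalm, x$acute_ly))
  invisible(x)
}
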