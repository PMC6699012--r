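#' @useDynLib appendcea, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbeta rnorm runif setNames uniroot
#' @importFrom utils read.delim write.table
"_PACKAGE"

# Required registry inventory: 13 probability rows + the lifetime-risk tail,
# 9 cost rows, 8 utility rows, the 5-year recurrence schedule and the four
# cancer schedules.
.required_parameters <- c(
  "p_short_term_complication", "p_long_term_complication_annual",
  "p_perioperative_mortality", "p_mortality_lt_complication",
  "p_failure_inpatient_NOM", "p_complicated_failure_inpatient_NOM",
  "p_outpatient_failure_after_inpatient_NOM",
  "p_complicated_outpatient_failure_after_inpatient_NOM",
  "p_failure_outpatient_NOM", "p_complicated_failure_outpatient_NOM",
  "p_complicated_recurrence", "p_mortality_complicated_appendectomy",
  "p_appendiceal_malignancy", "p_recurrence_tail_lifetime",
  "cost_laparoscopic_appendectomy", "cost_inpatient_NOM",
  "cost_outpatient_NOM", "cost_percutaneous_drain", "cost_er_visit",
  "cost_short_term_complication", "cost_long_term_complication",
  "cost_hemicolectomy", "cost_folfox_chemotherapy",
  "u_laparoscopic_appendectomy", "u_appendectomy_with_complication",
  "u_postoperative_recovery", "u_successful_NOM", "u_failure_NOM",
  "u_recurrent_appendicitis", "u_interval_appendectomy", "u_malignancy"
)

.required_schedules <- c(
  "recurrence_after_NOM", "adeno_mortality", "adeno_remission",
  "carcinoid_mortality", "carcinoid_remission"
)

.utility_names <- c(
  "u_laparoscopic_appendectomy", "u_appendectomy_with_complication",
  "u_postoperative_recovery", "u_successful_NOM", "u_failure_NOM",
  "u_recurrent_appendicitis", "u_interval_appendectomy", "u_malignancy"
)

#' Path to the packaged base-case parameter registry
#'
#' @return Path of the YAML file holding every model parameter's base value,
#'   plausible range and uncertainty distribution family.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "parameters.yaml", package = "appendcea",
              mustWork = TRUE)
}

#' Load the model parameter set
#'
#' Reads a flat YAML registry of parameter specifications (base value,
#' plausible range `low`/`high`, distribution `family`, `role`) and
#' year-indexed schedules (cumulative recurrence after nonoperative
#' management, appendiceal-cancer mortality and remission series), validates
#' it, and returns a `parameter_set`.
#'
#' Validation is strict: a missing required parameter or schedule is an
#' error naming the missing key; a base value outside its legal domain
#' (probabilities and utilities in \[0,1\], costs nonnegative) or outside
#' its printed `low`/`high` range is an error; cumulative schedules must be
#' non-decreasing with strictly increasing year indices.
#'
#' @param source Path to a YAML parameter file. Defaults to the packaged
#'   base-case registry.
#' @return An object of class `parameter_set`: a list with elements `specs`
#'   (named list of parameter specifications) and `schedules` (named list of
#'   schedules).
#' @export
load_parameters <- function(source = default_parameter_file()) {
  raw <- yaml::read_yaml(source)
  if (is.null(raw$parameters) || is.null(raw$schedules)) {
    stop("parameter file must contain 'parameters' and 'schedules' sections")
  }
  specs <- lapply(names(raw$parameters), function(nm) {
    x <- raw$parameters[[nm]]
    for (f in c("base", "low", "high", "family", "role")) {
      if (is.null(x[[f]])) stop("parameter '", nm, "' is missing field '", f, "'")
    }
    spec <- list(name = nm, base = as.numeric(x$base), low = as.numeric(x$low),
                 high = as.numeric(x$high), family = x$family, role = x$role)
    class(spec) <- "parameter_spec"
    spec
  })
  names(specs) <- names(raw$parameters)

  schedules <- lapply(names(raw$schedules), function(nm) {
    x <- raw$schedules[[nm]]
    sch <- list(name = nm, years = as.integer(x$years),
                values = as.numeric(x$values),
                cumulative = isTRUE(x$cumulative),
                tail_rule = x$tail_rule,
                low = if (is.null(x$low)) NA_real_ else as.numeric(x$low),
                high = if (is.null(x$high)) NA_real_ else as.numeric(x$high))
    class(sch) <- "schedule"
    sch
  })
  names(schedules) <- names(raw$schedules)

  params <- structure(list(specs = specs, schedules = schedules),
                      class = "parameter_set")
  validate_parameters(params)
  params
}

#' Validate a parameter set against its invariants
#'
#' @param params A `parameter_set`.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  missing <- setdiff(.required_parameters, names(params$specs))
  if (length(missing)) {
    stop("parameter set is missing required parameter(s): ",
         paste(missing, collapse = ", "))
  }
  missing_s <- setdiff(.required_schedules, names(params$schedules))
  if (length(missing_s)) {
    stop("parameter set is missing required schedule(s): ",
         paste(missing_s, collapse = ", "))
  }
  for (spec in params$specs) {
    dom <- .legal_domain(spec$role)
    if (spec$base < dom[1] || spec$base > dom[2]) {
      stop("base value of '", spec$name, "' (", spec$base,
           ") outside its legal domain [", dom[1], ", ", dom[2], "]")
    }
    if (spec$low > spec$base || spec$base > spec$high) {
      stop("parameter '", spec$name, "' violates low <= base <= high")
    }
    if (!spec$family %in% c("beta", "normal", "log-normal", "fixed")) {
      stop("parameter '", spec$name, "' has unsupported family '",
           spec$family, "'")
    }
  }
  for (sch in params$schedules) {
    if (length(sch$years) != length(sch$values)) {
      stop("schedule '", sch$name, "' has mismatched years/values lengths")
    }
    if (any(diff(sch$years) <= 0)) {
      stop("schedule '", sch$name, "' must have strictly increasing years")
    }
    if (any(sch$values < 0 | sch$values > 1)) {
      stop("schedule '", sch$name, "' has values outside [0,1]")
    }
    if (sch$cumulative && any(diff(sch$values) < 0)) {
      stop("cumulative schedule '", sch$name, "' must be non-decreasing")
    }
  }
  invisible(params)
}

.legal_domain <- function(role) {
  switch(role,
         probability = c(0, 1),
         utility = c(0, 1),
         cost = c(0, Inf),
         schedule = c(0, 1),
         stop("unknown parameter role '", role, "'"))
}

#' Base value of a parameter
#'
#' @param params A `parameter_set`.
#' @param name Parameter name.
#' @return The parameter's current base value.
#' @export
base_value <- function(params, name) {
  spec <- params$specs[[name]]
  if (is.null(spec)) stop("unknown parameter '", name, "'")
  spec$base
}

#' Return a copy of a parameter set with one value replaced
#'
#' The replacement must lie in the parameter's legal domain (probability or
#' utility in \[0,1\], cost nonnegative) but may lie outside its printed
#' plausible range, which is what threshold and scenario analyses need.
#' The input set is not modified.
#'
#' @param params A `parameter_set`.
#' @param name Parameter name to change.
#' @param value New base value.
#' @return A new `parameter_set` differing from `params` only in `name`.
#' @export
with_value <- function(params, name, value) {
  spec <- params$specs[[name]]
  if (is.null(spec)) stop("unknown parameter '", name, "'")
  dom <- .legal_domain(spec$role)
  if (!is.finite(value) || value < dom[1] || value > dom[2]) {
    stop("value ", value, " for '", name, "' outside legal domain [",
         dom[1], ", ", dom[2], "]")
  }
  out <- params
  out$specs[[name]]$base <- value
  # keep the stored range consistent with the invariant low <= base <= high
  out$specs[[name]]$low <- min(spec$low, value)
  out$specs[[name]]$high <- max(spec$high, value)
  out
}

#' Scale a year-indexed schedule by a multiplicative factor
#'
#' Used by two-way sensitivity analysis and the PSA: the whole 5-year series
#' is scaled proportionally (values capped just below 1), so a cumulative
#' schedule stays cumulative.
#'
#' @param params A `parameter_set`.
#' @param name Schedule name.
#' @param factor Positive multiplicative factor.
#' @return A new `parameter_set` with the scaled schedule.
#' @export
with_schedule_scaled <- function(params, name, factor) {
  sch <- params$schedules[[name]]
  if (is.null(sch)) stop("unknown schedule '", name, "'")
  if (!is.finite(factor) || factor < 0) stop("factor must be nonnegative")
  out <- params
  out$schedules[[name]]$values <- pmin(sch$values * factor, 0.999)
  out
}

# Method-of-moments beta fit with mean preserved under shape clamping.
.fit_beta <- function(mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1) return(NULL)
  v <- mean * (1 - mean) / sd^2 - 1
  if (v <= 0) v <- 1e-6
  alpha <- mean * v
  beta <- (1 - mean) * v
  if (alpha < 0.5) { alpha <- 0.5; beta <- alpha * (1 - mean) / mean }
  if (beta < 0.5) { beta <- 0.5; alpha <- beta * mean / (1 - mean) }
  c(alpha = alpha, beta = beta)
}

.range_sd <- function(spec) (spec$high - spec$low) / (2 * 1.96)

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Probabilities and utilities are drawn from beta distributions whose mean
#' equals the base value and whose standard deviation is fitted from the
#' plausible range as (high - low) / (2 * 1.96) by the method of moments
#' (shape parameters clamped at 0.5, mean-preserving). Costs are drawn from
#' normal distributions with the same range-derived spread, truncated at 0.
#' The eight health-state utilities are drawn independently and then
#' rank-reordered so that every draw respects the base-case preference
#' ordering over health states (joint distribution via ordinal correlation).
#' Year-indexed schedules are scaled by a single multiplicative factor each:
#' the recurrence schedule so that its year-5 cumulative value follows a
#' range-fitted beta, the cancer series log-normally with unit mean.
#' Parameters with a degenerate range are treated as fixed.
#'
#' @param params A `parameter_set` (base case).
#' @param seed Integer seed; the same seed reproduces the identical draw.
#' @return A new `parameter_set` with sampled base values.
#' @export
sample_psa <- function(params, seed) {
  set.seed(seed)
  out <- params
  for (nm in names(params$specs)) {
    spec <- params$specs[[nm]]
    if (spec$family == "fixed" || spec$high <= spec$low) next
    sd <- .range_sd(spec)
    if (spec$family == "beta") {
      ab <- .fit_beta(spec$base, sd)
      if (is.null(ab)) next
      out$specs[[nm]]$base <- rbeta(1, ab["alpha"], ab["beta"])
    } else if (spec$family == "normal") {
      x <- rnorm(1, spec$base, sd)
      tries <- 0
      while (x < 0 && tries < 100) { x <- rnorm(1, spec$base, sd); tries <- tries + 1 }
      out$specs[[nm]]$base <- max(x, 0)
    } else if (spec$family == "log-normal") {
      sdlog <- sqrt(log(1 + (sd / spec$base)^2))
      out$specs[[nm]]$base <- stats::rlnorm(1, log(spec$base) - sdlog^2 / 2, sdlog)
    }
  }
  # rank reassignment: sorted draws take the base-case preference order
  base_order <- .utility_names[order(vapply(.utility_names, function(n)
    params$specs[[n]]$base, numeric(1)), decreasing = TRUE)]
  draws <- vapply(.utility_names, function(n) out$specs[[n]]$base, numeric(1))
  sorted <- sort(draws, decreasing = TRUE)
  for (i in seq_along(base_order)) out$specs[[base_order[i]]]$base <- sorted[i]

  # schedules: one multiplicative factor per schedule preserves monotonicity
  rec <- params$schedules$recurrence_after_NOM
  if (!is.na(rec$low) && rec$high > rec$low) {
    y5 <- rec$values[length(rec$values)]
    ab <- .fit_beta(y5, (rec$high - rec$low) / (2 * 1.96))
    if (!is.null(ab)) {
      target <- rbeta(1, ab["alpha"], ab["beta"])
      out <- with_schedule_scaled(out, "recurrence_after_NOM", target / y5)
    }
  }
  sdlog <- 0.2
  for (nm in c("adeno_mortality", "adeno_remission",
               "carcinoid_mortality", "carcinoid_remission")) {
    f <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    out <- with_schedule_scaled(out, nm, f)
  }
  # clamp any utility/probability pushed out of [0,1) by sampling noise
  for (nm in names(out$specs)) {
    role <- out$specs[[nm]]$role
    if (role %in% c("probability", "utility")) {
      out$specs[[nm]]$base <- min(max(out$specs[[nm]]$base, 0), 1)
    }
    out$specs[[nm]]$low <- min(out$specs[[nm]]$low, out$specs[[nm]]$base)
    out$specs[[nm]]$high <- max(out$specs[[nm]]$high, out$specs[[nm]]$base)
  }
  out
}

#' Serialize a parameter set back to YAML
#'
#' `load_parameters(write_parameters(p, f))` reproduces `p` exactly.
#'
#' @param params A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  plist <- lapply(params$specs, function(s)
    list(base = s$base, low = s$low, high = s$high,
         family = s$family, role = s$role))
  slist <- lapply(params$schedules, function(s) {
    x <- list(years = s$years, values = s$values,
              cumulative = s$cumulative, tail_rule = s$tail_rule)
    if (!is.na(s$low)) { x$low <- s$low; x$high <- s$high }
    x
  })
  yaml::write_yaml(list(parameters = plist, schedules = slist), path)
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>: ", length(x$specs), " parameters, ",
      length(x$schedules), " schedules\n", sep = "")
  roles <- vapply(x$specs, `[[`, character(1), "role")
  cat("  probabilities:", sum(roles == "probability"),
      " costs:", sum(roles == "cost"),
      " utilities:", sum(roles == "utility"), "\n")
  invisible(x)
}

#' Parameter registry as a data frame
#'
#' @param x A `parameter_set`.
#' @param ... Unused.
#' @return A data frame with one row per scalar parameter.
#' @export
as.data.frame.parameter_set <- function(x, ...) {
  data.frame(
    name = names(x$specs),
    base = vapply(x$specs, `[[`, numeric(1), "base"),
    low = vapply(x$specs, `[[`, numeric(1), "low"),
    high = vapply(x$specs, `[[`, numeric(1), "high"),
    family = vapply(x$specs, `[[`, character(1), "family"),
    role = vapply(x$specs, `[[`, character(1), "role"),
    row.names = NULL
  )
}
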