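# Deterministic and probabilistic sensitivity analysis: one-way grids with
# threshold search by bisection, two-way preferred-strategy region maps, and
# Monte Carlo probabilistic sensitivity analysis with cost-effectiveness
# acceptability curves.

# Set a scalar parameter, or - for a schedule name - scale the whole series
# proportionally so its final-year cumulative value equals `value`.
.set_param <- function(params, name, value) {
  if (name %in% names(params$schedules)) {
    v <- params$schedules[[name]]$values
    with_schedule_scaled(params, name, value / v[length(v)])
  } else {
    with_value(params, name, value)
  }
}

.param_range <- function(params, name) {
  if (name %in% names(params$schedules)) {
    s <- params$schedules[[name]]
    if (is.na(s$low)) return(NULL)
    return(c(s$low, s$high))
  }
  spec <- params$specs[[name]]
  if (is.null(spec)) stop("unknown parameter '", name, "'")
  if (spec$family == "fixed" || spec$high <= spec$low) return(NULL)
  if (spec$role == "cost") return(c(0.5, 1.5) * spec$base)  # 50%-150% of base
  c(spec$low, spec$high)
}

#' One-way deterministic sensitivity analysis
#'
#' Evaluates the full three-strategy model over a grid spanning the
#' parameter's plausible range (costs: 50% to 150% of the base value), all
#' other parameters held at base, and records the preferred strategy at the
#' configured willingness-to-pay. Grid points where the preferred strategy
#' changes bracket decision thresholds; refine them with [find_threshold()].
#'
#' @inheritParams run_strategy
#' @param name Parameter (or schedule) name; a schedule is varied through
#'   its final-year cumulative value with proportional scaling.
#' @param n_points Number of grid points.
#' @return An object of class `owsa_result`: data frame with columns
#'   `value`, per-strategy `cost_*`/`qaly_*`, `preferred`; attribute
#'   `thresholds` gives the bracketing midpoints of preferred-strategy
#'   changes (empty for a fixed parameter, with a note).
#' @export
one_way <- function(params, demographics, config = model_config(),
                    name, n_points = 11) {
  rng <- .param_range(params, name)
  if (is.null(rng)) {
    out <- data.frame(value = numeric(0), preferred = character(0))
    return(structure(out, class = c("owsa_result", "data.frame"),
                     parameter = name, thresholds = numeric(0),
                     note = "fixed parameter: no plausible range to vary"))
  }
  grid <- if (n_points == 1) mean(rng) else
    seq(rng[1], rng[2], length.out = n_points)
  rows <- lapply(grid, function(v) {
    res <- run_model(.set_param(params, name, v), demographics, config)
    tab <- incremental_analysis(res, config$wtp)
    wide <- setNames(c(res$cost, res$qaly),
                     c(paste0("cost_", res$strategy),
                       paste0("qaly_", res$strategy)))
    cbind(data.frame(value = v), as.data.frame(as.list(wide)),
          data.frame(preferred = preferred_strategy(tab)))
  })
  df <- do.call(rbind, rows)
  chg <- which(df$preferred[-1] != df$preferred[-nrow(df)])
  thresholds <- (df$value[chg] + df$value[chg + 1]) / 2
  structure(df, class = c("owsa_result", "data.frame"),
            parameter = name, thresholds = thresholds, note = NULL)
}

#' Built-in threshold predicates
#'
#' `pred_preferred(s)` is true when strategy `s` is preferred at the
#' configured willingness-to-pay (frontier analysis); `pred_dominates(a, b)`
#' is true when strategy `a` strictly dominates `b` (costs no more, at
#' least as effective).
#'
#' @param s,a,b Strategy names.
#' @return A predicate `function(results_df, config)` for [find_threshold()].
#' @export
pred_preferred <- function(s) {
  function(results, config) {
    preferred_strategy(incremental_analysis(results, config$wtp)) == s
  }
}

#' @rdname pred_preferred
#' @export
pred_dominates <- function(a, b) {
  function(results, config) {
    ra <- results[results$strategy == a, ]
    rb <- results[results$strategy == b, ]
    ra$cost <= rb$cost && ra$qaly >= rb$qaly &&
      (ra$cost < rb$cost || ra$qaly > rb$qaly)
  }
}

#' Find a decision threshold by bisection
#'
#' Bisects the parameter value between `bounds` on a strategy-change
#' predicate until the bracket shrinks below a relative tolerance of 1e-4.
#' If the predicate does not differ at the two bounds, a no-threshold result
#' (`NA` with attribute `note`) is returned rather than an error.
#'
#' @inheritParams one_way
#' @param bounds Numeric length-2 search interval.
#' @param predicate A `function(results_df, config)` returning `TRUE`/
#'   `FALSE`, e.g. [pred_preferred()] or [pred_dominates()].
#' @param tol Relative bracket tolerance.
#' @return The crossing value (numeric), or `NA` if no sign change.
#' @export
find_threshold <- function(params, demographics, config = model_config(),
                           name, bounds, predicate, tol = 1e-4) {
  eval_at <- function(v) {
    predicate(run_model(.set_param(params, name, v), demographics, config),
              config)
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- eval_at(lo); f_hi <- eval_at(hi)
  if (f_lo == f_hi) {
    return(structure(NA_real_, note = "predicate constant across bounds"))
  }
  while ((hi - lo) > tol * max(abs(hi), abs(lo), 1e-12)) {
    mid <- (lo + hi) / 2
    if (eval_at(mid) == f_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Two-way sensitivity analysis (preferred-strategy region map)
#'
#' Varies two parameters jointly over grids and records the preferred
#' strategy in each cell. A schedule axis (e.g. 5-year recurrence after
#' nonoperative management) is scaled proportionally so its final-year
#' cumulative value equals the grid value.
#'
#' @inheritParams one_way
#' @param x,y Parameter or schedule names.
#' @param x_grid,y_grid Numeric grids.
#' @return An object of class `twsa_grid`: data frame with columns `x`,
#'   `y`, `preferred`; attributes `x_parameter`, `y_parameter`.
#' @export
two_way <- function(params, demographics, config = model_config(),
                    x, y, x_grid, y_grid) {
  cells <- expand.grid(x = x_grid, y = y_grid, KEEP.OUT.ATTRS = FALSE)
  cells$preferred <- vapply(seq_len(nrow(cells)), function(i) {
    p2 <- .set_param(.set_param(params, x, cells$x[i]), y, cells$y[i])
    preferred_strategy(incremental_analysis(
      run_model(p2, demographics, config), config$wtp))
  }, character(1))
  structure(cells, class = c("twsa_grid", "data.frame"),
            x_parameter = x, y_parameter = y)
}

#' Probabilistic sensitivity analysis with acceptability curves
#'
#' Draws `n` parameter sets with [sample_psa()] (iteration `i` uses seed
#' `seed + i`, so a fixed `seed` reproduces the full run bit for bit), runs
#' the full three-strategy model per draw, and assembles the
#' cost-effectiveness acceptability curve: at each willingness-to-pay value
#' the fraction of iterations in which each strategy maximizes net monetary
#' benefit. Draws that violate model invariants (non-finite outputs or
#' QALY > LY) are rejected, logged and replaced; the rejection count must
#' stay below 1% of `n`.
#'
#' @inheritParams run_strategy
#' @param n Number of Monte Carlo iterations (>= 1).
#' @param seed Integer base seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return An object of class `psa_result`: `draws` (data frame with
#'   `iter`, `strategy`, `cost`, `qaly`), `ceac` (data frame with `wtp`,
#'   `strategy`, `fraction`), `n`, `seed`, `rejections`.
#' @export
run_psa <- function(params, demographics, config = model_config(),
                    n = 10000, seed = 1,
                    wtp_grid = seq(0, 150000, by = 10000)) {
  stopifnot(n >= 1)
  strat <- strategies()
  costs <- matrix(NA_real_, n, length(strat), dimnames = list(NULL, strat))
  qalys <- costs
  rejections <- 0L
  spare <- 0L
  for (i in seq_len(n)) {
    repeat {
      draw_seed <- if (spare == 0L) seed + i else seed + n + spare
      ps <- sample_psa(params, draw_seed)
      res <- run_model(ps, demographics, config)
      ok <- all(is.finite(res$cost), is.finite(res$qaly),
                res$qaly <= res$ly + 1e-9, res$cost >= 0)
      if (ok) break
      rejections <- rejections + 1L
      spare <- spare + 1L
    }
    costs[i, res$strategy] <- res$cost
    qalys[i, res$strategy] <- res$qaly
  }
  if (rejections >= 0.01 * n) {
    warning("PSA rejected ", rejections, " draws (>= 1% of n)")
  }
  nmb_pref <- function(wtp) {
    nmb <- wtp * qalys - costs
    best <- max.col(nmb, ties.method = "first")
    factor(strat[best], levels = strat)
  }
  ceac <- do.call(rbind, lapply(wtp_grid, function(w) {
    tab <- table(nmb_pref(w)) / n
    data.frame(wtp = w, strategy = names(tab),
               fraction = as.numeric(tab), row.names = NULL)
  }))
  draws <- data.frame(
    iter = rep(seq_len(n), times = length(strat)),
    strategy = rep(strat, each = n),
    cost = as.vector(costs), qaly = as.vector(qalys))
  structure(list(draws = draws, ceac = ceac, n = n, seed = seed,
                 rejections = rejections),
            class = "psa_result")
}

#' Fraction of PSA iterations preferring a strategy at one threshold
#'
#' @param psa A `psa_result`.
#' @param strategy Strategy name.
#' @param wtp Willingness-to-pay.
#' @return Fraction in \[0,1\].
#' @export
psa_acceptability <- function(psa, strategy, wtp) {
  costs <- matrix(psa$draws$cost, psa$n)
  qalys <- matrix(psa$draws$qaly, psa$n)
  colnames(costs) <- colnames(qalys) <- unique(psa$draws$strategy)
  nmb <- wtp * qalys - costs
  best <- max.col(nmb, ties.method = "first")
  mean(colnames(nmb)[best] == strategy)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> n =", x$n, "seed =", x$seed,
      "rejections =", x$rejections, "\n")
  w50 <- x$ceac[x$ceac$wtp == 50000, ]
  if (nrow(w50)) {
    cat("  acceptability at $50,000/QALY:\n")
    for (i in seq_len(nrow(w50))) {
      cat(sprintf("    %s: %.3f\n", w50$strategy[i], w50$fraction[i]))
    }
  }
  invisible(x)
}
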