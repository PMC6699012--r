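# Incremental cost-effectiveness analysis: dominance, extended dominance,
# ICERs along the efficient frontier, net monetary benefit, and
# preferred-strategy selection at a willingness-to-pay threshold.

#' Incremental cost-effectiveness analysis
#'
#' Strategies are sorted by cost; strictly dominated strategies (another
#' strategy costs no more and yields at least as many QALYs, with ties
#' broken toward lower cost) and extendedly dominated strategies (ICER
#' exceeding that of a more effective alternative) are flagged and excluded
#' from the frontier. ICERs are incremental cost divided by incremental
#' QALYs between adjacent frontier members. The preferred strategy is the
#' most effective frontier member whose ICER does not exceed `wtp`; an
#' exact tie at the threshold resolves toward the less costly strategy.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly` (and
#'   optionally `ly`), e.g. from [run_model()], or a list of
#'   `strategy_result` objects.
#' @param wtp Willingness-to-pay threshold, US$ per QALY.
#' @return An object of class `cea_table`: the input rows (cost order)
#'   with columns `dominated`, `ext_dominated`, `icer`, `icer_rounded`
#'   (nearest $100), `comparator`, and attributes `preferred` and `wtp`.
#' @export
incremental_analysis <- function(results, wtp = 50000) {
  df <- .as_results_df(results)
  if (nrow(df) < 2) stop("need at least two strategies")
  df <- df[order(df$cost, -df$qaly), ]
  df$dominated <- FALSE
  df$ext_dominated <- FALSE
  df$icer <- NA_real_
  df$comparator <- NA_character_

  # strict dominance (cost tie resolves against the later, costlier row)
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      better <- (df$cost[j] < df$cost[i] && df$qaly[j] >= df$qaly[i]) ||
        (df$cost[j] == df$cost[i] && df$qaly[j] > df$qaly[i]) ||
        (df$cost[j] == df$cost[i] && df$qaly[j] == df$qaly[i] && j < i)
      if (better) { df$dominated[i] <- TRUE; break }
    }
  }
  # extended dominance on the survivors: drop members whose segment ICER
  # is not strictly increasing
  repeat {
    idx <- which(!df$dominated & !df$ext_dominated)
    if (length(idx) < 3) break
    icers <- diff(df$cost[idx]) / diff(df$qaly[idx])
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    df$ext_dominated[idx[bad[1] + 1]] <- TRUE
  }
  frontier <- which(!df$dominated & !df$ext_dominated)
  if (length(frontier) > 1) {
    for (k in 2:length(frontier)) {
      i <- frontier[k]; j <- frontier[k - 1]
      dq <- df$qaly[i] - df$qaly[j]
      df$icer[i] <- if (dq > 0) (df$cost[i] - df$cost[j]) / dq else Inf
      df$comparator[i] <- df$strategy[j]
    }
  }
  df$icer_rounded <- round(df$icer / 100) * 100

  # walk up the frontier while the segment ICER stays below the threshold;
  # an exact boundary tie keeps the less costly strategy
  pref <- df$strategy[frontier[1]]
  if (length(frontier) > 1) {
    for (k in 2:length(frontier)) {
      if (df$icer[frontier[k]] < wtp) pref <- df$strategy[frontier[k]]
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("cea_table", "data.frame"),
            preferred = pref, wtp = wtp)
}

.as_results_df <- function(results) {
  if (is.data.frame(results)) return(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(strategy = r$strategy, cost = r$cost, qaly = r$qaly,
               ly = if (is.null(r$ly)) NA_real_ else r$ly)))
}

#' Preferred strategy of a CEA table
#'
#' @param tab A `cea_table`.
#' @return Strategy name.
#' @export
preferred_strategy <- function(tab) attr(tab, "preferred")

#' Net monetary benefit
#'
#' NMB = wtp x QALYs - cost. The NMB-maximizing strategy coincides with the
#' frontier-based preferred strategy at the same willingness-to-pay.
#'
#' @param result A `strategy_result`, or a data frame of results.
#' @param wtp Willingness-to-pay, US$ per QALY (nonnegative).
#' @return Numeric NMB in US$ (vector for a data frame input).
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(wtp >= 0)
  if (is.data.frame(result)) return(wtp * result$qaly - result$cost)
  wtp * result$qaly - result$cost
}

# NMB-argmax with cost tie-break; used by the PSA and as the CEA oracle's
# counterpart in tests.
.nmb_preferred <- function(df, wtp) {
  nmb <- wtp * df$qaly - df$cost
  best <- which(nmb == max(nmb))
  if (length(best) > 1) best <- best[which.min(df$cost[best])]
  df$strategy[best]
}

#' @export
print.cea_table <- function(x, ...) {
  cat("Incremental cost-effectiveness analysis (WTP $",
      format(attr(x, "wtp"), big.mark = ","), "/QALY)\n", sep = "")
  show <- data.frame(
    strategy = x$strategy,
    cost = round(x$cost),
    qaly = round(x$qaly, 4),
    status = ifelse(x$dominated, "dominated",
                    ifelse(x$ext_dominated, "ext. dominated", "frontier")),
    icer = ifelse(is.na(x$icer), "-",
                  format(x$icer_rounded, big.mark = ","))
  )
  print(show, row.names = FALSE)
  cat("Preferred:", attr(x, "preferred"), "\n")
  invisible(x)
}

#' Export a CEA table with incremental columns
#'
#' Mirrors the usual total/incremental presentation: per-strategy totals
#' plus increments against the least costly (referent) strategy.
#'
#' @param tab A `cea_table`.
#' @param path Optional path for a tab-separated export.
#' @return Data frame.
#' @export
export_cea_table <- function(tab, path = NULL) {
  ref <- 1
  df <- data.frame(
    strategy = tab$strategy,
    cost = tab$cost,
    incr_cost = tab$cost - tab$cost[ref],
    ly = tab$ly,
    incr_ly = tab$ly - tab$ly[ref],
    qaly = tab$qaly,
    incr_qaly = tab$qaly - tab$qaly[ref],
    icer = tab$icer,
    status = ifelse(tab$dominated, "dominated",
                    ifelse(tab$ext_dominated, "ext_dominated", "frontier"))
  )
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  df
}
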