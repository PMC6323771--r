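# Discounted accumulation, ICER/dominance frontier, net monetary benefit,
# and the imatinib price threshold solver.

#' Accumulate lifetime costs, life years and QALYs over a cohort trace
#'
#' Rewards are attributed to the state occupied at cycle start (no
#' half-cycle correction): cycle t (0-based) contributes occupancy-weighted
#' state costs, alive mass / 12 life years, and occupancy-weighted
#' utility / 12 QALYs, each multiplied by the discount factor
#' `(1 + rate)^(-t/12)`. Undiscounted twins use factor 1.
#'
#' @param trace Occupancy matrix (cycles 0..H in rows; the last row is the
#'   end-of-horizon state and accrues nothing).
#' @param rewards A `state_rewards` whose states match the trace columns.
#' @param annual_rate Annual discount rate (default 3%).
#' @param option_id Strategy label carried into the result.
#' @return Object of class `econ_result`: one-row data frame with
#'   `option_id`, `cost_undisc`, `cost_disc`, `ly_undisc`, `ly_disc`,
#'   `qaly_undisc`, `qaly_disc`.
#' @export
accumulate <- function(trace, rewards, annual_rate = 0.03,
                       option_id = attr(trace, "option_id") %||% NA_character_) {
  if (annual_rate < 0) stop("accumulate(): annual_rate must be >= 0")
  states <- colnames(trace)
  if (is.null(states) || !setequal(states, rewards$state)) {
    stop("accumulate(): trace columns and rewards states do not match")
  }
  cost_vec <- stats::setNames(rewards$cost, rewards$state)[states]
  util_vec <- stats::setNames(rewards$utility, rewards$state)[states]
  alive_vec <- as.numeric(states != "Dead")

  H <- nrow(trace) - 1
  occ <- unclass(trace)[seq_len(H), , drop = FALSE]
  t0 <- 0:(H - 1)
  df <- (1 + annual_rate)^(-t0 / 12)

  cost_cycle <- as.numeric(occ %*% cost_vec)
  ly_cycle <- as.numeric(occ %*% alive_vec) / 12
  qaly_cycle <- as.numeric(occ %*% util_vec) / 12

  structure(data.frame(
    option_id = option_id,
    cost_undisc = sum(cost_cycle), cost_disc = sum(cost_cycle * df),
    ly_undisc = sum(ly_cycle), ly_disc = sum(ly_cycle * df),
    qaly_undisc = sum(qaly_cycle), qaly_disc = sum(qaly_cycle * df),
    stringsAsFactors = FALSE
  ), class = c("econ_result", "data.frame"))
}

#' Run one strategy end to end
#'
#' Convenience wrapper: cohort trace, state rewards, accumulation.
#'
#' @inheritParams run_cohort
#' @param imatinib_price_override Optional THB per 400 mg tablet (see
#'   [state_rewards()]).
#' @param annual_rate Annual discount rate; defaults to the parameter
#'   scalar.
#' @return An `econ_result` row.
#' @export
run_strategy <- function(strategy, params, life_table,
                         horizon = params$scalars$horizon_cycles,
                         imatinib_price_override = NULL,
                         annual_rate = params$scalars$annual_discount_rate) {
  if (!inherits(strategy, "gist_strategy")) strategy <- make_strategy(strategy)
  trace <- run_cohort(strategy, params, life_table, horizon)
  rew <- state_rewards(strategy, params, imatinib_price_override)
  accumulate(trace, rew, annual_rate, option_id = strategy$option_id)
}

#' Deterministic base case over a set of strategies
#'
#' @param params A `gist_params`.
#' @param life_table A `life_table`.
#' @param options Option ids (default all six).
#' @param ... Passed to [run_strategy()].
#' @return Data frame with one `econ_result` row per option.
#' @export
run_base_case <- function(params, life_table,
                          options = c("1", "4", "2.1", "2.2", "3.1", "3.2"),
                          ...) {
  do.call(rbind, lapply(options, function(id) {
    run_strategy(id, params, life_table, ...)
  }))
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' @param lower,higher `econ_result` rows; `higher` is the more effective
#'   (or at least different-QALY) strategy.
#' @return `(cost_disc[higher] - cost_disc[lower]) / (qaly_disc[higher] -
#'   qaly_disc[lower])` in THB per QALY. `NA` with a warning when the QALY
#'   difference is zero (undefined ICER); negative values indicate
#'   dominance (check the frontier labelling instead).
#' @export
icer <- function(lower, higher) {
  dq <- higher$qaly_disc - lower$qaly_disc
  dc <- higher$cost_disc - lower$cost_disc
  if (dq == 0) {
    warning("undefined ICER: zero discounted QALY difference")
    return(NA_real_)
  }
  dc / dq
}

#' Efficiency frontier with strict and extended dominance
#'
#' Sorts strategies by discounted cost, marks strict dominance (costlier
#' and no more effective than some other strategy), then iteratively
#' removes extended dominance until the ICER sequence along the frontier is
#' strictly increasing. Ties are broken toward inclusion.
#'
#' @param results Data frame of `econ_result` rows (>= 2 strategies).
#' @return Data frame sorted by discounted cost with columns of `results`
#'   plus `label` (`on_frontier`, `strictly_dominated`,
#'   `extendedly_dominated`) and `icer` (vs the previous frontier member;
#'   `NA` for the cheapest member and for dominated strategies).
#' @export
efficiency_frontier <- function(results) {
  if (nrow(results) < 2) stop("efficiency_frontier(): need at least 2 strategies")
  res <- results[order(results$cost_disc, results$qaly_disc), , drop = FALSE]
  n <- nrow(res)
  label <- rep("on_frontier", n)

  for (i in seq_len(n)) {
    dominated <- any(res$cost_disc < res$cost_disc[i] & res$qaly_disc >= res$qaly_disc[i]) ||
      any(res$cost_disc == res$cost_disc[i] & res$qaly_disc > res$qaly_disc[i])
    if (dominated) label[i] <- "strictly_dominated"
  }

  repeat {
    idx <- which(label == "on_frontier")
    if (length(idx) < 3) break
    ic <- diff(res$cost_disc[idx]) / diff(res$qaly_disc[idx])
    # an interior member whose incoming ICER is >= the outgoing one is
    # extendedly dominated; remove the worst offender and recompute
    bad <- which(ic[-1] < ic[-length(ic)])
    if (!length(bad)) break
    label[idx[bad[1] + 1]] <- "extendedly_dominated"
  }

  icers <- rep(NA_real_, n)
  idx <- which(label == "on_frontier")
  if (length(idx) > 1) {
    icers[idx[-1]] <- diff(res$cost_disc[idx]) / diff(res$qaly_disc[idx])
  }
  res$label <- label
  res$icer <- icers
  res
}

#' Net monetary benefit
#'
#' @param result An `econ_result` row (or data frame of rows).
#' @param wtp Willingness-to-pay threshold in THB per QALY (>= 0).
#' @return `wtp * qaly_disc - cost_disc`, in THB.
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) stop("nmb(): wtp must be >= 0")
  wtp * result$qaly_disc - result$cost_disc
}

#' Imatinib price at which a strategy becomes cost-effective
#'
#' Bisection on the imatinib price per 400 mg tablet — rescaling the drug
#' cost of every imatinib-dispensing state, adjuvant and recurrence lines
#' alike, in both strategies — until the deterministic ICER of `strategy`
#' versus `comparator` equals the willingness-to-pay threshold. The cohort
#' traces do not depend on price, so they are computed once and only the
#' reward accumulation is repeated.
#'
#' @param params A `gist_params`.
#' @param life_table A `life_table`.
#' @param strategy,comparator Option ids (defaults: 3-year adjuvant option
#'   "2.2" vs current practice "1").
#' @param wtp Target ICER in THB per QALY.
#' @param price_bounds Bracket for the price in THB per tablet; the ICER
#'   must straddle `wtp` across it.
#' @param tol Relative ICER tolerance (default 1e-6).
#' @param max_iter Bisection iteration cap.
#' @return List with `price` (THB per 400 mg), `icer` (achieved), and
#'   `iterations`.
#' @export
threshold_price <- function(params, life_table, strategy = "2.2",
                            comparator = "1", wtp = params$scalars$wtp,
                            price_bounds = c(1, param_value(params, "imatinib_tablet_price")),
                            tol = 1e-6, max_iter = 200) {
  if (any(price_bounds <= 0)) stop("threshold_price(): price bounds must be positive")
  s_hi <- make_strategy(strategy)
  s_lo <- make_strategy(comparator)
  rate <- params$scalars$annual_discount_rate
  tr_hi <- run_cohort(s_hi, params, life_table)
  tr_lo <- run_cohort(s_lo, params, life_table)
  icer_at <- function(price) {
    icer(accumulate(tr_lo, state_rewards(s_lo, params, price), rate),
         accumulate(tr_hi, state_rewards(s_hi, params, price), rate))
  }
  lo <- min(price_bounds); hi <- max(price_bounds)
  f_lo <- icer_at(lo); f_hi <- icer_at(hi)
  if (!(f_lo <= wtp && f_hi >= wtp)) {
    stop(sprintf(paste0("threshold_price(): no bracket: ICER at %.2f THB is %.0f, ",
                        "at %.2f THB is %.0f, target %.0f"),
                 lo, f_lo, hi, f_hi, wtp))
  }
  iter <- 0
  repeat {
    iter <- iter + 1
    mid <- (lo + hi) / 2
    f_mid <- icer_at(mid)
    if (abs(f_mid - wtp) / wtp < tol || iter >= max_iter) {
      return(list(price = mid, icer = f_mid, iterations = iter))
    }
    if (f_mid > wtp) hi <- mid else lo <- mid
  }
}

#' Export a base-case results table as CSV
#'
#' Mirrors the headline results table: option, lifetime cost, life years
#' and QALYs (undiscounted and discounted), and the frontier ICER or
#' dominance label.
#'
#' @param frontier Output of [efficiency_frontier()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_results_table <- function(frontier, path) {
  utils::write.csv(frontier, path, row.names = FALSE)
  invisible(path)
}
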