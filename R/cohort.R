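# The Markov cohort engine: per-cycle transition matrices over the eight
# health states, cohort trace propagation, and per-state monthly rewards.

#' Monthly drug acquisition cost from a unit price
#'
#' Audit helper: unit price x units per day x days per month, truncated to
#' whole THB. With the 2014 reference price of 3,659.40 THB per 400 mg
#' tablet and 365/12 days per month this reproduces the imatinib monthly
#' cost of 111,306 THB. The sunitinib monthly cost used in the model
#' (82,173 THB) additionally embeds the 4-weeks-on / 2-weeks-off schedule
#' and is carried as an input rather than recomputed.
#'
#' @param unit_price THB per unit (tablet/capsule).
#' @param units_per_day Units dispensed per day.
#' @param days_per_month Days per month (default 365/12).
#' @return Monthly cost in whole THB.
#' @export
monthly_drug_cost <- function(unit_price, units_per_day, days_per_month = 365 / 12) {
  if (any(unit_price <= 0) || any(units_per_day <= 0) || any(days_per_month <= 0)) {
    stop("monthly_drug_cost(): all inputs must be positive")
  }
  trunc(unit_price * units_per_day * days_per_month)
}

#' Combine cause-specific and background mortality
#'
#' Independent competing risks within a cycle:
#' `1 - (1 - p_cause) * (1 - p_background)`. Symmetric and never below
#' either input.
#'
#' @param p_cause,p_background Monthly probabilities in `[0, 1]`.
#' @return Combined monthly death probability.
#' @export
combine_mortality <- function(p_cause, p_background) {
  if (any(p_cause < 0 | p_cause > 1) || any(p_background < 0 | p_background > 1)) {
    stop("combine_mortality(): probabilities must be in [0, 1]")
  }
  1 - (1 - p_cause) * (1 - p_background)
}

#' Per-state monthly cost and utility rewards
#'
#' Monthly state costs sum drug acquisition (imatinib 111,306 THB in any
#' imatinib-dispensing state, sunitinib 82,173 THB), monitoring/care costs,
#' adverse-event treatment (on adjuvant only), and direct non-medical costs
#' (travel + food + caregiver per visit, times the state's visit rate).
#' Utilities are the annual quality-of-life weights of each state. The dead
#' state has zero cost and utility.
#'
#' @param strategy A `gist_strategy` (rewards are pathway-independent, but
#'   the signature mirrors the rest of the model surface).
#' @param params A `gist_params`.
#' @param imatinib_price_override Optional THB per 400 mg tablet; rescales
#'   every imatinib drug cost (adjuvant and recurrence lines alike)
#'   proportionally from the reference price. Used by the price threshold
#'   analysis.
#' @return Object of class `state_rewards`: data frame with columns
#'   `state`, `cost`, `utility`.
#' @export
state_rewards <- function(strategy, params, imatinib_price_override = NULL) {
  pv <- function(nm) param_value(params, nm)
  visit_cost <- pv("cost_travel_visit") + pv("cost_food_visit") + pv("cost_caregiver_visit")
  imatinib_month <- pv("cost_drug_imatinib_month")
  if (!is.null(imatinib_price_override)) {
    if (imatinib_price_override <= 0) stop("imatinib price override must be > 0")
    imatinib_month <- imatinib_month * imatinib_price_override / pv("imatinib_tablet_price")
  }
  norec_off <- pv("cost_norec_noadj") + pv("visits_norec_noadj") * visit_cost
  cost <- c(
    NoRec_NoAdj = norec_off,
    NoRec_OnAdj = imatinib_month + pv("cost_norec_adj") + pv("cost_ae_adjuvant") +
      pv("visits_norec_adj") * visit_cost,
    NoRec_Completed = norec_off,
    NoRec_Discontinued = norec_off,
    Rec_Imatinib = imatinib_month + pv("cost_rec_imatinib") + pv("visits_rec") * visit_cost,
    Rec_Sunitinib = pv("cost_drug_sunitinib_month") + pv("cost_rec_sunitinib") +
      pv("visits_rec") * visit_cost,
    Rec_BSC = pv("cost_rec_bsc") + pv("visits_rec") * visit_cost,
    Dead = 0
  )
  utility <- c(
    NoRec_NoAdj = pv("u_norec_noadj"),
    NoRec_OnAdj = pv("u_norec_adj"),
    NoRec_Completed = pv("u_norec_noadj"),
    NoRec_Discontinued = pv("u_norec_noadj"),
    Rec_Imatinib = pv("u_rec_imatinib"),
    Rec_Sunitinib = pv("u_rec_sunitinib"),
    Rec_BSC = pv("u_rec_bsc"),
    Dead = 0
  )
  structure(data.frame(state = gist_states(),
                       cost = unname(cost[gist_states()]),
                       utility = unname(utility[gist_states()])),
            class = c("state_rewards", "data.frame"))
}

# per-cycle scalar inputs driving the transition matrix; vectorised over
# cycles so the cohort run can reuse matrices across cycles with identical
# inputs
.cycle_inputs <- function(strategy, params, life_table, cycles) {
  sc <- params$scalars
  bg <- if (isTRUE(sc$include_background_mortality)) {
    monthly_background_prob(life_table, sc$start_age + (cycles - 1) / 12)
  } else {
    rep(0, length(cycles))
  }
  data.frame(
    cycle = cycles,
    p_rec_on = schedule_prob(build_recurrence_schedule(params, strategy, TRUE), cycles),
    p_rec_off = schedule_prob(baseline_recurrence_schedule(params), cycles),
    p_gd = schedule_prob(gist_death_schedule(params), cycles),
    p_disc = schedule_prob(discontinuation_schedule(params, strategy$adjuvant_months), cycles),
    bg = bg,
    complete = cycles == strategy$adjuvant_months & strategy$adjuvant_months > 0
  )
}

# fill one row: named exits, remainder stays in `stay`; drawn PSA inputs
# can push competing exits past 1, in which case they are renormalised
# proportionally (with a warning)
.fill_row <- function(M, from, exits, stay) {
  s <- sum(exits)
  if (s > 1) {
    warning("competing exit probabilities from ", from, " sum to ",
            format(s, digits = 6), "; renormalising proportionally",
            call. = FALSE)
    exits <- exits / s
    s <- 1
  }
  M[from, names(exits)] <- M[from, names(exits)] + exits
  M[from, stay] <- M[from, stay] + (1 - s)
  M
}

.build_matrix <- function(strategy, params, inp) {
  S <- gist_states()
  M <- matrix(0, 8, 8, dimnames = list(S, S))
  pv <- function(nm) param_value(params, nm)
  after_target <- .rec_state_for(strategy$after_sequence[1])
  during_target <- if (is.null(strategy$during_sequence)) after_target
                   else .rec_state_for(strategy$during_sequence[1])
  d_norec <- combine_mortality(inp$p_gd, inp$bg)

  M <- .fill_row(M, "NoRec_NoAdj",
                 c(Dead = d_norec, stats::setNames(inp$p_rec_off, after_target)),
                 "NoRec_NoAdj")
  onadj_stay <- if (inp$complete) "NoRec_Completed" else "NoRec_OnAdj"
  M <- .fill_row(M, "NoRec_OnAdj",
                 c(Dead = d_norec,
                   stats::setNames(inp$p_rec_on, during_target),
                   NoRec_Discontinued = inp$p_disc),
                 onadj_stay)
  M <- .fill_row(M, "NoRec_Completed",
                 c(Dead = d_norec, stats::setNames(inp$p_rec_off, after_target)),
                 "NoRec_Completed")
  # discontinued patients are imatinib-intolerant: on recurrence they follow
  # the during-adjuvant sequence, at baseline (no-adjuvant) recurrence risk
  M <- .fill_row(M, "NoRec_Discontinued",
                 c(Dead = d_norec, stats::setNames(inp$p_rec_off, during_target)),
                 "NoRec_Discontinued")

  seq_after <- strategy$after_sequence
  next_after_imatinib <- seq_after[match("Imatinib", seq_after) + 1]
  M <- .fill_row(M, "Rec_Imatinib",
                 c(Dead = combine_mortality(pv("p_death_imatinib"), inp$bg),
                   stats::setNames(pv("p_prog_imatinib"),
                                   .rec_state_for(next_after_imatinib))),
                 "Rec_Imatinib")
  M <- .fill_row(M, "Rec_Sunitinib",
                 c(Dead = combine_mortality(pv("p_death_sunitinib"), inp$bg),
                   Rec_BSC = pv("p_prog_sunitinib")),
                 "Rec_Sunitinib")
  M <- .fill_row(M, "Rec_BSC",
                 c(Dead = combine_mortality(pv("p_death_bsc"), inp$bg)),
                 "Rec_BSC")
  M["Dead", "Dead"] <- 1
  M
}

#' Transition matrix for one cycle
#'
#' Row-stochastic 8x8 matrix over [gist_states()] governing the transition
#' into the given cycle. No-recurrence exits are recurrence (hazard-ratio
#' adjusted while on adjuvant therapy), adjuvant discontinuation (banded),
#' and death (banded GIST-specific mortality combined with age-specific
#' background mortality); at the last adjuvant cycle the remaining
#' on-adjuvant mass moves to the completed state. Recurrence-state exits
#' are progression to the next treatment line in the strategy's sequence
#' and death at the line-specific rate.
#'
#' @param strategy A `gist_strategy`.
#' @param params A `gist_params`.
#' @param life_table A `life_table`.
#' @param cycle Cycle number (>= 1).
#' @return 8x8 row-stochastic matrix.
#' @export
transition_matrix <- function(strategy, params, life_table, cycle) {
  stopifnot(inherits(strategy, "gist_strategy"), cycle >= 1)
  inp <- .cycle_inputs(strategy, params, life_table, cycle)
  .build_matrix(strategy, params, as.list(inp[1, ]))
}

#' Propagate a cohort through a sequence of transition matrices
#'
#' Low-level engine shared by the full model and the miniature test
#' fixtures: row t+1 of the trace is row t times the t-th matrix.
#'
#' @param mats A single matrix (applied every cycle), a list of matrices
#'   (one per cycle), or a function `function(cycle)` returning one.
#' @param init Named initial occupancy vector (cycle 0), summing to 1.
#' @param n_cycles Number of cycles if `mats` is a single matrix or a
#'   function; ignored for a list.
#' @return Occupancy matrix with `n_cycles + 1` rows (cycle 0 first) and
#'   one column per state.
#' @export
propagate_cohort <- function(mats, init, n_cycles = NULL) {
  if (is.matrix(mats)) {
    stopifnot(!is.null(n_cycles))
    mats <- rep(list(mats), n_cycles)
  } else if (is.function(mats)) {
    stopifnot(!is.null(n_cycles))
    mats <- lapply(seq_len(n_cycles), mats)
  }
  H <- length(mats)
  S <- names(init)
  trace <- matrix(0, H + 1, length(init), dimnames = list(0:H, S))
  trace[1, ] <- init
  for (t in seq_len(H)) {
    trace[t + 1, ] <- trace[t, , drop = TRUE] %*% mats[[t]]
  }
  trace
}

#' Run the cohort model for one strategy
#'
#' Starts the whole cohort at age `start_age` in the strategy's
#' no-recurrence entry state and propagates it over monthly cycles to the
#' horizon. Transition matrices are piecewise constant in cycle (bands and
#' integer age), so each distinct matrix is built once.
#'
#' @param strategy A `gist_strategy` or an option id accepted by
#'   [make_strategy()].
#' @param params A `gist_params`.
#' @param life_table A `life_table`.
#' @param horizon Number of monthly cycles (default from the parameter
#'   scalars; 480 = 40 years, to age 100).
#' @return Object of class `cohort_trace`: occupancy matrix (cycles 0..H by
#'   the eight states) with attributes `start_age` and `option_id`.
#' @export
run_cohort <- function(strategy, params, life_table,
                       horizon = params$scalars$horizon_cycles) {
  if (!inherits(strategy, "gist_strategy")) strategy <- make_strategy(strategy)
  stopifnot(horizon >= 1)
  inputs <- .cycle_inputs(strategy, params, life_table, seq_len(horizon))
  key <- do.call(paste, c(inputs[, -1], sep = "|"))
  mats <- vector("list", horizon)
  for (k in unique(key)) {
    idx <- which(key == k)
    M <- .build_matrix(strategy, params, as.list(inputs[idx[1], ]))
    mats[idx] <- list(M)
  }
  init <- stats::setNames(numeric(8), gist_states())
  init[strategy$start_state] <- 1
  trace <- propagate_cohort(mats, init)
  structure(trace, class = c("cohort_trace", class(trace)),
            start_age = params$scalars$start_age, option_id = strategy$option_id)
}

#' Overall survival curve from a cohort trace
#'
#' @param trace A `cohort_trace` (or any occupancy matrix with a `Dead`
#'   column).
#' @return Data frame with columns `month` (0..H) and `surviving`
#'   (proportion alive), non-increasing from 1.
#' @export
overall_survival <- function(trace) {
  if (!"Dead" %in% colnames(trace)) stop("trace has no 'Dead' column")
  data.frame(month = 0:(nrow(trace) - 1),
             surviving = unname(1 - trace[, "Dead"]))
}

#' Export a cohort trace as CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_trace <- function(trace, path) {
  cyc <- 0:(nrow(trace) - 1)
  start_age <- attr(trace, "start_age") %||% NA_real_
  m <- unclass(trace)
  rownames(m) <- NULL
  out <- cbind(data.frame(cycle = cyc, age = start_age + cyc / 12),
               as.data.frame(m))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
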