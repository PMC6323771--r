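# Treatment-effect synthesis: indirect comparison of the adjuvant hazard
# ratios and the year-banded monthly transition-probability schedules.

#' Construct a hazard-ratio estimate
#'
#' Carries a hazard ratio with its standard error on both the natural and
#' the log scale; the two SEs are linked by the delta method
#' (`se_log ~ se_hr / hr`), and whichever is supplied determines the other.
#'
#' @param hr Point estimate, > 0.
#' @param se_hr SE on the natural (HR) scale.
#' @param se_log SE on the log-HR scale. Supply exactly one of `se_hr`,
#'   `se_log`.
#' @return Object of class `hr_estimate` with fields `hr`, `se_hr`, `se_log`.
#' @export
hr_estimate <- function(hr, se_hr = NULL, se_log = NULL) {
  if (hr <= 0) stop("hr_estimate(): hr must be > 0")
  if (is.null(se_hr) == is.null(se_log)) {
    stop("hr_estimate(): supply exactly one of se_hr, se_log")
  }
  if (is.null(se_log)) {
    if (se_hr < 0) stop("hr_estimate(): se_hr must be >= 0")
    se_log <- se_hr / hr
  } else {
    if (se_log < 0) stop("hr_estimate(): se_log must be >= 0")
    se_hr <- se_log * hr
  }
  structure(list(hr = hr, se_hr = se_hr, se_log = se_log), class = "hr_estimate")
}

#' Bucher indirect comparison of two hazard ratios
#'
#' Combines an A-vs-B and a B-vs-C hazard ratio into an A-vs-C estimate:
#' the point estimates multiply (add on the log scale) and the log-scale
#' SEs add in quadrature; the natural-scale SE follows by the delta method.
#' Used to obtain the 3-years-vs-none adjuvant effect from the
#' 1-year-vs-none and 3-years-vs-1-year trials.
#'
#' @param hr_ab,hr_bc `hr_estimate` objects.
#' @return Combined `hr_estimate`.
#' @export
bucher_combine <- function(hr_ab, hr_bc) {
  stopifnot(inherits(hr_ab, "hr_estimate"), inherits(hr_bc, "hr_estimate"))
  hr <- hr_ab$hr * hr_bc$hr
  se_log <- sqrt(hr_ab$se_log^2 + hr_bc$se_log^2)
  hr_estimate(hr, se_log = se_log)
}

#' Apply a hazard ratio to a per-cycle probability
#'
#' Converts the probability to a constant within-cycle rate, scales the
#' rate by the hazard ratio, and converts back:
#' `1 - (1 - p)^hr`. Monotone in both arguments; identity at `hr = 1`.
#'
#' @param p Monthly probability in `[0, 1)`.
#' @param hr Hazard ratio, > 0.
#' @return Adjusted monthly probability.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(hr <= 0)) stop("apply_hazard_ratio(): hr must be > 0")
  if (any(p < 0) || any(p >= 1)) {
    stop("apply_hazard_ratio(): p must lie in [0, 1) (p = 1 is degenerate)")
  }
  1 - (1 - p)^hr
}

#' Build a piecewise-constant monthly probability schedule
#'
#' @param start,end Integer cycle bounds of each band (inclusive); use
#'   `Inf` for the open-ended last band.
#' @param p Monthly probability per band.
#' @return Object of class `prob_schedule` (data frame with columns
#'   `start`, `end`, `p`). Bands must be contiguous from cycle 1 and
#'   non-overlapping.
#' @export
prob_schedule <- function(start, end, p) {
  stopifnot(length(start) == length(end), length(end) == length(p))
  o <- order(start)
  start <- start[o]; end <- end[o]; p <- p[o]
  if (start[1] != 1) stop("prob_schedule(): bands must start at cycle 1")
  if (length(start) > 1 && any(start[-1] != end[-length(end)] + 1)) {
    stop("prob_schedule(): bands must be contiguous and non-overlapping")
  }
  if (!is.infinite(end[length(end)])) {
    stop("prob_schedule(): last band must be open-ended (end = Inf)")
  }
  if (any(p < 0 | p > 1)) stop("prob_schedule(): probabilities must be in [0, 1]")
  structure(data.frame(start = start, end = end, p = p),
            class = c("prob_schedule", "data.frame"))
}

#' Look up the scheduled probability at a cycle
#'
#' @param schedule A `prob_schedule`.
#' @param cycle Cycle number (>= 1); vectorised.
#' @return Monthly probability at each cycle.
#' @export
schedule_prob <- function(schedule, cycle) {
  if (any(cycle < 1)) stop("schedule_prob(): cycle must be >= 1")
  idx <- findInterval(cycle, schedule$start)
  if (any(idx < 1)) stop("schedule_prob(): cycle before first band")
  schedule$p[idx]
}

# baseline (no-adjuvant) recurrence bands: year-1 value held over months
# 1-12, year-3 over 13-36, year-5 from month 37 on
baseline_recurrence_schedule <- function(params) {
  prob_schedule(start = c(1, 13, 37), end = c(12, 36, Inf),
                p = c(param_value(params, "p_rec_yr1"),
                      param_value(params, "p_rec_yr3"),
                      param_value(params, "p_rec_yr5")))
}

# GIST-specific death bands in the no-recurrence states (all strategies)
gist_death_schedule <- function(params) {
  prob_schedule(start = c(1, 13, 37, 61, 85), end = c(12, 36, 60, 84, Inf),
                p = c(param_value(params, "p_death_gist_yr1"),
                      param_value(params, "p_death_gist_yr3"),
                      param_value(params, "p_death_gist_yr5"),
                      param_value(params, "p_death_gist_yr7"),
                      param_value(params, "p_death_gist_yr9")))
}

#' Monthly recurrence-probability schedule for a strategy
#'
#' Baseline year-banded recurrence probabilities with the strategy's
#' adjuvant hazard ratio applied — via [apply_hazard_ratio()] — only to
#' cycles inside the adjuvant window (the treatment effect is assumed to
#' hold while patients take the drug). Patients who discontinued, completed
#' the course, or never received adjuvant therapy face the unmodified
#' baseline, which this returns when `on_adjuvant = FALSE`.
#'
#' @param params A `gist_params` object.
#' @param strategy A `gist_strategy` (see [make_strategy()]).
#' @param on_adjuvant Schedule for the on-adjuvant state (HR-adjusted
#'   within the window) or for everyone else (baseline)?
#' @return A `prob_schedule`.
#' @export
build_recurrence_schedule <- function(params, strategy, on_adjuvant = TRUE) {
  stopifnot(inherits(strategy, "gist_strategy"))
  base <- baseline_recurrence_schedule(params)
  m <- strategy$adjuvant_months
  if (!on_adjuvant || m == 0) return(base)
  hr <- param_value(params, strategy$hr_param)
  # split baseline bands at the adjuvant-window edge, apply the HR inside
  starts <- c(); ends <- c(); ps <- c()
  for (i in seq_len(nrow(base))) {
    s <- base$start[i]; e <- base$end[i]; p <- base$p[i]
    if (s <= m) {
      starts <- c(starts, s); ends <- c(ends, min(e, m))
      ps <- c(ps, apply_hazard_ratio(p, hr))
    }
    if (e > m) {
      starts <- c(starts, max(s, m + 1)); ends <- c(ends, e); ps <- c(ps, p)
    }
  }
  prob_schedule(starts, ends, ps)
}

# adjuvant discontinuation bands per arm duration; zero outside the window
discontinuation_schedule <- function(params, adjuvant_months) {
  if (adjuvant_months == 0) {
    return(prob_schedule(1, Inf, 0))
  }
  if (adjuvant_months == 12) {
    prob_schedule(start = c(1, 7, 13), end = c(6, 12, Inf),
                  p = c(param_value(params, "p_disc_1yr_m1_6"),
                        param_value(params, "p_disc_1yr_m7_12"), 0))
  } else if (adjuvant_months == 36) {
    prob_schedule(start = c(1, 7, 37), end = c(6, 36, Inf),
                  p = c(param_value(params, "p_disc_3yr_m1_6"),
                        param_value(params, "p_disc_3yr_m7_36"), 0))
  } else {
    stop("no discontinuation bands defined for adjuvant_months = ", adjuvant_months)
  }
}

#' Export a probability schedule as per-cycle CSV
#'
#' @param schedule A `prob_schedule`.
#' @param path Output CSV path.
#' @param cycles Cycles to tabulate (default 1-480).
#' @return The path, invisibly.
#' @export
export_schedule <- function(schedule, path, cycles = 1:480) {
  utils::write.csv(data.frame(cycle = cycles,
                              probability = schedule_prob(schedule, cycles)),
                   path, row.names = FALSE)
  invisible(path)
}
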