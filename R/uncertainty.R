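# Uncertainty analysis: one-way (tornado) sensitivity analysis on the ICER
# and probabilistic sensitivity analysis with CEAC construction.

.support_clip <- function(value, role) {
  switch(role,
         probability = ,
         utility = pmin(pmax(value, 0), 1),
         hazard_ratio = pmax(value, 1e-12),
         pmax(value, 0))
}

#' One-way sensitivity analysis (tornado) on the ICER
#'
#' Varies each target parameter one at a time to the bounds of its 95%
#' confidence interval (mean +/- 1.96 SE on the natural scale, clipped to
#' the parameter's support) while holding everything else at base values,
#' and records the deterministic ICER of `strategy` versus `comparator` at
#' each bound. The discount rate is varied over an explicit 0%-6% range
#' instead (its special target name is `annual_discount_rate`). Entries are
#' sorted by bar width (|ICER high - ICER low|) descending.
#'
#' @param params A `gist_params`.
#' @param life_table A `life_table`.
#' @param targets Parameter names to vary; default: every parameter with
#'   SE > 0 and a non-fixed family, plus the discount rate.
#' @param strategy,comparator Option ids (defaults "2.2" vs "1").
#' @return Data frame with columns `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `width`, sorted by `width` descending.
#' @export
owsa <- function(params, life_table, targets = NULL,
                 strategy = "2.2", comparator = "1") {
  specs <- params$specs
  if (is.null(targets)) {
    targets <- c(specs$name[specs$se > 0 & specs$family != "fixed"],
                 "annual_discount_rate")
  }
  unknown <- setdiff(targets, c(specs$name, "annual_discount_rate"))
  if (length(unknown)) stop("owsa(): unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  base_rate <- params$scalars$annual_discount_rate

  icer_with <- function(p, rate) {
    icer(run_strategy(comparator, p, life_table, annual_rate = rate),
         run_strategy(strategy, p, life_table, annual_rate = rate))
  }

  rows <- lapply(targets, function(nm) {
    if (nm == "annual_discount_rate") {
      lo <- 0; hi <- 0.06
      i_lo <- icer_with(params, lo)
      i_hi <- icer_with(params, hi)
    } else {
      row <- specs[specs$name == nm, ]
      lo <- .support_clip(row$mean - 1.96 * row$se, row$role)
      hi <- .support_clip(row$mean + 1.96 * row$se, row$role)
      i_lo <- icer_with(set_param_values(params, stats::setNames(lo, nm)), base_rate)
      i_hi <- icer_with(set_param_values(params, stats::setNames(hi, nm)), base_rate)
    }
    data.frame(parameter = nm, low = lo, high = hi,
               icer_low = i_lo, icer_high = i_hi,
               width = abs(i_hi - i_lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$width), , drop = FALSE]
}

#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Each parameter with SE > 0 and a non-fixed family is drawn independently
#' from its method-of-moments distribution: Beta for probabilities and
#' utilities, Gamma for costs and visit rates, Lognormal for hazard ratios.
#' Fixed parameters keep their point values. Uses the current RNG state;
#' seed upstream for reproducibility.
#'
#' @param params A `gist_params`.
#' @return A `gist_params` with drawn point values.
#' @export
psa_draw <- function(params) {
  specs <- params$specs
  draw <- params$values
  for (i in seq_len(nrow(specs))) {
    if (specs$family[i] == "fixed" || specs$se[i] <= 0) next
    m <- specs$mean[i]; s <- specs$se[i]
    draw[[specs$name[i]]] <- switch(
      specs$family[i],
      beta = {
        hp <- beta_from_moments(m, s)
        stats::rbeta(1, hp$alpha, hp$beta)
      },
      gamma = {
        hp <- gamma_from_moments(m, s)
        stats::rgamma(1, shape = hp$shape, scale = hp$scale)
      },
      lognormal = {
        hp <- lognormal_from_moments(m, s)
        stats::rlnorm(1, meanlog = hp$mu, sdlog = hp$sigma)
      },
      stop("no sampler for family '", specs$family[i], "'")
    )
  }
  params$values <- draw
  params
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of every uncertain parameter, with each draw
#' evaluated through the full cohort model for every strategy.
#' Deterministic given the seed.
#'
#' @param params A `gist_params`.
#' @param life_table A `life_table`.
#' @param n Number of iterations (default 1000).
#' @param seed RNG seed (required; no silent default).
#' @param options Option ids to evaluate (default all six).
#' @return Object of class `psa_result`: list with `samples` (data frame:
#'   `iteration`, `option_id`, `cost_disc`, `qaly_disc`, `ly_disc`) and
#'   `draws` (matrix of drawn parameter values, one row per iteration).
#' @export
run_psa <- function(params, life_table, n = 1000, seed,
                    options = c("1", "4", "2.1", "2.2", "3.1", "3.2")) {
  if (missing(seed)) stop("run_psa(): a seed is required")
  if (n < 1) stop("run_psa(): n must be >= 1")
  set.seed(seed)
  strategies <- lapply(options, make_strategy)
  rate <- params$scalars$annual_discount_rate
  varied <- params$specs$name[params$specs$se > 0 & params$specs$family != "fixed"]
  draws <- matrix(NA_real_, n, length(varied), dimnames = list(NULL, varied))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- psa_draw(params)
    draws[i, ] <- p_i$values[varied]
    samples[[i]] <- do.call(rbind, lapply(strategies, function(s) {
      res <- run_strategy(s, p_i, life_table, annual_rate = rate)
      data.frame(iteration = i, option_id = s$option_id,
                 cost_disc = res$cost_disc, qaly_disc = res$qaly_disc,
                 ly_disc = res$ly_disc, stringsAsFactors = FALSE)
    }))
  }
  structure(list(samples = do.call(rbind, samples), draws = draws),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the proportion of PSA iterations in
#' which each strategy attains the maximal net monetary benefit; exact ties
#' share their iteration equally.
#'
#' @param psa A `psa_result` (or its `samples` data frame).
#' @param wtp_grid Willingness-to-pay grid in THB per QALY (default 0 to
#'   3,000,000 in steps of 20,000).
#' @return Data frame with columns `wtp`, `option_id`, `probability`;
#'   probabilities sum to 1 at each grid point.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 3e6, by = 2e4)) {
  if (!length(wtp_grid)) stop("ceac(): empty wtp grid")
  samples <- if (inherits(psa, "psa_result")) psa$samples else psa
  if (!nrow(samples)) stop("ceac(): no PSA samples")
  opts <- unique(samples$option_id)
  iters <- sort(unique(samples$iteration))
  cost <- matrix(NA_real_, length(iters), length(opts),
                 dimnames = list(NULL, opts))
  qaly <- cost
  for (j in seq_along(opts)) {
    sub <- samples[samples$option_id == opts[j], ]
    sub <- sub[match(iters, sub$iteration), ]
    cost[, j] <- sub$cost_disc
    qaly[, j] <- sub$qaly_disc
  }
  out <- lapply(wtp_grid, function(w) {
    nmb_mat <- w * qaly - cost
    best <- nmb_mat == apply(nmb_mat, 1, max)
    share <- best / rowSums(best)
    data.frame(wtp = w, option_id = opts,
               probability = colMeans(share), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
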