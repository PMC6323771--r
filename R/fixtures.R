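# Miniature hand-checkable model instances. Each fixture bundles a tiny
# three-state chain with oracle values written as explicit arithmetic
# expressions (exact fractions where possible), so engine output can be
# compared against hand computation at machine precision.

#' Miniature model fixtures with hand-computed oracles
#'
#' Variants:
#' * `"identity"` — identity transitions, utility 1, zero cost, 12 cycles,
#'   no discounting: one full (quality-adjusted) life year, zero cost.
#' * `"two-cycle"` — Alive -> Sick with probability 1/2, Sick -> Dead with
#'   probability 1/2, cost 100 in Sick only, utilities 1 / 1/2 / 0, two
#'   cycles, no discounting: expected cost 50, LY 2/12, QALY 1.75/12.
#' * `"discounting"` — the two-cycle chain at a 3% annual rate: the cycle-1
#'   reward rows pick up the factor 1.03^(-1/12).
#'
#' @param variant Fixture name.
#' @return List with `states`, `P` (transition matrix), `init`, `n_cycles`,
#'   `rate`, `rewards` (a `state_rewards`-shaped data frame), and
#'   `expected` (list: `trace`, `cost`, `ly`, `qaly`).
#' @export
make_mini_fixture <- function(variant = c("identity", "two-cycle", "discounting")) {
  variant <- match.arg(variant)
  states <- c("Alive", "Sick", "Dead")
  init <- c(Alive = 1, Sick = 0, Dead = 0)

  if (variant == "identity") {
    P <- diag(3)
    dimnames(P) <- list(states, states)
    rewards <- data.frame(state = states, cost = c(0, 0, 0), utility = c(1, 1, 0))
    trace <- matrix(rep(c(1, 0, 0), each = 13), 13, 3, dimnames = list(0:12, states))
    return(list(states = states, P = P, init = init, n_cycles = 12, rate = 0,
                rewards = rewards,
                expected = list(trace = trace, cost = 0, ly = 1, qaly = 1)))
  }

  P <- matrix(c(1 / 2, 1 / 2, 0,
                0, 1 / 2, 1 / 2,
                0, 0, 1),
              3, 3, byrow = TRUE, dimnames = list(states, states))
  rewards <- data.frame(state = states, cost = c(0, 100, 0), utility = c(1, 1 / 2, 0))
  # trace by hand: (1,0,0) -> (1/2,1/2,0) -> (1/4, 1/4+1/4, 1/4)
  trace <- matrix(c(1, 0, 0,
                    1 / 2, 1 / 2, 0,
                    1 / 4, 1 / 2, 1 / 4),
                  3, 3, byrow = TRUE, dimnames = list(0:2, states))
  rate <- if (variant == "discounting") 0.03 else 0
  d1 <- (1 + rate)^(-1 / 12)  # discount factor of the cycle-1 reward row
  expected <- list(
    trace = trace,
    cost = 0 * 1 + 100 * (1 / 2) * d1,
    ly = (1 / 12) * (1 + 1 * d1),
    qaly = (1 / 12) * (1 * 1 + (1 / 2 + 1 / 2 * 1 / 2) * d1)
  )
  list(states = states, P = P, init = init, n_cycles = 2, rate = rate,
       rewards = rewards, expected = expected)
}
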