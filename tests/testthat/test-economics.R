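test_that("accumulation matches the hand-computed miniature oracles", {
  for (variant in c("identity", "two-cycle", "discounting")) {
    fx <- make_mini_fixture(variant)
    # independent brute-force propagation: explicit loops, no engine code
    occ <- fx$init
    trace <- matrix(NA_real_, fx$n_cycles + 1, length(fx$states),
                    dimnames = list(0:fx$n_cycles, fx$states))
    trace[1, ] <- occ
    for (t in seq_len(fx$n_cycles)) {
      nxt <- stats::setNames(numeric(length(fx$states)), fx$states)
      for (from in fx$states) for (to in fx$states) {
        nxt[to] <- nxt[to] + occ[from] * fx$P[from, to]
      }
      occ <- nxt
      trace[t + 1, ] <- occ
    }
    expect_equal(trace, fx$expected$trace, tolerance = 1e-12)

    # engine path agrees with both the brute force and the frozen oracle
    eng <- propagate_cohort(fx$P, fx$init, n_cycles = fx$n_cycles)
    expect_equal(unname(eng), unname(trace), tolerance = 1e-12)
    res <- accumulate(eng, fx$rewards, fx$rate, option_id = variant)
    expect_equal(res$cost_disc, fx$expected$cost, tolerance = 1e-12)
    expect_equal(res$ly_disc, fx$expected$ly, tolerance = 1e-12)
    expect_equal(res$qaly_disc, fx$expected$qaly, tolerance = 1e-12)
  }
  expect_error(make_mini_fixture("nope"))
})

test_that("a full year alive at utility one is exactly one (QA)LY", {
  fx <- make_mini_fixture("identity")
  res <- accumulate(propagate_cohort(fx$P, fx$init, 12), fx$rewards, 0)
  expect_equal(res$ly_undisc, 1, tolerance = 1e-12)
  expect_equal(res$qaly_undisc, 1, tolerance = 1e-12)
  expect_identical(res$cost_undisc, 0)
})

test_that("zero discount rate collapses discounted onto undiscounted", {
  res <- run_strategy("1", test_params(), test_life_table(), annual_rate = 0)
  expect_equal(res$cost_disc, res$cost_undisc, tolerance = 1e-12)
  expect_equal(res$ly_disc, res$ly_undisc, tolerance = 1e-12)
  expect_equal(res$qaly_disc, res$qaly_undisc, tolerance = 1e-12)
})

test_that("accumulation is linear in rewards and shape-checked", {
  params <- test_params()
  lt <- test_life_table()
  s <- make_strategy("1")
  tr <- run_cohort(s, params, lt, horizon = 60)
  rew <- state_rewards(s, params)
  res1 <- accumulate(tr, rew, 0.03)
  rew2 <- rew
  rew2$cost <- 2 * rew2$cost
  res2 <- accumulate(tr, rew2, 0.03)
  expect_equal(res2$cost_disc, 2 * res1$cost_disc, tolerance = 1e-12)
  expect_equal(res2$qaly_disc, res1$qaly_disc)
  bad <- rew[rew$state != "Dead", ]
  expect_error(accumulate(tr, bad, 0.03), "do not match")
})

test_that("econ results satisfy the discounting and utility bounds", {
  res <- test_base_case()
  expect_true(all(res$cost_disc <= res$cost_undisc))
  expect_true(all(res$ly_disc <= res$ly_undisc))
  expect_true(all(res$qaly_disc <= res$qaly_undisc))
  expect_true(all(res$qaly_disc <= res$ly_disc))
  expect_true(all(res$qaly_undisc <= res$ly_undisc))
  expect_true(all(unlist(res[-1]) >= 0))
})

test_that("the ICER is incremental cost over incremental QALYs", {
  # on the reference cost/QALY table: (4,648,080 - 2,744,275) / (6.50 - 5.34);
  # with QALYs rounded to 2 d.p. the ratio is 1,641,211
  lo <- data.frame(option_id = "1", cost_disc = 2744275, qaly_disc = 5.34)
  hi <- data.frame(option_id = "2.2", cost_disc = 4648080, qaly_disc = 6.50)
  expect_equal(icer(lo, hi), 1903805 / 1.16, tolerance = 1e-12)
  expect_equal(icer(lo, hi), 1641211, tolerance = 1e-6 * 1641211)
  expect_equal(icer(data.frame(cost_disc = 5, qaly_disc = 1),
                    data.frame(cost_disc = 5, qaly_disc = 2)), 0)
  expect_warning(out <- icer(lo, transform(lo, cost_disc = 99)), "undefined")
  expect_true(is.na(out))
})

test_that("the frontier reproduces the reference dominance pattern", {
  # reference discounted cost/QALY pairs of the six options
  printed <- data.frame(
    option_id = c("1", "4", "2.1", "3.1", "2.2", "3.2"),
    cost_disc = c(2744275, 3368809, 3393388, 3979869, 4648080, 5056583),
    qaly_disc = c(5.34, 5.58, 5.63, 5.86, 6.50, 6.65)
  )
  fr <- efficiency_frontier(printed)
  lab <- stats::setNames(fr$label, fr$option_id)
  expect_equal(unname(lab[c("1", "2.2", "3.2")]), rep("on_frontier", 3))
  expect_equal(unname(lab[c("4", "2.1", "3.1")]), rep("extendedly_dominated", 3))
  ic <- fr$icer[fr$label == "on_frontier"]
  expect_true(all(diff(ic[-1]) > 0) || length(ic) <= 2)
  expect_equal(fr$icer[fr$option_id == "2.2"], (4648080 - 2744275) / (6.50 - 5.34),
               tolerance = 1e-12)
})

test_that("frontier labelling is order-invariant and handles edge shapes", {
  two <- data.frame(option_id = c("a", "b"),
                    cost_disc = c(10, 5), qaly_disc = c(1, 2))
  fr <- efficiency_frontier(two)
  expect_equal(fr$label[fr$option_id == "a"], "strictly_dominated")

  # three collinear points: the middle one stays on the frontier
  col3 <- data.frame(option_id = c("a", "b", "c"),
                     cost_disc = c(0, 100, 200), qaly_disc = c(0, 1, 2))
  fr3 <- efficiency_frontier(col3)
  expect_equal(fr3$label, rep("on_frontier", 3))

  set.seed(33)
  pts <- data.frame(option_id = letters[1:6],
                    cost_disc = runif(6, 1e6, 5e6), qaly_disc = runif(6, 4, 7))
  f1 <- efficiency_frontier(pts)
  f2 <- efficiency_frontier(pts[sample(6), ])
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f1, f2)
  idx <- f1$label == "on_frontier"
  expect_true(all(diff(f1$icer[idx][-1]) > 0) || sum(idx) <= 2)
})

test_that("net monetary benefit follows the standard definition", {
  res <- data.frame(cost_disc = 2744275, qaly_disc = 5.34)
  expect_equal(nmb(res, 0), -2744275)
  expect_equal(nmb(res, 160000), 160000 * 5.34 - 2744275)
  expect_equal(nmb(res, 160000), -1889875)
  # at huge WTP the NMB ordering is the QALY ordering
  base <- test_base_case()
  expect_equal(order(nmb(base, 1e12)), order(base$qaly_disc))
  expect_error(nmb(res, -1), ">= 0")
})

test_that("the ICER is monotone in the imatinib price (bisection premise)", {
  params <- test_params()
  lt <- test_life_table()
  s1 <- make_strategy("1"); s22 <- make_strategy("2.2")
  tr1 <- run_cohort(s1, params, lt)
  tr22 <- run_cohort(s22, params, lt)
  prices <- seq(100, 3659.40, length.out = 10)
  icers <- sapply(prices, function(p) {
    icer(accumulate(tr1, state_rewards(s1, params, p), 0.03),
         accumulate(tr22, state_rewards(s22, params, p), 0.03))
  })
  expect_true(all(diff(icers) > 0))
})

test_that("the threshold solver recovers a fixed point and flags bad brackets", {
  params <- test_params()
  lt <- test_life_table()
  base <- test_base_case()
  base_icer <- icer(base["1", ], base["2.2", ])
  th <- threshold_price(params, lt, wtp = base_icer, price_bounds = c(1, 5000))
  expect_equal(th$price, 3659.40, tolerance = 1e-3 * 3659.40)
  # a target far above the ICER at the full current price cannot be bracketed
  expect_error(threshold_price(params, lt, wtp = 1e9), "bracket")
})
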