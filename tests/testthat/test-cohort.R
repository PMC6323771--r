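test_that("monthly drug cost is truncated unit-price arithmetic", {
  # imatinib: one 400 mg tablet per day at the 2014 reference price
  expect_equal(monthly_drug_cost(3659.40, 1), 111306)
  expect_equal(monthly_drug_cost(1, 1, 30), 30)
  # four 12.5 mg sunitinib capsules per day without the on/off schedule;
  # the scheduled monthly cost used in the model (82,173) is a direct input
  expect_equal(monthly_drug_cost(1100.53, 4), 133897)
  expect_error(monthly_drug_cost(-1, 1), "positive")
})

test_that("mortality combination is independent competing risks", {
  expect_equal(combine_mortality(0, 0.001), 0.001)
  expect_equal(combine_mortality(0.0017, 0.0008), 1 - 0.9983 * 0.9992, tolerance = 1e-12)
  expect_equal(combine_mortality(0.0017, 0.0008), 0.0024986, tolerance = 1e-4)
  expect_equal(combine_mortality(1, 0.3), 1)
  set.seed(11)
  p <- runif(20); q <- runif(20)
  expect_equal(combine_mortality(p, q), combine_mortality(q, p))
  expect_true(all(combine_mortality(p, q) >= pmax(p, q)))
  expect_error(combine_mortality(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("state rewards assemble drug, monitoring, AE and visit costs", {
  params <- test_params()
  rew <- state_rewards(make_strategy("2.2"), params)
  r <- function(st, col) rew[rew$state == st, col]
  visit <- 296 + 109 + 99
  expect_equal(r("NoRec_NoAdj", "cost"), 2758 + 0.3 * visit)   # 2909.2
  expect_equal(r("NoRec_OnAdj", "cost"), 111306 + 1477 + 570 + 0.6 * visit)
  expect_equal(r("NoRec_Completed", "cost"), r("NoRec_NoAdj", "cost"))
  expect_equal(r("Rec_Imatinib", "cost"), 111306 + 4213 + visit)
  expect_equal(r("Rec_Sunitinib", "cost"), 82173 + 7141 + visit)
  expect_equal(r("Rec_BSC", "cost"), 4247 + visit)
  expect_equal(r("NoRec_OnAdj", "utility"), 0.79)
  expect_equal(r("NoRec_Discontinued", "utility"), 0.89)
  expect_equal(r("Rec_BSC", "utility"), 0.42)
  expect_equal(r("Dead", "cost"), 0)
  expect_equal(r("Dead", "utility"), 0)
})

test_that("a price override rescales every imatinib-dispensing state", {
  params <- test_params()
  s <- make_strategy("2.2")
  full <- state_rewards(s, params)
  half <- state_rewards(s, params, imatinib_price_override = 3659.40 / 2)
  d <- function(st) full$cost[full$state == st] - half$cost[half$state == st]
  expect_equal(d("NoRec_OnAdj"), 111306 / 2)
  expect_equal(d("Rec_Imatinib"), 111306 / 2)
  expect_equal(d("Rec_Sunitinib"), 0)
  expect_equal(d("Rec_BSC"), 0)
})

test_that("transition rows are stochastic for all options across the horizon", {
  params <- test_params()
  lt <- test_life_table()
  cycles <- c(1, 6, 7, 12, 13, 36, 37, 40, 60, 61, 84, 85, 120, 480)
  for (s in all_strategies()) {
    for (cyc in cycles) {
      M <- transition_matrix(s, params, lt, cyc)
      expect_equal(unname(rowSums(M)), rep(1, 8), tolerance = 1e-12)
      expect_true(all(M >= 0))
      expect_equal(unname(M["Dead", "Dead"]), 1)
    }
  }
})

test_that("transition structure matches the pathway encoding", {
  params <- test_params()
  lt <- test_life_table()
  bg60 <- monthly_background_prob(lt, 60)

  # option 1, cycle 6: recurrence goes to the imatinib line at the year-1
  # band value; death combines chart-review and background mortality
  M <- transition_matrix(make_strategy("1"), params, lt, 6)
  expect_equal(unname(M["NoRec_NoAdj", "Rec_Imatinib"]), 0.0205)
  expect_equal(unname(M["NoRec_NoAdj", "Dead"]), combine_mortality(0.0017, bg60),
               tolerance = 1e-12)
  expect_equal(unname(M["Rec_BSC", "Dead"]), combine_mortality(0.0680, bg60),
               tolerance = 1e-12)
  expect_equal(unname(M["Rec_BSC", "Rec_Imatinib"]), 0)  # no progression exit
  # option 1 progresses imatinib -> BSC; option 4 imatinib -> sunitinib
  expect_equal(unname(M["Rec_Imatinib", "Rec_BSC"]), 0.015)
  M4 <- transition_matrix(make_strategy("4"), params, lt, 6)
  expect_equal(unname(M4["Rec_Imatinib", "Rec_Sunitinib"]), 0.015)

  # option 2.2 on adjuvant: HR-adjusted recurrence straight to BSC,
  # banded discontinuation
  M22 <- transition_matrix(make_strategy("2.2"), params, lt, 6)
  expect_equal(unname(M22["NoRec_OnAdj", "Rec_BSC"]),
               apply_hazard_ratio(0.0205, 0.133), tolerance = 1e-12)
  expect_equal(unname(M22["NoRec_OnAdj", "NoRec_Discontinued"]), 0.0097)
  # discontinued patients recur at baseline risk into the during-adjuvant line
  expect_equal(unname(M22["NoRec_Discontinued", "Rec_BSC"]), 0.0205)
  # post-completion recurrence goes to imatinib at baseline risk
  expect_equal(unname(M22["NoRec_Completed", "Rec_Imatinib"]), 0.0205)

  # at the final adjuvant cycle the remaining on-adjuvant mass completes
  M36 <- transition_matrix(make_strategy("2.2"), params, lt, 36)
  expect_equal(unname(M36["NoRec_OnAdj", "NoRec_OnAdj"]), 0)
  expect_gt(M36["NoRec_OnAdj", "NoRec_Completed"], 0.9)
  tr <- run_cohort("2.2", params, lt, horizon = 40)
  expect_equal(unname(tr["37", "NoRec_OnAdj"]), 0)
  expect_gt(tr["37", "NoRec_Completed"], 0.5)
})

test_that("with all risks zeroed the cohort never leaves its start state", {
  p0 <- frozen_params()
  tr <- run_cohort("1", p0, test_life_table(), horizon = 24)
  expect_equal(unname(tr[, "NoRec_NoAdj"]), rep(1, 25))
})

test_that("short traces equal explicit matrix-power computation", {
  params <- test_params()
  lt <- test_life_table()
  for (id in c("1", "2.2", "3.1")) {
    s <- make_strategy(id)
    tr <- run_cohort(s, params, lt, horizon = 3)
    init <- stats::setNames(numeric(8), gist_states())
    init[s$start_state] <- 1
    M1 <- transition_matrix(s, params, lt, 1)
    M2 <- transition_matrix(s, params, lt, 2)
    M3 <- transition_matrix(s, params, lt, 3)
    expect_equal(unname(tr["1", ]), unname(init %*% M1)[1, ], tolerance = 1e-12)
    expect_equal(unname(tr["2", ]), unname(init %*% M1 %*% M2)[1, ], tolerance = 1e-12)
    expect_equal(unname(tr["3", ]), unname(init %*% M1 %*% M2 %*% M3)[1, ], tolerance = 1e-12)
  }
})

test_that("traces conserve mass with monotone deaths for random parameter sets", {
  params <- test_params()
  lt <- test_life_table()
  set.seed(202)
  for (i in 1:5) {
    p_i <- psa_draw(params)
    for (id in c("1", "2.2")) {
      tr <- suppressWarnings(run_cohort(id, p_i, lt, horizon = 120))
      expect_equal(unname(rowSums(tr)), rep(1, 121), tolerance = 1e-9)
      expect_true(all(tr >= -1e-15))
      expect_true(all(diff(tr[, "Dead"]) >= -1e-15))
    }
  }
})

test_that("neutralised adjuvant therapy replicates the no-adjuvant trace", {
  # HR = 1 and no discontinuation make option 2.2 equal option 1 through the
  # adjuvant window, up to the state label of the starting pool
  p <- set_param_values(test_params(), c(hr_adjuvant_3yr = 1,
                                         p_disc_3yr_m1_6 = 0, p_disc_3yr_m7_36 = 0))
  lt <- test_life_table()
  tr1 <- run_cohort("1", p, lt, horizon = 36)
  tr22 <- run_cohort("2.2", p, lt, horizon = 36)
  # the on-adjuvant pool (moved to Completed at the window edge) mirrors the
  # untreated pool exactly
  expect_equal(unname(tr22[, "NoRec_OnAdj"] + tr22[, "NoRec_Completed"]),
               unname(tr1[, "NoRec_NoAdj"]), tolerance = 1e-12)
  expect_equal(unname(tr22[, "Dead"] + tr22[, "Rec_BSC"]),
               unname(tr1[, "Dead"] + tr1[, "Rec_Imatinib"] + tr1[, "Rec_BSC"]),
               tolerance = 1e-12)
})

test_that("longer or more effective adjuvant therapy never loses life years", {
  # with discontinuation switched off, life expectancy is monotone in the
  # adjuvant exposure (none -> 1 year -> 3 years)
  p <- set_param_values(test_params(), c(p_disc_1yr_m1_6 = 0, p_disc_1yr_m7_12 = 0,
                                         p_disc_3yr_m1_6 = 0, p_disc_3yr_m7_36 = 0))
  lt <- test_life_table()
  ly <- sapply(c("1", "2.1", "2.2"), function(id) {
    run_strategy(id, p, lt)$ly_disc
  })
  expect_true(all(diff(ly) > 0))
})

test_that("overall survival starts at 1, never increases, and favours adjuvant", {
  params <- test_params()
  lt <- test_life_table()
  os1 <- overall_survival(run_cohort("1", params, lt, horizon = 120))
  expect_equal(os1$surviving[1], 1)
  expect_true(all(diff(os1$surviving) <= 1e-15))
  os22 <- overall_survival(run_cohort("2.2", params, lt, horizon = 120))
  expect_gt(os22$surviving[os22$month == 36], os1$surviving[os1$month == 36])
  # absorbing toy: certain death in one cycle
  toy <- matrix(c(0, 1, 0, 1), 2, 2, dimnames = list(0:1, c("Alive", "Dead")))
  expect_equal(overall_survival(toy)$surviving, c(1, 0))
})

test_that("traces export with cohort age per cycle", {
  tmp <- tempfile(fileext = ".csv")
  export_trace(run_cohort("1", test_params(), test_life_table(), horizon = 12), tmp)
  out <- read.csv(tmp)
  expect_equal(nrow(out), 13)
  expect_equal(out$age, 60 + (0:12) / 12)
  expect_equal(out$NoRec_NoAdj[1], 1)
})
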