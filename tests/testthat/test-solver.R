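test_that("with all parameters zeroed, value is just years alive and AM wins ties", {
  # no mortality, no lump sum, no disutility, no terminal reward: each
  # remaining year is worth exactly 1 QALY under AM, biopsy can only
  # forfeit continuation (lump sum 0), and exact ties resolve to AM
  inst <- make_small_instance(3L, 3L, seed = 11L, zero_rewards = TRUE)
  sol <- backward_induction(inst$mdp)
  expect_equal(unname(sol$value),
               matrix(rep(c(3, 2, 1, 0), 3), 4, 3), tolerance = 1e-12)
  expect_true(all(sol$policy == "AM"))
  # a zero-risk state is an exact tie between AM and BX: AM is chosen
  expect_true(all(sol$policy[, inst$risk_frac == 0] == "AM"))
})

test_that("a 2-state, 1-epoch instance matches enumeration of its 4 policies", {
  inst <- make_small_instance(2L, 1L, seed = 5L)
  sol <- backward_induction(inst$mdp)
  oracle <- oracle_enumerate(inst)
  expect_lt(max(abs(sol$value - oracle)), 1e-9)
  # and the recorded policy achieves that value
  expect_lt(max(abs(evaluate_policy(inst$mdp, sol$policy) - oracle)), 1e-9)
})

test_that("backward induction equals exhaustive policy enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:4, 1)
    epochs <- sample(1:3, 1)
    inst <- make_small_instance(n, epochs, seed = seed * 101L)
    sol <- backward_induction(inst$mdp)
    oracle <- oracle_enumerate(inst)
    expect_lt(max(abs(sol$value - oracle)), 1e-9)
  }
})

test_that("evaluating the optimal policy reproduces the optimal value", {
  inst <- make_small_instance(4L, 3L, seed = 77L)
  sol <- backward_induction(inst$mdp)
  expect_lt(max(abs(evaluate_policy(inst$mdp, sol$policy) - sol$value)), 1e-12)
})

test_that("fixed suboptimal policies are dominated by the optimum", {
  inst <- make_small_instance(3L, 3L, seed = 13L)
  sol <- backward_induction(inst$mdp)
  ages <- inst$horizon$start_age:inst$horizon$last_decision_age
  all_am <- matrix("AM", length(ages), 3)
  all_bx <- matrix("BX", length(ages), 3)
  expect_true(all(evaluate_policy(inst$mdp, all_am) <= sol$value + 1e-12))
  expect_true(all(evaluate_policy(inst$mdp, all_bx) <= sol$value + 1e-12))
})

test_that("a single-epoch all-BX policy equals its closed-form expectation", {
  inst <- make_small_instance(3L, 1L, seed = 21L)
  p <- inst$params
  a <- inst$horizon$start_age
  V <- evaluate_policy(inst$mdp, matrix("BX", 1, 3))
  oc <- inst$tabs$other_cause[[as.character(a)]]
  d <- (p$d40 + (p$factor - 1) * p$d40 * (a - 40) / 60) / 52
  L <- p$pct_invasive * inst$tabs$invasive[[as.character(a)]] +
    (1 - p$pct_invasive) * inst$tabs$dcis[[as.character(a)]]
  x <- inst$risk_frac
  expected <- x * (L - if (p$malignant_disutility) d else 0) +
    (1 - x) * (1 - oc / 2 - d + (1 - oc) * p$terminal_reward)
  expect_equal(unname(V[1, ]), expected, tolerance = 1e-12)
})

test_that("threshold extraction finds the smallest BX score and checks structure", {
  ages <- 60:62
  pol <- matrix("AM", 3, 101, dimnames = list(ages, 0:100))
  pol[, (2 + 1):101] <- "BX"    # BX exactly for s >= 2
  thr <- extract_threshold(pol)
  expect_equal(thr$threshold, rep(2L, 3))
  expect_true(all(thr$control_limit))

  all_am <- matrix("AM", 3, 101, dimnames = list(ages, 0:100))
  thr <- extract_threshold(all_am)
  expect_equal(thr$threshold, rep(101L, 3))   # sentinel: biopsy never optimal
  expect_true(all(thr$control_limit))

  # a non-control-limit row is reported, not repaired
  hole <- pol
  hole[2, 51] <- "AM"
  thr <- extract_threshold(hole)
  expect_equal(thr$threshold[2], 2L)
  expect_false(thr$control_limit[2])
  expect_true(all(thr$control_limit[-2]))
})

test_that("value function is finite and bounded by terminal reward plus horizon", {
  k <- synthetic_base_kernel()
  tabs <- make_fixture_tables()
  mdp <- build_instance(k, base_reward_spec(tabs))
  sol <- backward_induction(mdp)
  expect_true(all(is.finite(sol$value)))
  bound <- tabs$terminal_reward + (100 - 40)
  expect_true(all(sol$value <= bound))
  expect_true(all(sol$value >= 0))
})

test_that("raising a lump-sum entry never lowers any value", {
  inst <- make_small_instance(3L, 3L, seed = 31L)
  sol1 <- backward_induction(inst$mdp)
  bumped <- inst$mdp
  lifted <- inst$tabs$invasive
  lifted[2] <- lifted[2] + 0  # keep non-increasing: lift the first entry
  lifted[1] <- lifted[1] + 5
  bumped$rewards$lump <- lump_sum_tables(lifted, inst$tabs$dcis + 5,
                                         inst$params$pct_invasive)
  sol2 <- backward_induction(bumped)
  expect_true(all(sol2$value >= sol1$value - 1e-12))
})
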