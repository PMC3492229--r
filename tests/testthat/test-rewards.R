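test_that("disutility schedule is linear between its age anchors", {
  sched <- disutility_schedule()   # base case: 2 weeks at 40, factor 2
  expect_equal(disutility_at(40, sched) * 52, 2)
  expect_equal(disutility_at(100, sched) * 52, 4)
  expect_equal(disutility_at(70, sched) * 52, 3)   # linear midpoint
  expect_error(disutility_at(39, sched), "age")
  expect_error(disutility_at(101, sched), "age")
})

test_that("disutility is monotone in age according to the factor", {
  ages <- 40:100
  for (f in c(0.5, 1, 2, 4)) {
    d <- disutility_at(ages, disutility_schedule(2, f))
    if (f >= 1) expect_false(is.unsorted(d)) else expect_false(is.unsorted(rev(d)))
  }
  # factor 1: constant
  expect_equal(diff(disutility_at(ages, disutility_schedule(2, 1))),
               rep(0, 60))
})

test_that("annual death probability combines competing risks as specified", {
  tabs <- mortality_tables(c("50" = 0.01), c("50" = 0.10))
  eff <- treatment_effect(1.6)
  # hand arithmetic: 1 - 0.99 * (1 - 1.0 * 0.16) = 0.1684
  expect_equal(annual_death_prob(50, 100, tabs, eff), 0.1684)
  # no hazard at all
  tabs0 <- mortality_tables(c("50" = 0), c("50" = 0.10))
  expect_equal(annual_death_prob(50, 0, tabs0, eff), 0)
  # breast-cancer term vanishes at risk 0
  expect_equal(annual_death_prob(50, 0, tabs, eff), 0.01)
  # untreated mortality is capped at 1
  tabs_hi <- mortality_tables(c("50" = 0.01), c("50" = 0.9))
  expect_equal(annual_death_prob(50, 100, tabs_hi, eff), 1 - 0.99 * 0)
  expect_error(annual_death_prob(50, 101, tabs, eff), "range")
})

test_that("death probability is non-decreasing in risk and bounded", {
  tabs <- mortality_tables(c("60" = 0.02), c("60" = 0.12))
  eff <- treatment_effect(1.6)
  p <- annual_death_prob(rep(60, 101), 0:100, tabs, eff)
  expect_false(is.unsorted(p))
  expect_true(all(p >= 0.02 - 1e-15 & p <= 1))
})

test_that("intermediate reward applies the half-cycle correction", {
  expect_equal(intermediate_reward(0), 1)
  expect_equal(intermediate_reward(1), 0.5)   # half a year in the death year
  expect_equal(intermediate_reward(0.2), 0.9)
  p <- seq(0, 1, by = 0.01)
  r <- intermediate_reward(p)
  expect_equal(r, 1 - 0.5 * p)                # linear, decreasing
  expect_true(all(r >= 0.5 & r <= 1))
  expect_error(intermediate_reward(1.1), "p_death")
})

test_that("benign biopsy year subtracts the disutility from a cancer-free year", {
  sched <- disutility_schedule()
  expect_equal(benign_biopsy_reward(40, 0, sched), 1 - 2 / 52)
  # zero disutility: equals the plain intermediate reward
  z <- disutility_schedule(0, 2)
  expect_equal(benign_biopsy_reward(55, 0.03, z), intermediate_reward(0.03))
  expect_error(benign_biopsy_reward(100, 0.1, sched), "terminal")
})

test_that("lump sum mixes invasive and DCIS prognoses", {
  lt <- lump_sum_tables(c("60" = 10), c("60" = 14), pct_invasive = 0.75)
  expect_equal(lump_sum(60, lt), 11)
  expect_equal(lump_sum(60, lump_sum_tables(c("60" = 10), c("60" = 14), 1)), 10)
  expect_equal(lump_sum(60, lump_sum_tables(c("60" = 10), c("60" = 14), 0)), 14)
  expect_error(lump_sum(61, lt), "not covered")
  # non-increasing in pct_invasive when DCIS prognosis dominates invasive
  mixes <- sapply(seq(0, 1, 0.05), function(f)
    lump_sum(60, lump_sum_tables(c("60" = 10), c("60" = 14), f)))
  expect_false(is.unsorted(rev(mixes)))
})

test_that("reward-table constructors reject malformed inputs", {
  expect_error(mortality_tables(c("50" = 1.2), c("50" = 0.1)), "\\[0, 1\\]")
  expect_error(lump_sum_tables(setNames(c(5, 6), 60:61), c("60" = 9, "61" = 8)),
               "non-increasing")
  expect_error(treatment_effect(-1), "positive")
  expect_error(disutility_schedule(-1), "d40")
})
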