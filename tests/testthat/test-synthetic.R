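test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 300L, seed = 42L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$trajectories, c2$trajectories)
  expect_identical(c1$outcomes, c2$outcomes)
})

test_that("cohort summary statistics match their configured targets", {
  cfg <- cohort_config(n_patients = 4000L, seed = 7L)
  co <- generate_cohort(cfg)
  tr <- co$trajectories
  entry <- tr[, .(age = min(age)), by = finding_id]$age
  # clipping at 40 pulls the mean up slightly; allow for that
  expect_gt(mean(entry), 55.5)
  expect_lt(mean(entry), 59.5)
  expect_identical(length(unique(tr$finding_id)), 4000L)
  expect_true(all(tr$age >= 40))
  expect_true(all(tr$risk_score %in% 0:100))
  # some single-exam findings exist (the exclusion rule gets exercised)
  n_exams <- tr[, .N, by = finding_id]$N
  expect_gt(sum(n_exams == 1L), 0)
  expect_gt(mean(n_exams), 2.2)
  expect_lt(mean(n_exams), 3.2)
})

test_that("observed cancer rate lies in the exact binomial interval", {
  cfg <- cohort_config(n_patients = 1000L, seed = 123L,
                       cancer_rate_per_exam = 0.01)
  co <- generate_cohort(cfg)
  n <- nrow(co$outcomes)
  # exact binomial 99% interval for the observed count at the target rate
  ci_count <- stats::qbinom(c(0.005, 0.995), n, 0.01)
  expect_gte(sum(co$outcomes$cancer), ci_count[1])
  expect_lte(sum(co$outcomes$cancer), ci_count[2])
  # calibration hits the target in expectation
  expect_equal(mean(co$outcomes$p_cancer), 0.01, tolerance = 1e-6)
})

test_that("forced gaps give multi-year spacing and exercise interpolation", {
  cfg <- cohort_config(n_patients = 200L, seed = 5L, gap_probability = 1)
  co <- generate_cohort(cfg)
  sp <- co$trajectories[, if (.N > 1) .(d = diff(age)), by = finding_id]$d
  expect_true(all(sp >= 2 - 1e-9))
  ann <- annualize_trajectory(co$trajectories[finding_id %in%
    co$trajectories[, .N, by = finding_id][N > 1L, finding_id]])
  expect_gt(sum(ann$imputed), 0)
})

test_that("unachievable cancer rates are rejected", {
  cfg <- cohort_config(n_patients = 50L, seed = 1L,
                       baseline_score_weights = c(1, rep(0, 100)),
                       true_kernel = transition_kernel(diag(101)),
                       cancer_rate_per_exam = 0.5)
  expect_error(generate_cohort(cfg), "unsatisfiable")
})

test_that("fixture tables satisfy their constructed invariants", {
  tabs <- make_fixture_tables()
  expect_false(is.unsorted(tabs$other_cause))            # mortality rises
  expect_true(all(tabs$dcis_expected_life >= tabs$invasive_expected_life))
  expect_false(is.unsorted(rev(tabs$invasive_expected_life)))
  expect_false(is.unsorted(rev(tabs$dcis_expected_life)))
  expect_gt(tabs$terminal_reward, 0)
  expect_lt(tabs$terminal_reward, 10)
  expect_true(all(tabs$other_cause >= 0 & tabs$other_cause <= 1))
})

test_that("shipped fixture files match the generator exactly", {
  shipped <- read_fixture_tables()
  built <- make_fixture_tables()
  for (nm in c("other_cause", "treated_bc_invasive",
               "invasive_expected_life", "dcis_expected_life")) {
    expect_equal(shipped[[nm]], built[[nm]], tolerance = 1e-15, label = nm)
  }
  expect_equal(shipped$terminal_reward, built$terminal_reward,
               tolerance = 1e-15)
})

test_that("the synthetic base kernel is a valid, upward-drifting kernel", {
  k <- synthetic_base_kernel()
  expect_equal(rowSums(k$matrix), rep(1, 101), ignore_attr = TRUE)
  means <- as.vector(k$matrix %*% 0:100)
  drift <- means - 0:100
  # upward drift except where the 0..100 truncation pulls the mean back
  expect_gt(drift[1], 0)
  expect_gt(drift[51], drift[2])    # heavier upward pull at higher scores
})

test_that("kernel estimated from a dense cohort recovers the ground truth", {
  cfg <- cohort_config(
    n_patients = 6000L, seed = 99L, gap_probability = 0,
    baseline_score_weights = c(rep(1, 16), rep(0, 85)),  # cover rows 0..15
    exam_count_probs = c(0, 0, 0, 0, 0, 0, 0, 1)          # 8 exams each
  )
  co <- generate_cohort(cfg)
  k <- estimate_kernel(co$trajectories)
  true_k <- cfg$true_kernel
  rows <- which(k$support_counts >= 1500)
  expect_gt(length(rows), 10)
  tv <- sapply(rows, function(i)
    0.5 * sum(abs(k$matrix[i, ] - true_k$matrix[i, ])))
  expect_lt(max(tv), 0.05)
})
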