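traj <- function(id, age, score) {
  data.frame(finding_id = id, age = age, risk_score = score)
}

test_that("annualization imputes linearly with half-up integer rounding", {
  # 1% at 40, 5% at 42 -> imputed 3% at 41
  out <- annualize_trajectory(traj("f1", c(40, 42), c(1, 5)))
  expect_equal(out$age, c(40, 41, 42))
  expect_equal(out$risk_score, c(1, 3, 5))
  expect_equal(out$imputed, c(FALSE, TRUE, FALSE))

  # already-annual trajectories are unchanged
  out <- annualize_trajectory(traj("f2", c(50, 51), c(4, 7)))
  expect_equal(out$age, c(50, 51))
  expect_equal(out$risk_score, c(4, 7))
  expect_false(any(out$imputed))

  # three-year gap forces two interpolated points
  out <- annualize_trajectory(traj("f3", c(60, 63), c(2, 8)))
  expect_equal(out$age, 60:63)
  expect_equal(out$risk_score, c(2, 4, 6, 8))

  # non-integer ages: observed endpoints preserved, spacing ~annual
  out <- annualize_trajectory(traj("f4", c(40.3, 42.7), c(0, 10)))
  expect_equal(out$age, c(40.3, 41.5, 42.7))
  expect_equal(out$risk_score, c(0, 5, 10))

  expect_error(annualize_trajectory(traj("f5", c(40, 40), c(1, 2))),
               "duplicate")
  expect_error(annualize_trajectory(traj("f6", c(40, 41), c(1, 200))),
               "0..100")
})

test_that("kernel estimation counts annual pairs and normalizes rows", {
  obs <- rbind(traj("a", 40:42, c(2, 2, 3)),
               traj("b", 50:52, c(2, 3, 3)))
  k <- estimate_kernel(obs)
  expect_s3_class(k, "transition_kernel")
  expect_equal(k$support_counts[3], 3L)          # three departures from 2
  expect_equal(k$matrix[3, 3], 1 / 3)            # 2 -> 2 once
  expect_equal(k$matrix[3, 4], 2 / 3)            # 2 -> 3 twice
  expect_equal(rowSums(k$matrix), rep(1, 101), ignore_attr = TRUE)
  expect_true(all(k$matrix >= 0 & k$matrix <= 1))
})

test_that("self-transition corpora give identity rows for observed scores", {
  obs <- rbind(traj("a", 40:44, rep(6, 5)), traj("b", 50:53, rep(30, 4)))
  k <- estimate_kernel(obs)
  expect_equal(k$matrix[7, 7], 1)
  expect_equal(k$matrix[31, 31], 1)
  expect_false(k$imputed[7])
  expect_true(k$imputed[1])      # unobserved scores flagged as imputed ...
  expect_equal(k$matrix[1, 1], 1)  # ... with explicit self-transition mass
})

test_that("single-observation findings are excluded without side effects", {
  base <- rbind(traj("a", 40:42, c(1, 2, 2)))
  with_single <- rbind(base, traj("solo", 45, 60))
  k1 <- estimate_kernel(base)
  k2 <- estimate_kernel(with_single)
  expect_identical(k1$matrix, k2$matrix)
  expect_identical(k1$support_counts, k2$support_counts)
  expect_error(estimate_kernel(traj("solo", 45, 60)), "single observation")
})

test_that("estimation is invariant to trajectory ordering", {
  set.seed(7)
  obs <- do.call(rbind, lapply(1:50, function(i)
    traj(sprintf("f%02d", i), 40:44, sample(0:10, 5, replace = TRUE))))
  k1 <- estimate_kernel(obs)
  k2 <- estimate_kernel(obs[sample(nrow(obs)), ])
  expect_identical(k1$matrix, k2$matrix)
})

test_that("mean-drift mode concentrates each row on the mean next score", {
  obs <- rbind(traj("a", 40:41, c(5, 4)), traj("b", 50:51, c(5, 7)),
               traj("c", 60:61, c(5, 7)))
  k <- estimate_kernel(obs, mode = "mean-drift")
  expect_equal(k$matrix[6, 7], 1)   # mean(4,7,7) = 6
  expect_equal(sum(k$matrix[6, ]), 1)
})

test_that("estimated rows converge to the generating kernel", {
  km <- synthetic_base_kernel()
  rows <- c(0, 3, 10)
  tv_at_n <- sapply(c(100, 1000, 10000), function(nper) {
    set.seed(123)
    obs <- do.call(rbind, lapply(rows, function(s) {
      tos <- sample(0:100, nper, replace = TRUE, prob = km$matrix[s + 1, ])
      data.frame(
        finding_id = rep(sprintf("s%d_%05d", s, seq_len(nper)), each = 2),
        age = rep(c(50, 51), nper),
        risk_score = as.vector(rbind(rep(s, nper), tos))
      )
    }))
    k <- estimate_kernel(obs)
    max(sapply(rows, function(s)
      0.5 * sum(abs(k$matrix[s + 1, ] - km$matrix[s + 1, ]))))
  })
  expect_false(is.unsorted(rev(tv_at_n)))  # TV shrinks as n grows
  expect_lt(tv_at_n[3], 0.05)
})

test_that("kernels round-trip through their delimited-text format", {
  km <- synthetic_base_kernel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_kernel(km, path)
  back <- read_kernel(path)
  expect_lt(max(abs(back$matrix - km$matrix)), 1e-12)
  expect_identical(back$imputed, km$imputed)
})
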