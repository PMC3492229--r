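# Synthetic screening cohort: trajectories with the statistical structure
# the transition-estimation and solver modules assume (truncated-normal
# entry ages, mostly-low scores evolving by a known kernel, multi-year exam
# gaps, single-observation findings, calibrated cancer outcome rate), plus
# synthetic stand-in parameter tables shaped like US life tables and SEER
# survival.

#' Deterministic synthetic base transition kernel
#'
#' The shipped ground-truth kernel: each row is a discretized truncated
#' normal over next-year scores with a mild upward drift at low scores and a
#' heavier, wider upward tail at high scores, so that base-case solves have
#' non-trivial threshold structure. Fully deterministic (no RNG) and
#' versioned with the package.
#'
#' @param drift_intercept,drift_slope Mean next score is
#'   `s + drift_intercept + drift_slope * s`.
#' @param sd_intercept,sd_slope Standard deviation is
#'   `sd_intercept + sd_slope * s`.
#' @return A [transition_kernel()] (101 x 101), `support_counts` marked `NA`
#'   (the kernel is constructed, not estimated).
#' @export
synthetic_base_kernel <- function(drift_intercept = 0.05, drift_slope = 0.015,
                                  sd_intercept = 1.0, sd_slope = 0.05) {
  scores <- 0:100
  m <- vapply(scores, function(s) {
    w <- dnorm(scores, mean = s + drift_intercept + drift_slope * s,
               sd = sd_intercept + sd_slope * s)
    w[w < 1e-10] <- 0
    w / sum(w)
  }, numeric(101))
  m <- t(m)
  dimnames(m) <- list(from = scores, to = scores)
  transition_kernel(m, mode = "empirical")
}

#' Synthetic parameter tables for the reward model
#'
#' Builds smooth, monotone stand-ins for the model's external inputs, all
#' clearly synthetic:
#' \itemize{
#'   \item `other_cause`: Gompertz-shaped annual all-cause mortality,
#'     `0.002 * exp(0.0778 * (age - 40))` capped at 0.6 (US-life-table
#'     shape: ~0.2% at 40, ~4.5% at 80).
#'   \item `treated_bc_invasive`: annual death probability given invasive
#'     cancer under treatment, rising gently with age
#'     (`0.14 + 0.0013 * (age - 40)`).
#'   \item `invasive_expected_life` / `dcis_expected_life`: post-diagnosis
#'     expected remaining life years, 85% and 97% of the all-cause remaining
#'     life expectancy (SEER shape: cure-inclusive, DCIS prognosis near
#'     normal and never below invasive).
#'   \item `terminal_reward`: remaining life expectancy at the terminal age.
#' }
#' Remaining life expectancy is computed from the mortality curve itself
#' (extended to age 120) with half-cycle credit in the year of death, so the
#' tables are internally consistent and non-increasing in age.
#'
#' @param horizon An [mdp_horizon()].
#' @return A list of four named age vectors plus `terminal_reward`, spanning
#'   `start_age .. terminal_age`.
#' @export
make_fixture_tables <- function(horizon = mdp_horizon()) {
  ages <- horizon$start_age:horizon$terminal_age
  q <- function(a) pmin(0.6, 0.002 * exp(0.0778 * (a - 40)))
  # remaining life expectancy with half-cycle credit, horizon capped at 120
  life_exp <- function(a) {
    yrs <- a:119
    qa <- q(yrs)
    surv <- cumprod(c(1, 1 - qa[-length(qa)]))
    sum(surv * (1 - qa / 2))
  }
  le <- vapply(ages, life_exp, 0)
  tabs <- list(
    other_cause = setNames(q(ages), ages),
    treated_bc_invasive = setNames(0.14 + 0.0013 * (ages - 40), ages),
    invasive_expected_life = setNames(0.85 * le, ages),
    dcis_expected_life = setNames(0.97 * le, ages),
    terminal_reward = life_exp(horizon$terminal_age)
  )
  tabs
}

#' Read fixture tables shipped with the package (or written by
#' [write_fixture_tables()])
#'
#' @param dir Directory holding the four `age,value` CSVs and
#'   `terminal_reward_synthetic.csv`; defaults to the package's `extdata`.
#' @return List in the format of [make_fixture_tables()].
#' @export
read_fixture_tables <- function(dir = system.file("extdata",
                                                  package = "biopsyMDP")) {
  list(
    other_cause = read_age_table(
      file.path(dir, "other_cause_mortality_synthetic.csv")),
    treated_bc_invasive = read_age_table(
      file.path(dir, "treated_bc_mortality_invasive_synthetic.csv")),
    invasive_expected_life = read_age_table(
      file.path(dir, "expected_life_invasive_synthetic.csv")),
    dcis_expected_life = read_age_table(
      file.path(dir, "expected_life_dcis_synthetic.csv")),
    terminal_reward = unname(read_age_table(
      file.path(dir, "terminal_reward_synthetic.csv")))
  )
}

#' @rdname read_fixture_tables
#' @param tables List as returned by [make_fixture_tables()].
#' @export
write_fixture_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_age_table(tables$other_cause,
                  file.path(dir, "other_cause_mortality_synthetic.csv"))
  write_age_table(tables$treated_bc_invasive,
                  file.path(dir, "treated_bc_mortality_invasive_synthetic.csv"))
  write_age_table(tables$invasive_expected_life,
                  file.path(dir, "expected_life_invasive_synthetic.csv"))
  write_age_table(tables$dcis_expected_life,
                  file.path(dir, "expected_life_dcis_synthetic.csv"))
  write_age_table(setNames(tables$terminal_reward, 100),
                  file.path(dir, "terminal_reward_synthetic.csv"))
  invisible(dir)
}

#' Configuration of the synthetic cohort
#'
#' Defaults emulate the summary shape of a representative screening
#' mammography population: entry age Normal(56.5, 12.7) truncated to the
#' horizon, risk scores heavily concentrated below 5, about 2.7 exams per
#' patient including single-exam patients, occasional 2-3 year exam gaps,
#' and a marginal cancer detection rate of 9.7 per 1000 exams.
#'
#' @param n_patients Number of patients (one finding trajectory each).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param entry_age_mean,entry_age_sd Entry-age normal parameters (years).
#' @param age_range Entry ages are clipped into this interval
#'   (default `c(40, 96)` so multi-exam patients stay inside the horizon).
#' @param baseline_score_weights Probability weights over scores 0..100 at
#'   the first exam (default geometric with ratio 0.55: ~88% of mass below 5).
#' @param true_kernel Ground-truth annual [transition_kernel()] driving score
#'   evolution (default [synthetic_base_kernel()]).
#' @param exam_count_probs Distribution of exams per patient over counts
#'   `1..length(exam_count_probs)`; mass at 1 exercises the
#'   single-observation exclusion rule (default mean ~2.7 exams).
#' @param gap_probability Chance that an inter-exam interval is 2-3 years
#'   instead of 1 (exercises interpolation).
#' @param cancer_rate_per_exam Target marginal cancer rate per exam
#'   (default 0.0097).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10000L, seed = 1L,
                          entry_age_mean = 56.5, entry_age_sd = 12.7,
                          age_range = c(40, 96),
                          baseline_score_weights = 0.55^(0:100),
                          true_kernel = synthetic_base_kernel(),
                          exam_count_probs = c(0.25, 0.27, 0.20, 0.13,
                                               0.09, 0.06),
                          gap_probability = 0.25,
                          cancer_rate_per_exam = 0.0097) {
  stopifnot(n_patients >= 1, entry_age_sd > 0,
            length(age_range) == 2L, age_range[1] < age_range[2],
            length(baseline_score_weights) == 101L,
            all(baseline_score_weights >= 0),
            inherits(true_kernel, "transition_kernel"),
            all(exam_count_probs >= 0), sum(exam_count_probs) > 0,
            gap_probability >= 0, gap_probability <= 1,
            cancer_rate_per_exam >= 0, cancer_rate_per_exam <= 1)
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         entry_age_mean = entry_age_mean, entry_age_sd = entry_age_sd,
         age_range = age_range,
         baseline_score_weights =
           baseline_score_weights / sum(baseline_score_weights),
         true_kernel = true_kernel,
         exam_count_probs = exam_count_probs / sum(exam_count_probs),
         gap_probability = gap_probability,
         cancer_rate_per_exam = cancer_rate_per_exam),
    class = "cohort_config"
  )
}

# sample next-year scores for a vector of current scores, by kernel row
sample_next_scores <- function(scores, kernel) {
  nxt <- integer(length(scores))
  for (s in unique(scores)) {
    idx <- which(scores == s)
    nxt[idx] <- sample(0:100, length(idx), replace = TRUE,
                       prob = kernel$matrix[s + 1L, ])
  }
  nxt
}

#' Generate a synthetic screening cohort
#'
#' Per patient: entry age from the truncated (clipped) normal; baseline
#' score from the baseline distribution; latent scores evolve annually by
#' the ground-truth kernel; exams observe the latent score at intervals of
#' 1 year, or 2-3 years with probability `gap_probability` (so that
#' annualization is exercised); a per-exam cancer indicator is drawn with
#' probability proportional to the current score (capped at 1), scaled so
#' the marginal rate matches `cancer_rate_per_exam`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: `trajectories` (data.table
#'   `finding_id`, `age`, `risk_score`; one finding per patient), `outcomes`
#'   (per-exam `cancer` indicator and its generating probability),
#'   `ground_truth` (the config, kernel, and calibrated slope).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients

  entry_age <- pmin(pmax(rnorm(n, config$entry_age_mean, config$entry_age_sd),
                         config$age_range[1]), config$age_range[2])
  n_exams <- sample(seq_along(config$exam_count_probs), n, replace = TRUE,
                    prob = config$exam_count_probs)

  # inter-exam intervals in whole years (0 rows for single-exam patients)
  iv <- data.table::data.table(
    patient = rep(seq_len(n), n_exams - 1L)
  )
  if (nrow(iv)) {
    gap <- runif(nrow(iv)) < config$gap_probability
    iv[, interval := ifelse(gap, sample(2:3, .N, replace = TRUE), 1L)]
    iv[, offset := cumsum(interval), by = patient]
  } else {
    iv[, `:=`(interval = integer(0), offset = integer(0))]
  }

  # latent annual evolution out to each patient's last exam offset
  max_off <- if (nrow(iv)) max(iv$offset) else 0L
  lat <- matrix(NA_integer_, n, max_off + 1L)
  lat[, 1L] <- sample(0:100, n, replace = TRUE,
                      prob = config$baseline_score_weights)
  last_off <- integer(n)
  if (nrow(iv)) {
    lo <- iv[, max(offset), by = patient]
    last_off[lo$patient] <- lo$V1
  }
  if (max_off > 0L) {
    for (t in seq_len(max_off)) {
      active <- which(last_off >= t)
      if (length(active))
        lat[active, t + 1L] <- sample_next_scores(lat[active, t], config$true_kernel)
    }
  }

  exams <- rbind(
    data.table::data.table(patient = seq_len(n), offset = 0L),
    iv[, .(patient, offset)]
  )
  data.table::setorder(exams, patient, offset)
  exams[, `:=`(
    finding_id = sprintf("f%05d", patient),
    age = entry_age[patient] + offset,
    risk_score = lat[cbind(patient, offset + 1L)]
  )]

  # calibrate P(cancer | score) = min(1, beta * score / 100) to the target rate
  sfrac <- exams$risk_score / 100
  target <- config$cancer_rate_per_exam
  if (target > 0) {
    f <- function(beta) mean(pmin(1, beta * sfrac)) - target
    if (f(1e6) < 0)
      stop("unsatisfiable cancer-rate calibration: target rate ", target,
           " exceeds what the score distribution allows")
    beta <- if (f(0) >= 0) 0 else uniroot(f, c(0, 1e6), tol = 1e-12)$root
  } else beta <- 0
  p_cancer <- pmin(1, beta * sfrac)
  exams[, cancer := as.integer(runif(.N) < p_cancer)]
  exams[, p_cancer := p_cancer]

  structure(
    list(
      trajectories = exams[, .(finding_id, age, risk_score)],
      outcomes = exams[, .(finding_id, age, risk_score, p_cancer, cancer)],
      ground_truth = list(config = config, kernel = config$true_kernel,
                          cancer_slope = beta)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tr <- x$trajectories
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d exams (%.2f/patient), cancer rate %.4f\n",
    length(unique(tr$finding_id)), nrow(tr),
    nrow(tr) / length(unique(tr$finding_id)), mean(x$outcomes$cancer)))
  invisible(x)
}
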