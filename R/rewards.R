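# QALY reward construction: biopsy disutility, annual death probabilities,
# half-cycle-corrected intermediate rewards, and post-diagnosis lump sums.

WEEKS_PER_YEAR <- 52

#' Biopsy disutility schedule
#'
#' The time penalty (discomfort, anxiety, complications) of a biopsy,
#' expressed in weeks, anchored at age 40 and growing linearly so that the
#' age-100 disutility equals `factor` times the age-40 value.
#'
#' @param d40_weeks Disutility at age 40, in weeks (base case 2).
#' @param factor Multiplier giving the age-100 disutility as
#'   `factor * d40_weeks` (base case 2, i.e. 4 weeks at age 100).
#' @return An object of class `disutility_schedule`.
#' @export
disutility_schedule <- function(d40_weeks = 2, factor = 2) {
  if (d40_weeks < 0) stop("d40_weeks must be >= 0")
  if (factor <= 0) stop("factor must be > 0")
  structure(list(d40_weeks = d40_weeks, factor = factor),
            class = "disutility_schedule")
}

#' Biopsy disutility at a given age
#'
#' Linear in age between the anchors at 40 and 100:
#' `weeks = d40 + (factor - 1) * d40 * (age - 40) / 60`, returned in years
#' (52 weeks per year).
#'
#' @param age Age(s) in years, 40..100 (vectorized).
#' @param sched A [disutility_schedule()].
#' @return Disutility in years.
#' @export
#' @examples
#' disutility_at(100, disutility_schedule()) * 52  # 4 weeks in the base case
disutility_at <- function(age, sched = disutility_schedule()) {
  stopifnot(inherits(sched, "disutility_schedule"))
  if (any(age < 40 | age > 100)) stop("age outside [40, 100]")
  weeks <- sched$d40_weeks +
    (sched$factor - 1) * sched$d40_weeks * (age - 40) / 60
  weeks / WEEKS_PER_YEAR
}

#' Mortality tables
#'
#' @param other_cause Named numeric vector, age -> annual probability of
#'   death from causes other than breast cancer (US-life-table shaped).
#' @param treated_bc Named numeric vector, age -> annual probability of
#'   breast-cancer death, given cancer is present and treated. The
#'   untreated probability is derived from this via the treatment-effect
#'   factor.
#' @return An object of class `mortality_tables`.
#' @export
mortality_tables <- function(other_cause, treated_bc) {
  for (tab in list(other_cause, treated_bc)) {
    if (is.null(names(tab))) stop("mortality tables must be named by age")
    if (any(tab < 0 | tab > 1)) stop("mortality probabilities outside [0, 1]")
  }
  structure(list(other_cause = other_cause, treated_bc = treated_bc),
            class = "mortality_tables")
}

#' Treatment-effectiveness factor
#'
#' The ratio of untreated to treated breast-cancer mortality (tau >= 1 means
#' treatment reduces mortality). Base case 1.6; sensitivity range 1.2..2.
#'
#' @param tau Positive scalar.
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(tau = 1.6) {
  if (!(is.numeric(tau) && length(tau) == 1L && is.finite(tau) && tau > 0))
    stop("tau must be a positive finite scalar")
  structure(list(tau = tau), class = "treatment_effect")
}

#' Post-diagnosis expected-life tables and invasive fraction
#'
#' @param invasive_expected_life Named numeric vector, age -> expected
#'   post-treatment remaining life years with invasive disease (SEER-shaped).
#' @param dcis_expected_life Same for ductal carcinoma in situ; DCIS prognosis
#'   should dominate invasive at every age.
#' @param pct_invasive Fraction of cancers at diagnosis that are invasive
#'   (base case 0.75; sensitivity range 0.65..0.85).
#' @return An object of class `lump_sum_tables`.
#' @export
lump_sum_tables <- function(invasive_expected_life, dcis_expected_life,
                            pct_invasive = 0.75) {
  for (tab in list(invasive_expected_life, dcis_expected_life)) {
    if (is.null(names(tab))) stop("expected-life tables must be named by age")
    if (any(tab < 0)) stop("expected life must be nonnegative")
    if (is.unsorted(rev(tab))) stop("expected life must be non-increasing in age")
  }
  if (!(pct_invasive >= 0 && pct_invasive <= 1))
    stop("pct_invasive must be in [0, 1]")
  structure(
    list(invasive_expected_life = invasive_expected_life,
         dcis_expected_life = dcis_expected_life,
         pct_invasive = pct_invasive),
    class = "lump_sum_tables"
  )
}

lookup_age <- function(tab, age) {
  v <- tab[as.character(age)]
  if (anyNA(v)) stop("age not covered by table: ", paste(age[is.na(v)], collapse = ", "))
  unname(v)
}

#' Combined annual death probability
#'
#' Untreated breast-cancer mortality is `tau * treated_bc(age)` (capped at 1);
#' a patient in risk state `s` carries cancer with probability `s/100`, so her
#' breast-cancer hazard this year is `(s/100) * m_u(age)`. Other-cause and
#' breast-cancer deaths combine as independent competing risks.
#'
#' @param age Age in years (vectorized with `risk_score`).
#' @param risk_score Integer risk score 0..100, or a cancer probability via
#'   `risk_frac`.
#' @param tables A [mortality_tables()].
#' @param effect A [treatment_effect()].
#' @param risk_frac Optional cancer probability overriding `risk_score / 100`.
#' @return Annual probability of death in \[0, 1\].
#' @export
#' @examples
#' tabs <- mortality_tables(c("50" = 0.01), c("50" = 0.10))
#' annual_death_prob(50, 100, tabs, treatment_effect(1.6))  # 0.1684
annual_death_prob <- function(age, risk_score, tables, effect,
                              risk_frac = NULL) {
  stopifnot(inherits(tables, "mortality_tables"),
            inherits(effect, "treatment_effect"))
  if (is.null(risk_frac)) {
    if (any(risk_score < 0 | risk_score > 100)) stop("risk score out of range")
    risk_frac <- risk_score / 100
  }
  oc <- lookup_age(tables$other_cause, age)
  m_u <- pmin(1, effect$tau * lookup_age(tables$treated_bc, age))
  1 - (1 - oc) * (1 - risk_frac * m_u)
}

#' Half-cycle-corrected intermediate reward
#'
#' One QALY for a year survived; half a QALY for the year in which death
#' occurs (death can occur at any time during the year).
#'
#' @param p_death Annual death probability in \[0, 1\] (vectorized).
#' @return Expected QALYs for the year, in \[0.5, 1\].
#' @export
intermediate_reward <- function(p_death) {
  if (any(p_death < 0 | p_death > 1)) stop("p_death outside [0, 1]")
  (1 - p_death) + 0.5 * p_death
}

#' Intermediate reward of the benign-biopsy year
#'
#' As [intermediate_reward()] but with the biopsy time penalty subtracted.
#' Biopsy is assumed perfect, so a benign result means the patient is
#' cancer-free that year and faces other-cause mortality only.
#'
#' @param age Decision age (must be a decision epoch, i.e. < 100).
#' @param other_cause_p Annual other-cause death probability at `age`.
#' @param sched A [disutility_schedule()].
#' @return Expected QALYs for the benign-biopsy year.
#' @export
benign_biopsy_reward <- function(age, other_cause_p,
                                 sched = disutility_schedule()) {
  if (any(age >= 100)) stop("no decision epoch at or beyond the terminal age")
  intermediate_reward(other_cause_p) - disutility_at(age, sched)
}

#' Post-diagnosis lump-sum reward
#'
#' Expected post-treatment remaining life years on entering the
#' malignant-biopsy state: a `pct_invasive` mixture of the invasive and
#' DCIS expected-life tables at the diagnosis age.
#'
#' @param age Diagnosis age (vectorized).
#' @param lump A [lump_sum_tables()].
#' @return Expected remaining life years (QALYs) granted as a lump sum.
#' @export
lump_sum <- function(age, lump) {
  stopifnot(inherits(lump, "lump_sum_tables"))
  lump$pct_invasive * lookup_age(lump$invasive_expected_life, age) +
    (1 - lump$pct_invasive) * lookup_age(lump$dcis_expected_life, age)
}

#' Full reward specification
#'
#' Assembles the disutility schedule, mortality tables, treatment effect,
#' lump-sum tables and terminal reward into the object consumed by
#' [build_instance()].
#'
#' `mortality$treated_bc` must be the mortality actually faced by a patient
#' whose lesion is malignant; see [base_reward_spec()] for the standard
#' stage-mixture construction from an invasive-disease table.
#'
#' @param disutility A [disutility_schedule()].
#' @param mortality A [mortality_tables()].
#' @param effect A [treatment_effect()].
#' @param lump A [lump_sum_tables()].
#' @param terminal_reward Expected remaining life years at the terminal age,
#'   granted to every alive state irrespective of the final action.
#' @param malignant_disutility Should the biopsy time penalty also be
#'   subtracted from the malignant-branch lump sum? Default `TRUE`: the
#'   procedure's discomfort is incurred regardless of pathology.
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(disutility, mortality, effect, lump, terminal_reward,
                        malignant_disutility = TRUE) {
  stopifnot(inherits(disutility, "disutility_schedule"),
            inherits(mortality, "mortality_tables"),
            inherits(effect, "treatment_effect"),
            inherits(lump, "lump_sum_tables"))
  if (!(is.numeric(terminal_reward) && terminal_reward >= 0))
    stop("terminal_reward must be a nonnegative number")
  structure(
    list(disutility = disutility, mortality = mortality, effect = effect,
         lump = lump, terminal_reward = terminal_reward,
         malignant_disutility = isTRUE(malignant_disutility)),
    class = "reward_spec"
  )
}

#' Standard reward specification from fixture-shaped input tables
#'
#' Builds a [reward_spec()] from an other-cause mortality table, an
#' invasive-disease treated mortality table and the two expected-life tables.
#' The effective treated breast-cancer mortality entering
#' [annual_death_prob()] is the stage mixture
#' `pct_invasive * treated_bc_invasive(age)`: short-term mortality of in-situ
#' disease is taken as zero, so the invasive fraction scales both the hazard
#' of deferring biopsy and the post-diagnosis prognosis.
#'
#' @param tables A list as returned by [make_fixture_tables()] /
#'   [read_fixture_tables()]: `other_cause`, `treated_bc_invasive`,
#'   `invasive_expected_life`, `dcis_expected_life`, `terminal_reward`.
#' @param d40_weeks,factor Disutility anchors (base case 2 weeks, factor 2).
#' @param pct_invasive Invasive fraction at diagnosis (base case 0.75).
#' @param tau Treatment-effectiveness factor (base case 1.6).
#' @param malignant_disutility Passed to [reward_spec()].
#' @return A `reward_spec`.
#' @export
base_reward_spec <- function(tables, d40_weeks = 2, factor = 2,
                             pct_invasive = 0.75, tau = 1.6,
                             malignant_disutility = TRUE) {
  reward_spec(
    disutility = disutility_schedule(d40_weeks, factor),
    mortality = mortality_tables(
      other_cause = tables$other_cause,
      treated_bc = pct_invasive * tables$treated_bc_invasive
    ),
    effect = treatment_effect(tau),
    lump = lump_sum_tables(tables$invasive_expected_life,
                           tables$dcis_expected_life, pct_invasive),
    terminal_reward = tables$terminal_reward,
    malignant_disutility = malignant_disutility
  )
}
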