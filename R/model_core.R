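#' biopsyMDP: optimal breast-biopsy thresholds from a finite-horizon MDP
#'
#' Annual decisions between breast biopsy (BX) and annual mammography (AM)
#' are modelled as a finite-horizon Markov decision process over integer
#' breast-cancer risk scores 0..100, solved by backward induction to
#' maximize quality-adjusted life years (QALYs). See the methods vignette
#' for the model and its assumptions.
#'
#' @import data.table
#' @importFrom stats dnorm rnorm runif uniroot weighted.mean setNames rbinom
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

# Half-up rounding to integer. base::round() rounds half to even, which
# would map an interpolated score of 2.5 to 2; the model's score grid uses
# conventional half-up rounding throughout.
round_half_up <- function(x) floor(x + 0.5)

#' State space of the biopsy MDP
#'
#' 101 integer risk-score states (0..100, the percent probability of breast
#' cancer), a benign-biopsy state, an absorbing malignant-biopsy state and an
#' absorbing death state: 104 states in total.
#'
#' @return An object of class `mdp_state_space` with elements `risk_states`
#'   (integer vector 0:100), `biopsy_benign`, `biopsy_malignant`, `death`
#'   (state labels) and `n_states` (104).
#' @export
#' @examples
#' state_space()$n_states
state_space <- function() {
  ss <- list(
    risk_states = 0:100,
    biopsy_benign = "Biopsy-B",
    biopsy_malignant = "Biopsy-M",
    death = "Death"
  )
  ss$n_states <- length(ss$risk_states) + 3L
  structure(ss, class = "mdp_state_space")
}

#' Available actions
#'
#' Two actions exist in every risk-score state: `"AM"` (annual mammography)
#' and `"BX"` (biopsy). Absorbing states admit no action.
#'
#' @return Character vector `c("AM", "BX")`.
#' @export
mdp_actions <- function() c("AM", "BX")

#' Decision horizon
#'
#' Decisions are made annually from `start_age` through `last_decision_age`;
#' a terminal reward (expected remaining life) is assigned at `terminal_age`,
#' which must be exactly one year after the last decision.
#'
#' @param start_age First decision age in years (default 40).
#' @param last_decision_age Last age at which a decision is made (default 99).
#' @param terminal_age Age at which the terminal reward is granted
#'   (default 100; must equal `last_decision_age + 1`).
#' @return An object of class `mdp_horizon`.
#' @export
#' @examples
#' mdp_horizon()
mdp_horizon <- function(start_age = 40L, last_decision_age = 99L,
                        terminal_age = 100L) {
  start_age <- as.integer(start_age)
  last_decision_age <- as.integer(last_decision_age)
  terminal_age <- as.integer(terminal_age)
  # single-epoch horizons (start == last decision age) are allowed for
  # reduced instances; the standard model uses 40 < 99 < 100
  if (!(start_age <= last_decision_age && last_decision_age < terminal_age))
    stop("invalid horizon: need start_age <= last_decision_age < terminal_age")
  if (terminal_age != last_decision_age + 1L)
    stop("invalid horizon: terminal_age must equal last_decision_age + 1")
  structure(
    list(start_age = start_age, last_decision_age = last_decision_age,
         terminal_age = terminal_age),
    class = "mdp_horizon"
  )
}

#' @export
print.mdp_horizon <- function(x, ...) {
  cat(sprintf("<mdp_horizon> decisions at ages %d..%d, terminal reward at %d\n",
              x$start_age, x$last_decision_age, x$terminal_age))
  invisible(x)
}

#' Outcome probabilities of a (perfect) biopsy
#'
#' Biopsy is assumed to have perfect sensitivity and specificity, and the
#' risk score completely defines current cancer risk, so a patient in risk
#' state `s` moves to the malignant-biopsy state with probability `s/100`
#' and to the benign-biopsy state otherwise.
#'
#' @param risk_score Integer risk score(s) in 0..100 (vectorized).
#' @return A list with numeric elements `p_malignant` and `p_benign`
#'   (each the length of `risk_score`; the two always sum to 1).
#' @export
#' @examples
#' biopsy_branch(5)   # 5% malignant, 95% benign
biopsy_branch <- function(risk_score) {
  if (length(risk_score) == 0L || anyNA(risk_score))
    stop("risk_score must be non-missing")
  if (any(risk_score != as.integer(risk_score)))
    stop("risk_score must be integer-valued")
  if (any(risk_score < 0L | risk_score > 100L))
    stop("risk_score out of range 0..100")
  p_m <- as.numeric(risk_score) / 100
  list(p_malignant = p_m, p_benign = 1 - p_m)
}

#' Convert a model probability of cancer to an integer risk-score state
#'
#' Probabilities from the upstream risk model are mapped onto the 0..100
#' integer grid by half-up rounding to the nearest percent.
#'
#' @param p Probability (or vector of probabilities) in \[0, 1\].
#' @return Integer risk score(s) in 0..100.
#' @export
#' @examples
#' risk_score_from_prob(0.122)  # 12
risk_score_from_prob <- function(p) {
  if (any(p < 0 | p > 1)) stop("probability out of [0, 1]")
  as.integer(round_half_up(100 * p))
}

#' Assemble and validate a complete MDP instance
#'
#' Binds a transition kernel, reward specification and horizon into a single
#' validated instance consumed by [backward_induction()]. Validation failures
#' are rejected, never repaired.
#'
#' @param kernel A `transition_kernel` (see [estimate_kernel()] or
#'   [transition_kernel()]).
#' @param rewards A `reward_spec` (see [reward_spec()]).
#' @param horizon An `mdp_horizon` (default [mdp_horizon()]).
#' @param risk_frac Optional numeric vector giving the cancer probability
#'   carried by each risk state (defaults to `risk_states / 100`). Exposed so
#'   that small test instances can use arbitrary risk fractions.
#' @param discount Per-year discount factor on continuation values
#'   (default 1: QALYs are summed undiscounted).
#' @return An object of class `mdp_instance` with 104 states.
#' @export
build_instance <- function(kernel, rewards, horizon = mdp_horizon(),
                           risk_frac = NULL, discount = 1.0) {
  stopifnot(inherits(horizon, "mdp_horizon"))
  if (!inherits(kernel, "transition_kernel"))
    stop("kernel must be a transition_kernel")
  if (!inherits(rewards, "reward_spec"))
    stop("rewards must be a reward_spec")
  validate_kernel(kernel)
  n <- nrow(kernel$matrix)
  if (is.null(risk_frac)) {
    if (n != 101L)
      stop("kernel must have 101 rows (risk scores 0..100) unless risk_frac is supplied")
    risk_frac <- (0:100) / 100
  }
  if (length(risk_frac) != n || any(risk_frac < 0 | risk_frac > 1))
    stop("risk_frac must be a probability vector of length nrow(kernel)")
  if (!(discount > 0 && discount <= 1)) stop("discount must be in (0, 1]")

  ages <- horizon$start_age:horizon$last_decision_age
  for (tab in c("other_cause", "treated_bc")) {
    miss <- setdiff(ages, as.integer(names(rewards$mortality[[tab]])))
    if (length(miss))
      stop(sprintf("mortality table '%s' missing ages: %s", tab,
                   paste(head(miss, 5), collapse = ", ")))
  }
  for (tab in c("invasive_expected_life", "dcis_expected_life")) {
    miss <- setdiff(ages, as.integer(names(rewards$lump[[tab]])))
    if (length(miss))
      stop(sprintf("lump-sum table '%s' missing ages: %s", tab,
                   paste(head(miss, 5), collapse = ", ")))
  }

  structure(
    list(state_space = state_space(), horizon = horizon, kernel = kernel,
         rewards = rewards, risk_frac = risk_frac, discount = discount),
    class = "mdp_instance"
  )
}

#' @export
print.mdp_instance <- function(x, ...) {
  cat(sprintf(
    "<mdp_instance> %d risk states (+Biopsy-B, Biopsy-M, Death), ages %d..%d\n",
    nrow(x$kernel$matrix), x$horizon$start_age, x$horizon$last_decision_age))
  invisible(x)
}

#' Number of states in an instance (risk states plus Biopsy-B, Biopsy-M, Death)
#' @param mdp An `mdp_instance`.
#' @return Integer state count (104 for the standard model).
#' @export
n_states <- function(mdp) {
  stopifnot(inherits(mdp, "mdp_instance"))
  nrow(mdp$kernel$matrix) + 3L
}
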