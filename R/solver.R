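# Finite-horizon backward induction, fixed-policy evaluation, and
# threshold-curve extraction.

# One-step action values for all risk states at a given age.
# V_next: continuation value per risk state at age + 1.
step_action_values <- function(mdp, age, V_next) {
  rw <- mdp$rewards
  x <- mdp$risk_frac
  oc <- lookup_age(rw$mortality$other_cause, age)
  p <- annual_death_prob(age, NULL, rw$mortality, rw$effect, risk_frac = x)
  cont <- as.vector(mdp$kernel$matrix %*% V_next)
  d <- disutility_at(age, rw$disutility)
  L <- lump_sum(age, rw$lump) - if (rw$malignant_disutility) d else 0

  v_am <- intermediate_reward(p) + (1 - p) * mdp$discount * cont
  v_bx <- x * L +
    (1 - x) * (benign_biopsy_reward(age, oc, rw$disutility) +
                 (1 - oc) * mdp$discount * cont)
  list(AM = v_am, BX = v_bx)
}

#' Solve the MDP by backward induction
#'
#' Solves the Bellman recursion from the last decision age down to the start
#' age. At each age and risk state the value of annual mammography (AM) is
#' the half-cycle-corrected survival reward plus the survival-weighted
#' expected continuation over next-year scores; the value of biopsy (BX)
#' mixes the malignant lump sum and the benign branch (disutility-penalized
#' year plus continuation under other-cause survival) by the state's cancer
#' probability. Ties within `1e-12` resolve to AM, so BX is recorded only
#' where it is strictly better.
#'
#' @param mdp A validated [build_instance()] result.
#' @return A list of class `mdp_solution`:
#'   \describe{
#'     \item{value}{numeric matrix, rows = ages `start..terminal`,
#'       columns = risk states; QALYs-to-go. The terminal row equals the
#'       terminal reward everywhere (value at Death is identically 0 and is
#'       not tabulated).}
#'     \item{policy}{character matrix (`"AM"`/`"BX"`), rows = decision ages,
#'       columns = risk states.}
#'   }
#' @export
backward_induction <- function(mdp) {
  stopifnot(inherits(mdp, "mdp_instance"))
  hz <- mdp$horizon
  ages <- hz$start_age:hz$last_decision_age
  n <- nrow(mdp$kernel$matrix)
  state_names <- rownames(mdp$kernel$matrix)
  if (is.null(state_names)) state_names <- as.character(seq_len(n) - 1L)

  V <- matrix(NA_real_, length(ages) + 1L, n,
              dimnames = list(c(ages, hz$terminal_age), state_names))
  policy <- matrix(NA_character_, length(ages), n,
                   dimnames = list(ages, state_names))
  V[nrow(V), ] <- mdp$rewards$terminal_reward

  for (age in rev(ages)) {
    i <- age - hz$start_age + 1L
    av <- step_action_values(mdp, age, V[i + 1L, ])
    if (any(!is.finite(av$AM)) || any(!is.finite(av$BX)))
      stop("non-finite action value at age ", age)
    take_bx <- av$BX > av$AM + 1e-12
    V[i, ] <- ifelse(take_bx, av$BX, av$AM)
    policy[i, ] <- ifelse(take_bx, "BX", "AM")
  }
  structure(list(value = V, policy = policy, horizon = hz),
            class = "mdp_solution")
}

#' Evaluate a fixed policy
#'
#' Expected QALYs-to-go under a prescribed action for every (age, risk state),
#' with no maximization. Evaluating the optimal policy reproduces the
#' [backward_induction()] value function.
#'
#' @param mdp A validated [build_instance()] result.
#' @param policy Character matrix (`"AM"`/`"BX"`) with one row per decision
#'   age and one column per risk state.
#' @return Value matrix as in [backward_induction()].
#' @export
evaluate_policy <- function(mdp, policy) {
  stopifnot(inherits(mdp, "mdp_instance"))
  hz <- mdp$horizon
  ages <- hz$start_age:hz$last_decision_age
  n <- nrow(mdp$kernel$matrix)
  if (!is.matrix(policy) || nrow(policy) != length(ages) || ncol(policy) != n)
    stop("policy must be a ", length(ages), " x ", n, " action matrix")
  if (any(!policy %in% c("AM", "BX")))
    stop("policy entries must be 'AM' or 'BX'")

  V <- matrix(NA_real_, length(ages) + 1L, n,
              dimnames = list(c(ages, hz$terminal_age),
                              rownames(mdp$kernel$matrix)))
  V[nrow(V), ] <- mdp$rewards$terminal_reward
  for (age in rev(ages)) {
    i <- age - hz$start_age + 1L
    av <- step_action_values(mdp, age, V[i + 1L, ])
    bx <- policy[i, ] == "BX"
    V[i, ] <- ifelse(bx, av$BX, av$AM)
  }
  V
}

#' Extract the age-indexed optimal biopsy threshold
#'
#' For each decision age, the smallest risk score at which BX is optimal
#' (sentinel 101 if biopsy is never optimal at that age). Each age is also
#' checked for control-limit structure — BX optimal for *every* score at or
#' above the threshold. Non-control-limit ages are reported, not repaired.
#'
#' @param policy Policy matrix from [backward_induction()] (or an
#'   `mdp_solution`).
#' @return A data.frame of class `threshold_curve` with columns `age`,
#'   `threshold` (0..101) and `control_limit` (logical).
#' @export
extract_threshold <- function(policy) {
  if (inherits(policy, "mdp_solution")) policy <- policy$policy
  scores <- as.integer(colnames(policy))
  if (anyNA(scores)) scores <- seq_len(ncol(policy)) - 1L
  res <- lapply(seq_len(nrow(policy)), function(i) {
    bx <- policy[i, ] == "BX"
    thr <- if (any(bx)) scores[which(bx)[1L]] else max(scores) + 1L
    cl <- all(bx[scores >= thr])
    data.frame(age = as.integer(rownames(policy)[i]),
               threshold = thr, control_limit = cl)
  })
  out <- do.call(rbind, res)
  class(out) <- c("threshold_curve", class(out))
  out
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat("<threshold_curve>\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
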