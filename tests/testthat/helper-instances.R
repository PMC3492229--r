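# Builders for reduced MDP instances and an independent exhaustive-policy
# oracle used to cross-check backward induction.

# A small random instance: n risk states with arbitrary risk fractions,
# a few decision epochs, random row-stochastic kernel and random tables.
make_small_instance <- function(n_states = 3L, n_epochs = 2L, seed = 1L,
                                zero_rewards = FALSE) {
  set.seed(seed)
  start <- 50L
  horizon <- mdp_horizon(start, start + n_epochs - 1L, start + n_epochs)
  ages <- start:(start + n_epochs)

  m <- matrix(rexp(n_states^2), n_states)
  m <- m / rowSums(m)
  kernel <- transition_kernel(m)

  le <- sort(runif(length(ages), 1, 25), decreasing = TRUE)
  tabs <- list(
    other_cause = setNames(runif(length(ages), 0, 0.1), ages),
    treated_bc = setNames(runif(length(ages), 0, 0.3), ages),
    invasive = setNames(le, ages),
    dcis = setNames(le + runif(length(ages), 0, 3), ages)
  )
  # dcis table must also be non-increasing
  tabs$dcis <- setNames(sort(tabs$dcis, decreasing = TRUE), ages)

  params <- list(
    d40 = runif(1, 0, 3), factor = runif(1, 0.5, 4),
    pct_invasive = runif(1), tau = runif(1, 1, 2),
    terminal_reward = runif(1, 0, 10),
    malignant_disutility = sample(c(TRUE, FALSE), 1)
  )
  if (zero_rewards) {
    tabs$other_cause[] <- 0; tabs$treated_bc[] <- 0
    tabs$invasive[] <- 0; tabs$dcis[] <- 0
    params$d40 <- 0; params$terminal_reward <- 0
  }
  rewards <- reward_spec(
    disutility = disutility_schedule(params$d40, params$factor),
    mortality = mortality_tables(tabs$other_cause, tabs$treated_bc),
    effect = treatment_effect(params$tau),
    lump = lump_sum_tables(tabs$invasive, tabs$dcis, params$pct_invasive),
    terminal_reward = params$terminal_reward,
    malignant_disutility = params$malignant_disutility
  )
  risk_frac <- sort(runif(n_states))
  if (zero_rewards) risk_frac[1] <- 0  # exposes the exact AM/BX tie
  mdp <- build_instance(kernel, rewards, horizon, risk_frac = risk_frac)
  list(mdp = mdp, kernel = m, tabs = tabs, params = params,
       risk_frac = risk_frac, horizon = horizon)
}

# Independent evaluation of one fixed policy: plain scalar recursion over
# epochs and states, formulas re-derived from the model definition.
oracle_policy_value <- function(inst, policy) {
  hz <- inst$horizon
  ages <- hz$start_age:hz$last_decision_age
  n <- length(inst$risk_frac)
  p <- inst$params
  V <- matrix(NA_real_, length(ages) + 1L, n)
  V[length(ages) + 1L, ] <- p$terminal_reward
  for (i in rev(seq_along(ages))) {
    a <- ages[i]
    oc <- inst$tabs$other_cause[[as.character(a)]]
    m_u <- min(1, p$tau * inst$tabs$treated_bc[[as.character(a)]])
    d <- (p$d40 + (p$factor - 1) * p$d40 * (a - 40) / 60) / 52
    L <- p$pct_invasive * inst$tabs$invasive[[as.character(a)]] +
      (1 - p$pct_invasive) * inst$tabs$dcis[[as.character(a)]]
    for (s in seq_len(n)) {
      x <- inst$risk_frac[s]
      cont <- sum(inst$kernel[s, ] * V[i + 1L, ])
      if (policy[i, s] == "AM") {
        pd <- 1 - (1 - oc) * (1 - x * m_u)
        V[i, s] <- (1 - pd) + 0.5 * pd + (1 - pd) * cont
      } else {
        V[i, s] <- x * (L - if (p$malignant_disutility) d else 0) +
          (1 - x) * ((1 - oc) + 0.5 * oc - d + (1 - oc) * cont)
      }
    }
  }
  V
}

# Exhaustive enumeration over all deterministic Markov policies: the
# optimal value at every (age, state) is the policy-wise maximum.
oracle_enumerate <- function(inst) {
  hz <- inst$horizon
  n_epochs <- hz$last_decision_age - hz$start_age + 1L
  n <- length(inst$risk_frac)
  cells <- n_epochs * n
  best <- NULL
  for (code in 0:(2^cells - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(cells)]
    policy <- matrix(ifelse(bits == 1L, "BX", "AM"), n_epochs, n)
    V <- oracle_policy_value(inst, policy)
    best <- if (is.null(best)) V else pmax(best, V)
  }
  best
}
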