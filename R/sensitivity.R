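# Base-case solve and one-way sensitivity sweeps over the four headline
# parameters (biopsy disutility at 40, disutility factor, invasive fraction,
# treatment-effectiveness factor).

BASE_CASE <- list(d40 = 2, factor = 2, pct_invasive = 0.75, tau = 1.6)

SWEEP_RANGES <- list(
  d40 = c(0, 3), factor = c(0.5, 4),
  pct_invasive = c(0.65, 0.85), tau = c(1.2, 2)
)

#' Solve for a threshold curve at given parameter settings
#'
#' Convenience wrapper: builds the reward specification via
#' [base_reward_spec()], assembles the instance, runs
#' [backward_induction()] and extracts the threshold curve.
#'
#' @param kernel A [transition_kernel()] over scores 0..100.
#' @param tables Parameter tables ([make_fixture_tables()] format).
#' @param d40,factor,pct_invasive,tau Model parameters (defaults: base case
#'   2 weeks, 2, 0.75, 1.6).
#' @param horizon An [mdp_horizon()].
#' @return A `threshold_curve` data.frame; the full `mdp_solution` is
#'   attached as attribute `"solution"`.
#' @export
solve_threshold <- function(kernel, tables = make_fixture_tables(),
                            d40 = BASE_CASE$d40, factor = BASE_CASE$factor,
                            pct_invasive = BASE_CASE$pct_invasive,
                            tau = BASE_CASE$tau, horizon = mdp_horizon()) {
  rewards <- base_reward_spec(tables, d40_weeks = d40, factor = factor,
                              pct_invasive = pct_invasive, tau = tau)
  mdp <- build_instance(kernel, rewards, horizon)
  sol <- backward_induction(mdp)
  curve <- extract_threshold(sol)
  attr(curve, "solution") <- sol
  curve
}

#' Base-case threshold curve
#'
#' Solves the MDP at the base-case parameters (biopsy disutility 2 weeks at
#' age 40, disutility factor 2, 75% invasive, treatment-effect factor 1.6).
#'
#' @inheritParams solve_threshold
#' @return A `threshold_curve`.
#' @export
run_base_case <- function(kernel, tables = make_fixture_tables(),
                          horizon = mdp_horizon()) {
  solve_threshold(kernel, tables, horizon = horizon)
}

check_sweep_value <- function(parameter, values) {
  if (any(!is.finite(values)))
    stop("sweep values must be finite")
  bad <- switch(parameter,
    d40 = values < 0,
    factor = values <= 0,
    pct_invasive = values < 0 | values > 1,
    tau = values <= 0
  )
  if (any(bad))
    stop("impossible value(s) for ", parameter, ": ",
         paste(values[bad], collapse = ", "))
  rng <- SWEEP_RANGES[[parameter]]
  outside <- values < rng[1] | values > rng[2]
  if (any(outside))
    warning(sprintf("%s value(s) outside the declared range [%g, %g]: %s",
                    parameter, rng[1], rng[2],
                    paste(values[outside], collapse = ", ")))
  invisible(values)
}

#' One-way sensitivity sweep
#'
#' Solves the MDP once per requested value of a single parameter, holding
#' the other three at base case. The base-case value is always included so
#' every sweep carries its reference curve. Values outside the declared
#' sensitivity range are allowed with a warning (sweeps exist to probe
#' extremes); non-finite or impossible values are rejected.
#'
#' @param parameter One of `"d40"`, `"factor"`, `"pct_invasive"`, `"tau"`.
#' @param values Numeric settings to sweep (base value appended if absent).
#' @inheritParams solve_threshold
#' @return An object of class `sweep_result`: a long data.frame with columns
#'   `parameter`, `value`, `age`, `threshold`, `control_limit`; curves in
#'   value order are in attribute `"curves"`.
#' @export
one_way_sweep <- function(parameter = c("d40", "factor", "pct_invasive", "tau"),
                          values, kernel, tables = make_fixture_tables(),
                          horizon = mdp_horizon()) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop("values must be nonempty")
  check_sweep_value(parameter, values)
  base_val <- BASE_CASE[[parameter]]
  values <- sort(unique(c(values, base_val)))

  curves <- lapply(values, function(v) {
    args <- BASE_CASE
    args[[parameter]] <- v
    solve_threshold(kernel, tables, d40 = args$d40, factor = args$factor,
                    pct_invasive = args$pct_invasive, tau = args$tau,
                    horizon = horizon)
  })
  names(curves) <- values
  long <- do.call(rbind, lapply(seq_along(values), function(i) {
    cbind(parameter = parameter, value = values[i],
          as.data.frame(curves[[i]]))
  }))
  structure(long, curves = curves, class = c("sweep_result", class(long)))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s at values {%s}\n", x$parameter[1],
              paste(unique(x$value), collapse = ", ")))
  invisible(x)
}
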