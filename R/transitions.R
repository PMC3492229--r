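# Empirical estimation of the annual risk-score transition kernel from
# longitudinal finding trajectories: linear-interpolation annualization of
# irregular exam gaps, exclusion of single-observation findings, and
# row-normalized counting of annual score pairs.

N_SCORES <- 101L

#' Construct a validated transition kernel
#'
#' @param matrix 101 x 101 (or n x n for reduced test instances) row-stochastic
#'   matrix; row `i` is the distribution of next-year scores for score `i - 1`.
#' @param support_counts Integer vector of observed annual-transition counts
#'   per from-score (default: unknown, all `NA`).
#' @param imputed Logical vector flagging rows that had no observed support
#'   and were imputed (default: none).
#' @param mode Estimation mode label (`"empirical"` or `"mean-drift"`).
#' @return An object of class `transition_kernel`.
#' @export
transition_kernel <- function(matrix,
                              support_counts = rep(NA_integer_, nrow(matrix)),
                              imputed = rep(FALSE, nrow(matrix)),
                              mode = "empirical") {
  k <- structure(
    list(matrix = matrix, support_counts = support_counts,
         imputed = imputed, mode = mode),
    class = "transition_kernel"
  )
  validate_kernel(k)
  k
}

validate_kernel <- function(kernel, tol = 1e-9) {
  m <- kernel$matrix
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("kernel matrix must be square")
  if (any(m < 0 | m > 1))
    stop("kernel entries outside [0, 1]")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("kernel rows do not sum to 1 (worst deviation %.3g)",
                 max(abs(rs - 1))))
  if (length(kernel$support_counts) != nrow(m) ||
      length(kernel$imputed) != nrow(m))
    stop("support_counts / imputed must have one entry per row")
  invisible(kernel)
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat(sprintf("<transition_kernel> %d x %d (%s), %d imputed row(s)\n",
              nrow(x$matrix), ncol(x$matrix), x$mode, sum(x$imputed)))
  invisible(x)
}

check_observations <- function(obs) {
  obs <- data.table::as.data.table(obs)
  need <- c("finding_id", "age", "risk_score")
  if (!all(need %in% names(obs)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  if (any(obs$risk_score < 0 | obs$risk_score > 100) ||
      any(obs$risk_score != as.integer(obs$risk_score)))
    stop("risk scores must be integers in 0..100")
  obs <- obs[, c("finding_id", "age", "risk_score"), with = FALSE]
  data.table::setorder(obs, finding_id, age)
  same <- obs$finding_id == data.table::shift(obs$finding_id) &
    obs$age == data.table::shift(obs$age)
  if (any(same, na.rm = TRUE))
    stop("duplicate ages within a finding trajectory")
  obs
}

#' Annualize a finding trajectory by linear interpolation
#'
#' Exam gaps longer than one year are filled by linearly interpolating the
#' risk score at (approximately) annual spacing between the observed points,
#' rounding each interpolated score half-up to the nearest integer. A gap of
#' `g` years is split into `max(1, round(g))` equal steps, so observed points
#' are always preserved and already-annual trajectories come back unchanged.
#' For example, scores 1 at age 40 and 5 at age 42 impute a score of 3 at
#' age 41 (linear increase in risk with time).
#'
#' @param obs A data.frame of observations with columns
#'   `finding_id`, `age` (decimal years, strictly increasing within a
#'   finding) and `risk_score` (integer 0..100). One or many findings.
#' @return A data.table in the same format with interpolated rows added and
#'   a logical column `imputed` marking them.
#' @export
#' @examples
#' annualize_trajectory(data.frame(finding_id = "f1",
#'                                 age = c(40, 42), risk_score = c(1, 5)))
annualize_trajectory <- function(obs) {
  obs <- check_observations(obs)
  n <- nrow(obs)
  nxt_same <- c(obs$finding_id[-1L] == obs$finding_id[-n], FALSE)
  pairs <- data.table::data.table(
    finding_id = obs$finding_id[nxt_same],
    a1 = obs$age[nxt_same], s1 = obs$risk_score[nxt_same],
    a2 = obs$age[which(nxt_same) + 1L],
    s2 = obs$risk_score[which(nxt_same) + 1L]
  )
  lasts <- data.table::data.table(
    finding_id = obs$finding_id[!nxt_same],
    age = obs$age[!nxt_same], risk_score = obs$risk_score[!nxt_same],
    imputed = FALSE
  )
  if (nrow(pairs) == 0L) {
    data.table::setorder(lasts, finding_id, age)
    return(lasts[])
  }
  pairs[, k := pmax(1L, as.integer(round_half_up(a2 - a1)))]
  ex <- pairs[rep(seq_len(.N), k)]
  ex[, j := seq_len(.N) - 1L, by = data.table::rleidv(ex, c("finding_id", "a1"))]
  ex[, `:=`(
    age = a1 + j * (a2 - a1) / k,
    risk_score = as.integer(round_half_up(s1 + j * (s2 - s1) / k)),
    imputed = j > 0L
  )]
  out <- rbind(ex[, .(finding_id, age, risk_score, imputed)], lasts)
  data.table::setorder(out, finding_id, age)
  out[]
}

#' Estimate the annual transition kernel from trajectories
#'
#' Single-observation findings are excluded (they contain no transition
#' information); the remaining trajectories are annualized with
#' [annualize_trajectory()]; every consecutive annual score pair
#' `(s_t, s_{t+1})` — observed or imputed — contributes one count to the
#' corresponding kernel cell; rows are normalized to empirical distributions.
#' Scores never observed as a starting state get an imputed self-transition
#' row (flagged in the result, never silently).
#'
#' @param obs Long-format observations (`finding_id`, `age`, `risk_score`),
#'   as read by [read_trajectories()].
#' @param mode `"empirical"` (default): each row is the empirical
#'   distribution over observed next scores. `"mean-drift"`: each observed
#'   row places all mass on the half-up-rounded mean next score — a
#'   deterministic comparison kernel that collapses the stochastic structure.
#' @return A [transition_kernel()] with `support_counts` and `imputed` filled.
#' @export
estimate_kernel <- function(obs, mode = c("empirical", "mean-drift")) {
  mode <- match.arg(mode)
  obs <- check_observations(obs)
  n <- nrow(obs)
  nxt_same <- c(obs$finding_id[-1L] == obs$finding_id[-n], FALSE)
  multi <- obs$finding_id %in% obs$finding_id[nxt_same]
  if (!any(multi))
    stop("no estimable transitions: all trajectories have a single observation")
  ann <- annualize_trajectory(obs[multi])

  m <- nrow(ann)
  pair_start <- c(ann$finding_id[-1L] == ann$finding_id[-m], FALSE)
  from <- ann$risk_score[pair_start]
  to <- ann$risk_score[which(pair_start) + 1L]

  counts <- matrix(0, N_SCORES, N_SCORES,
                   dimnames = list(from = 0:100, to = 0:100))
  tab <- data.table::data.table(from = from, to = to)[, .N, by = .(from, to)]
  counts[cbind(tab$from + 1L, tab$to + 1L)] <- tab$N

  support <- as.integer(rowSums(counts))
  mat <- matrix(0, N_SCORES, N_SCORES, dimnames = dimnames(counts))
  observed <- support > 0L
  if (mode == "empirical") {
    mat[observed, ] <- counts[observed, , drop = FALSE] / support[observed]
  } else {
    for (i in which(observed)) {
      mval <- round_half_up(weighted.mean(0:100, counts[i, ]))
      mat[i, mval + 1L] <- 1
    }
  }
  # zero-support rows: score persists (explicit, flagged imputation)
  imputed <- !observed
  mat[cbind(which(imputed), which(imputed))] <- 1
  transition_kernel(mat, support_counts = support, imputed = imputed,
                    mode = mode)
}
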