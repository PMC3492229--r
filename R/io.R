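# Delimited-text I/O: trajectories, kernels, age-value tables, and
# plain-text instance serialization. All numeric output is written with
# enough digits to round-trip doubles exactly.

fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%.0f", x), sprintf("%.17g", x))
}

#' Read / write finding trajectories
#'
#' Dialect: headered delimited text with columns `finding_id,age,risk_score`,
#' one row per observation.
#'
#' @param path File path.
#' @return `read_trajectories()`: a data.table of observations.
#' @export
read_trajectories <- function(path) {
  obs <- data.table::fread(path)
  check_observations(obs)
}

#' @rdname read_trajectories
#' @param obs Observation table (`finding_id`, `age`, `risk_score`).
#' @export
write_trajectories <- function(obs, path) {
  obs <- data.table::as.data.table(obs)[, .(finding_id, age, risk_score)]
  data.table::fwrite(obs, path)
  invisible(path)
}

#' Read / write a transition kernel
#'
#' The kernel is stored sparsely as `from_score,to_score,probability` (zero
#' cells omitted); support counts go to a sidecar file
#' `from_score,support_count,imputed`.
#'
#' @param path Kernel file path.
#' @param support_path Sidecar path (default: `<path>` with `_support`
#'   inserted before the extension).
#' @return `read_kernel()`: a [transition_kernel()].
#' @export
read_kernel <- function(path, support_path = default_support_path(path)) {
  dt <- data.table::fread(path)
  n <- max(dt$from_score, dt$to_score) + 1L
  n <- max(n, 101L)
  m <- matrix(0, n, n, dimnames = list(from = 0:(n - 1L), to = 0:(n - 1L)))
  m[cbind(dt$from_score + 1L, dt$to_score + 1L)] <- dt$probability
  support <- rep(NA_integer_, n)
  imputed <- rep(FALSE, n)
  if (file.exists(support_path)) {
    sc <- data.table::fread(support_path)
    support[sc$from_score + 1L] <- sc$support_count
    imputed[sc$from_score + 1L] <- as.logical(sc$imputed)
  }
  transition_kernel(m, support_counts = support, imputed = imputed)
}

default_support_path <- function(path) {
  sub("(\\.[^.]+)?$", "_support\\1", path)
}

#' @rdname read_kernel
#' @param kernel A [transition_kernel()].
#' @export
write_kernel <- function(kernel, path,
                         support_path = default_support_path(path)) {
  m <- kernel$matrix
  nz <- which(m > 0, arr.ind = TRUE)
  dt <- data.table::data.table(
    from_score = nz[, 1L] - 1L, to_score = nz[, 2L] - 1L,
    probability = fmt_num(m[nz])
  )
  data.table::setorder(dt, from_score, to_score)
  data.table::fwrite(dt, path, quote = FALSE)
  sc <- data.table::data.table(
    from_score = seq_len(nrow(m)) - 1L,
    support_count = kernel$support_counts,
    imputed = kernel$imputed
  )
  data.table::fwrite(sc, support_path, quote = FALSE)
  invisible(path)
}

#' Read / write an age-indexed table
#'
#' Dialect: headered delimited text `age,value`.
#'
#' @param path File path.
#' @return `read_age_table()`: named numeric vector (names are ages).
#' @export
read_age_table <- function(path) {
  dt <- data.table::fread(path)
  setNames(dt$value, dt$age)
}

#' @rdname read_age_table
#' @param tab Named numeric vector (names are ages).
#' @export
write_age_table <- function(tab, path) {
  dt <- data.table::data.table(age = as.integer(names(tab)),
                               value = fmt_num(unname(tab)))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a full MDP instance
#'
#' `write_instance()` writes a plain-text `instance.cfg` (key: value) naming
#' the horizon, scalar reward parameters and the relative paths of the kernel
#' and reward tables, all stored as delimited text in `dir`.
#' `read_instance()` reconstructs the instance; integer fields round-trip
#' exactly and probabilities to double precision.
#'
#' @param mdp An `mdp_instance`.
#' @param dir Output directory (created if needed).
#' @return `read_instance()`: an `mdp_instance`.
#' @export
write_instance <- function(mdp, dir) {
  stopifnot(inherits(mdp, "mdp_instance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rw <- mdp$rewards
  write_kernel(mdp$kernel, file.path(dir, "kernel.csv"))
  write_age_table(rw$mortality$other_cause, file.path(dir, "other_cause.csv"))
  write_age_table(rw$mortality$treated_bc, file.path(dir, "treated_bc.csv"))
  write_age_table(rw$lump$invasive_expected_life,
                  file.path(dir, "invasive_expected_life.csv"))
  write_age_table(rw$lump$dcis_expected_life,
                  file.path(dir, "dcis_expected_life.csv"))
  cfg <- c(
    start_age = mdp$horizon$start_age,
    last_decision_age = mdp$horizon$last_decision_age,
    terminal_age = mdp$horizon$terminal_age,
    discount = fmt_num(mdp$discount),
    d40_weeks = fmt_num(rw$disutility$d40_weeks),
    disutility_factor = fmt_num(rw$disutility$factor),
    tau = fmt_num(rw$effect$tau),
    pct_invasive = fmt_num(rw$lump$pct_invasive),
    terminal_reward = fmt_num(rw$terminal_reward),
    malignant_disutility = rw$malignant_disutility,
    kernel_file = "kernel.csv",
    other_cause_file = "other_cause.csv",
    treated_bc_file = "treated_bc.csv",
    invasive_expected_life_file = "invasive_expected_life.csv",
    dcis_expected_life_file = "dcis_expected_life.csv"
  )
  writeLines(paste0(names(cfg), ": ", cfg), file.path(dir, "instance.cfg"))
  invisible(dir)
}

#' @rdname write_instance
#' @export
read_instance <- function(dir) {
  lines <- readLines(file.path(dir, "instance.cfg"))
  kv <- regmatches(lines, regexec("^([^:]+): (.*)$", lines))
  cfg <- setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  horizon <- mdp_horizon(as.integer(cfg["start_age"]),
                         as.integer(cfg["last_decision_age"]),
                         as.integer(cfg["terminal_age"]))
  kernel <- read_kernel(file.path(dir, cfg["kernel_file"]))
  rewards <- reward_spec(
    disutility = disutility_schedule(as.numeric(cfg["d40_weeks"]),
                                     as.numeric(cfg["disutility_factor"])),
    mortality = mortality_tables(
      read_age_table(file.path(dir, cfg["other_cause_file"])),
      read_age_table(file.path(dir, cfg["treated_bc_file"]))
    ),
    effect = treatment_effect(as.numeric(cfg["tau"])),
    lump = lump_sum_tables(
      read_age_table(file.path(dir, cfg["invasive_expected_life_file"])),
      read_age_table(file.path(dir, cfg["dcis_expected_life_file"])),
      as.numeric(cfg["pct_invasive"])
    ),
    terminal_reward = as.numeric(cfg["terminal_reward"]),
    malignant_disutility = as.logical(cfg["malignant_disutility"])
  )
  build_instance(kernel, rewards, horizon,
                 discount = as.numeric(cfg["discount"]))
}
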