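# End-to-end pipeline: simulate -> estimate transitions -> solve -> sweep
# -> report, with a machine-readable run manifest. Every artifact is
# headered delimited text; all randomness flows from one top-level seed.

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% 2147483647)
}

# small rolling hash of the serialized configuration (hex string);
# arithmetic stays below 2^38 so doubles carry it exactly
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      force = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param seed Top-level integer seed; per-stage seeds are derived from it.
#' @param n_patients Synthetic cohort size (default 10000).
#' @param simulate Generate the cohort in-run? If `FALSE`, `kernel_file`
#'   must point to an existing kernel CSV.
#' @param kernel_file Optional pre-estimated kernel (used when
#'   `simulate = FALSE`).
#' @param tables Parameter tables (default [make_fixture_tables()]).
#' @param horizon An [mdp_horizon()].
#' @param base Base-case parameter block (`d40`, `factor`, `pct_invasive`,
#'   `tau`).
#' @param sweeps Named list of sweep value vectors (defaults: the declared
#'   sensitivity ranges plus the base values, and factor 1).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 10000L, simulate = TRUE,
                            kernel_file = NULL,
                            tables = make_fixture_tables(),
                            horizon = mdp_horizon(),
                            base = BASE_CASE,
                            sweeps = list(d40 = c(0, 2, 3),
                                          factor = c(0.5, 1, 2, 4),
                                          pct_invasive = c(0.65, 0.75, 0.85),
                                          tau = c(1.2, 1.6, 2))) {
  if (!simulate && is.null(kernel_file))
    stop("configuration error: field 'kernel_file' is required when ",
         "'simulate' is FALSE")
  if (!is.null(kernel_file) && !file.exists(kernel_file))
    stop("configuration error: field 'kernel_file' does not exist: ",
         kernel_file)
  if (!all(c("d40", "factor", "pct_invasive", "tau") %in% names(base)))
    stop("configuration error: field 'base' must name d40, factor, ",
         "pct_invasive, tau")
  if (!all(names(sweeps) %in% names(SWEEP_RANGES)))
    stop("configuration error: unknown sweep parameter(s): ",
         paste(setdiff(names(sweeps), names(SWEEP_RANGES)), collapse = ", "))
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         simulate = isTRUE(simulate), kernel_file = kernel_file,
         tables = tables, horizon = horizon, base = base, sweeps = sweeps),
    class = "pipeline_config"
  )
}

#' Stage-at-diagnosis percentages from registry counts
#'
#' Early-stage (stage 0 or 1) and node-positive percentages among staged
#' cancers, reported to one decimal place as in registry summaries.
#'
#' @param n_early Count of early-stage (stage 0/1) cancers.
#' @param n_node_positive Count with lymph-node metastasis.
#' @param n_staged Total cancers with staging information.
#' @return List with `pct_early` and `pct_node_positive` (percentages).
#' @export
#' @examples
#' stage_distribution(300, 108, 417)  # 71.9% early, 25.9% node-positive
stage_distribution <- function(n_early, n_node_positive, n_staged) {
  stopifnot(n_staged > 0, n_early >= 0, n_node_positive >= 0,
            n_early <= n_staged, n_node_positive <= n_staged)
  list(pct_early = round(100 * n_early / n_staged, 1),
       pct_node_positive = round(100 * n_node_positive / n_staged, 1))
}

threshold_band_summary <- function(curve) {
  bands <- list("<42" = curve$age < 42,
                "42-75" = curve$age >= 42 & curve$age <= 75,
                ">75" = curve$age > 75)
  do.call(rbind, lapply(names(bands), function(b) {
    thr <- curve$threshold[bands[[b]]]
    fin <- thr[thr <= 100]
    data.frame(band = b,
               min_threshold = if (length(fin)) min(fin) else NA_integer_,
               max_threshold = if (length(fin)) max(fin) else NA_integer_,
               ages_without_biopsy = sum(thr > 100))
  }))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> estimate-transitions -> solve -> sweep ->
#' report, writing every artifact under `out_dir` and finishing with
#' `manifest.json` (config hash, seed, stage status, file list). Any stage
#' failure aborts with a stage-tagged error after writing a manifest that
#' marks the run incomplete.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_meta <- list(seed = config$seed, n_patients = config$n_patients,
                   simulate = config$simulate, base = config$base,
                   sweeps = config$sweeps,
                   horizon = unclass(config$horizon))
  manifest <- list(config = cfg_meta, config_hash = config_hash(cfg_meta),
                   seed = config$seed, stages = list(), files = character(),
                   complete = FALSE)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  add_file <- function(...) manifest$files <<- c(manifest$files, c(...))
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- "failed"
      write_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  # -- simulate ------------------------------------------------------------
  kernel <- run_stage("simulate", function() {
    if (config$simulate) {
      cohort <- generate_cohort(cohort_config(
        n_patients = config$n_patients,
        seed = derive_seed(config$seed, 1L)))
      write_trajectories(cohort$trajectories,
                         file.path(out_dir, "trajectories.csv"))
      data.table::fwrite(cohort$outcomes, file.path(out_dir, "outcomes.csv"))
      write_kernel(cohort$ground_truth$kernel,
                   file.path(out_dir, "true_kernel.csv"))
      add_file("trajectories.csv", "outcomes.csv", "true_kernel.csv",
               "true_kernel_support.csv")
      NULL
    } else NULL
  })

  # -- estimate-transitions -------------------------------------------------
  kernel <- run_stage("estimate_transitions", function() {
    if (config$simulate) {
      obs <- read_trajectories(file.path(out_dir, "trajectories.csv"))
      k <- estimate_kernel(obs)
    } else {
      k <- read_kernel(config$kernel_file)
    }
    write_kernel(k, file.path(out_dir, "kernel.csv"))
    add_file("kernel.csv", "kernel_support.csv")
    k
  })

  # -- solve ----------------------------------------------------------------
  curve <- run_stage("solve", function() {
    b <- config$base
    curve <- solve_threshold(kernel, config$tables, d40 = b$d40,
                             factor = b$factor,
                             pct_invasive = b$pct_invasive, tau = b$tau,
                             horizon = config$horizon)
    sol <- attr(curve, "solution")
    pol <- data.table::data.table(
      age = as.integer(rep(rownames(sol$policy), ncol(sol$policy))),
      risk_score = as.integer(rep(colnames(sol$policy),
                                  each = nrow(sol$policy))),
      action = as.vector(sol$policy))
    data.table::setorder(pol, age, risk_score)
    data.table::fwrite(pol, file.path(out_dir, "policy.csv"))
    val <- data.table::data.table(
      age = as.integer(rep(rownames(sol$value), ncol(sol$value))),
      state = as.integer(rep(colnames(sol$value), each = nrow(sol$value))),
      qalys = as.vector(sol$value))
    data.table::setorder(val, age, state)
    data.table::fwrite(val, file.path(out_dir, "value.csv"))
    data.table::fwrite(as.data.frame(curve),
                       file.path(out_dir, "threshold_curve.csv"))
    add_file("policy.csv", "value.csv", "threshold_curve.csv")
    curve
  })

  # -- sweep ----------------------------------------------------------------
  sweeps <- run_stage("sweep", function() {
    out <- list()
    for (param in names(config$sweeps)) {
      sw <- one_way_sweep(param, config$sweeps[[param]], kernel,
                          config$tables, horizon = config$horizon)
      for (v in unique(sw$value)) {
        f <- sprintf("threshold_curve_%s_%g.csv", param, v)
        data.table::fwrite(as.data.frame(attr(sw, "curves")[[as.character(v)]]),
                           file.path(out_dir, f))
        add_file(f)
      }
      out[[param]] <- sw
    }
    combined <- do.call(rbind, lapply(out, as.data.frame))
    data.table::fwrite(combined, file.path(out_dir, "sweeps_long.csv"))
    add_file("sweeps_long.csv")
    out
  })

  # -- report ---------------------------------------------------------------
  run_stage("report", function() {
    bands <- threshold_band_summary(curve)
    lines <- c(
      "# Optimal biopsy threshold report", "",
      sprintf("Config hash: %s; seed: %d", manifest$config_hash, config$seed),
      "",
      "## Base-case threshold by age band", "",
      "| Age band | Min threshold (%) | Max threshold (%) | Ages with no biopsy |",
      "|---|---|---|---|",
      sprintf("| %s | %s | %s | %d |", bands$band, bands$min_threshold,
              bands$max_threshold, bands$ages_without_biopsy),
      "",
      "## Sensitivity sweeps", "",
      sprintf("- %s: values {%s}", names(sweeps),
              vapply(sweeps, function(s) paste(unique(s$value), collapse = ", "),
                     "")),
      ""
    )
    writeLines(lines, file.path(out_dir, "report.md"))
    add_file("report.md")
    NULL
  })

  manifest$complete <- TRUE
  write_manifest()
  invisible(manifest)
}
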