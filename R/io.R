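#' Load a run configuration from a YAML file
#'
#' A run configuration is a YAML document with up to six sections —
#' `cohort`, `fractions`, `calibration`, `scenarios`, `sensitivity`,
#' `output` — all optional; documented defaults fill every omission
#' (cohort of 678,243 persons simulated from age 6 to 15, fractions
#' calibrated to the published base-case endpoints, the four national
#' scenarios, a +/-10% sensitivity analysis with 1000 runs). The schema is
#' strict: unknown keys are rejected by name, as are out-of-range values.
#'
#' @param path Path to the YAML file.
#' @return An object of class `run_config`: a named list with the six
#'   sections fully populated.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(raw)) raw <- list()
  build_run_config(raw)
}

# Validate a raw config list against the strict schema and fill defaults.
build_run_config <- function(raw) {
  known_sections <- c("cohort", "fractions", "calibration", "scenarios",
                      "sensitivity", "output")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(x, allowed, section) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      stop("unknown key(s) in config: ",
           paste(paste0(section, ".", extra), collapse = ", "), call. = FALSE)
    }
  }
  check_seed <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1 || x %% 1 != 0) {
      stop("config value ", key, " must be an integer seed", call. = FALSE)
    }
    as.integer(x)
  }

  cohort <- raw$cohort %||% list()
  check_keys(cohort, c("total_population", "start_age", "end_age",
                       "initial_allocation"), "cohort")
  cohort <- list(
    total_population = cohort$total_population %||% 678243,
    start_age = cohort$start_age %||% 6,
    end_age = cohort$end_age %||% 15,
    initial_allocation = unlist(cohort$initial_allocation) %||% c(1, 0, 0, 0, 0))

  fractions <- raw$fractions %||% "calibrate"
  if (!identical(fractions, "calibrate")) {
    check_keys(fractions, fraction_names(), "fractions")
    vals <- unlist(fractions)
    bad <- vals < 0 | vals > 1
    if (any(bad)) {
      stop("config value(s) out of [0, 1]: ",
           paste(paste0("fractions.", names(vals)[bad]), collapse = ", "),
           call. = FALSE)
    }
    miss <- setdiff(fraction_names(), names(vals))
    filled <- stats::setNames(numeric(length(miss)), miss)
    fractions <- as.list(c(vals, filled))
  }

  calibration <- raw$calibration %||% list()
  check_keys(calibration, c("targets", "fixed", "tolerance", "restarts",
                            "seed"), "calibration")
  calibration <- list(
    targets = calibration$targets %||% "published",
    fixed = unlist(calibration$fixed) %||%
      c(f_rec_restore = 0, f_rec_endo = 0),
    tolerance = calibration$tolerance %||% 1e-3,
    restarts = calibration$restarts %||% 16,
    seed = check_seed(calibration$seed %||% 1, "calibration.seed"))

  scenarios <- raw$scenarios %||% "moph_default"

  sensitivity <- raw$sensitivity %||% list()
  check_keys(sensitivity, c("relative_range", "n_runs", "seed"), "sensitivity")
  rr <- sensitivity$relative_range %||% 0.10
  if (rr < 0 || rr >= 1) {
    stop("config value out of range: sensitivity.relative_range must be in [0, 1)",
         call. = FALSE)
  }
  sensitivity <- list(relative_range = rr,
                      n_runs = sensitivity$n_runs %||% 1000,
                      seed = check_seed(sensitivity$seed %||% 1,
                                        "sensitivity.seed"))

  output <- raw$output %||% list()
  check_keys(output, c("directory", "formats"), "output")
  output <- list(directory = output$directory %||% "results",
                 formats = unlist(output$formats) %||% c("csv", "json"))

  structure(list(cohort = cohort, fractions = fractions,
                 calibration = calibration, scenarios = scenarios,
                 sensitivity = sensitivity, output = output),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#'
#' Inverse of [load_run_config()]; a write-then-load round trip reproduces
#' the configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  # named vectors must be written as YAML maps, not bare sequences
  out$calibration$fixed <- as.list(out$calibration$fixed)
  if (!identical(out$fractions, "calibrate")) {
    out$fractions <- as.list(unlist(out$fractions))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build the simulation pieces a run configuration describes
#'
#' Resolves a `run_config` into concrete objects: the [sim_config()], the
#' calibration problem (when `fractions: calibrate`), and the scenario
#' list.
#'
#' @param config A `run_config` from [load_run_config()].
#' @return List with `sim_config`, `scenarios`, and either `fractions`
#'   (when given literally) or `calibration_problem`.
#' @export
resolve_run_config <- function(config) {
  sc <- sim_config(config$cohort$total_population, config$cohort$start_age,
                   config$cohort$end_age, config$cohort$initial_allocation)
  scenarios <- config$scenarios
  if (identical(scenarios, "moph_default")) scenarios <- moph_scenarios()
  out <- list(sim_config = sc, scenarios = scenarios)
  if (identical(config$fractions, "calibrate")) {
    targets <- config$calibration$targets
    if (identical(targets, "published")) targets <- base_case_targets()
    out$calibration_problem <- calibration_problem(
      unlist(targets), sc, fixed = config$calibration$fixed,
      tolerance = config$calibration$tolerance)
  } else {
    out$fractions <- as_flow_fractions(config$fractions)
  }
  out
}

#' Write the standard report files
#'
#' Emits the analysis outputs under `outdir`:
#' \itemize{
#'   \item `scenario_report.csv` — the endpoint table in wide layout, one
#'     row per compartment, and per scenario a persons / percent /
#'     percent-change column triple;
#'   \item `sensitivity.csv` — per-scenario Monte-Carlo mean and 95%
#'     interval of the outcome compartment;
#'   \item `trajectories.csv` — long format (`scenario`, `age`,
#'     `compartment`, `persons`);
#'   \item `run_metadata.json` — seeds, package version, fitted fractions
#'     and any extra metadata, for full reproducibility.
#' }
#' Arguments other than `report` may be `NULL` to skip their file.
#'
#' @param report A [scenario_report()] data.frame.
#' @param summary A [run_sensitivity()] summary, or `NULL`.
#' @param trajectories Named list of `caries_trajectory` objects, or `NULL`.
#' @param outdir Output directory (created if absent).
#' @param metadata Named list merged into `run_metadata.json`.
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(report, summary = NULL, trajectories = NULL,
                          outdir = "results", metadata = list()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)

  wide <- report[report$scenario == report$scenario[1],
                 "compartment", drop = FALSE]
  for (nm in unique(report$scenario)) {
    sub <- report[report$scenario == nm, ]
    sub <- sub[match(wide$compartment, sub$compartment), ]
    wide[[paste0(nm, "_persons")]] <- sub$persons
    wide[[paste0(nm, "_percent")]] <- sub$percent
    wide[[paste0(nm, "_pct_change")]] <- sub$pct_change
  }
  f <- file.path(outdir, "scenario_report.csv")
  utils::write.csv(wide, f, row.names = FALSE)
  written <- c(written, f)

  if (!is.null(summary)) {
    f <- file.path(outdir, "sensitivity.csv")
    utils::write.csv(as.data.frame(summary), f, row.names = FALSE)
    written <- c(written, f)
  }

  if (!is.null(trajectories)) {
    long <- do.call(rbind, lapply(names(trajectories), function(nm) {
      tr <- trajectories[[nm]]
      data.frame(scenario = nm,
                 age = rep(tr$age, times = 5),
                 compartment = rep(compartment_names(), each = nrow(tr)),
                 persons = unlist(tr[compartment_names()], use.names = FALSE))
    }))
    f <- file.path(outdir, "trajectories.csv")
    utils::write.csv(long, f, row.names = FALSE)
    written <- c(written, f)
  }

  meta <- c(list(package = "cariesSDM",
                 version = as.character(utils::packageVersion("cariesSDM"))),
            metadata)
  f <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, f)

  invisible(written)
}
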