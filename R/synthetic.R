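#' Draw a random admissible set of flow fractions
#'
#' Samples each fraction uniformly within its range and rejects draws
#' violating the joint constraint `f_restore + f_endo + f_loss <= 1`.
#' Default ranges reflect plausible annual rates for a school-aged cohort:
#' caries development 0.1-0.3, restoration 0.05-0.3, endodontic treatment
#' 0.005-0.05, tooth loss 0.05-0.3, recurrence 0-0.2 per treated stock.
#'
#' @param seed Integer seed.
#' @param ranges Named list of `c(lower, upper)` per fraction (subsets of
#'   \[0, 1\]); point masses (`lower == upper`) are allowed.
#' @return A [flow_fractions()] object satisfying all invariants.
#' @export
sample_fractions <- function(seed,
                             ranges = list(
                               f_dev = c(0.10, 0.30),
                               f_restore = c(0.05, 0.30),
                               f_endo = c(0.005, 0.05),
                               f_loss = c(0.05, 0.30),
                               f_rec_restore = c(0, 0.20),
                               f_rec_endo = c(0, 0.20))) {
  miss <- setdiff(fraction_names(), names(ranges))
  if (length(miss) > 0) {
    stop("ranges missing fractions: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lo <- vapply(ranges[fraction_names()], `[`, numeric(1), 1)
  hi <- vapply(ranges[fraction_names()], `[`, numeric(1), 2)
  if (any(lo < 0) || any(hi > 1) || any(lo > hi)) {
    stop("each range must satisfy 0 <= lower <= upper <= 1", call. = FALSE)
  }
  set.seed(seed)
  max_attempts <- 10000L
  for (attempt in seq_len(max_attempts)) {
    draw <- stats::runif(6, lo, hi)
    names(draw) <- fraction_names()
    if (draw[["f_restore"]] + draw[["f_endo"]] + draw[["f_loss"]] <= 1) {
      return(structure(draw, class = "flow_fractions"))
    }
  }
  stop("infeasible ranges: rejection rate above 99% for the outflow constraint",
       call. = FALSE)
}

#' Generate a synthetic calibration study
#'
#' Simulates the no-intervention base case under known "true" fractions,
#' optionally perturbs the endpoint counts with multiplicative Gaussian
#' noise of a given relative scale, and renormalizes the noised counts to
#' conserve the cohort total. The result stands in for an observed
#' endpoint prevalence table with known ground truth, so calibration can
#' be tested as a parameter-recovery problem. The noise model is a test
#' harness construct — the real survey data informing the published table
#' carry no stated error model.
#'
#' @param true_fractions The generating [flow_fractions()].
#' @param config A [sim_config()].
#' @param noise_sd Relative standard deviation of the multiplicative
#'   Gaussian noise on endpoint counts; 0 gives the exact simulation
#'   endpoint.
#' @param seed Integer seed for the noise draws.
#' @return An object of class `synthetic_study`: list with
#'   `true_fractions`, `config`, `endpoint_table` (named counts summing to
#'   the cohort total), `noise_sd`, `seed`.
#' @export
generate_study <- function(true_fractions, config = sim_config(),
                           noise_sd = 0, seed = 1) {
  true_fractions <- validate_fractions(true_fractions)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  ends <- endpoint_counts(simulate_cohort(config, true_fractions))
  if (noise_sd > 0) {
    set.seed(seed)
    noised <- ends * (1 + stats::rnorm(length(ends), 0, noise_sd))
    noised[noised < 0] <- 0
    ends <- noised * config$total_population / sum(noised)
  }
  structure(list(true_fractions = true_fractions, config = config,
                 endpoint_table = ends, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_study")
}

#' Serialize a synthetic study to JSON
#'
#' @param study A [generate_study()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(study, path) {
  jsonlite::write_json(
    list(true_fractions = as.list(unclass(study$true_fractions)),
         config = list(total_population = study$config$total_population,
                       start_age = study$config$start_age,
                       end_age = study$config$end_age,
                       initial_allocation = study$config$initial_allocation),
         endpoint_table = as.list(study$endpoint_table),
         noise_sd = study$noise_sd,
         seed = study$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a synthetic study from JSON
#'
#' @param path File written by [write_study_json()].
#' @return A `synthetic_study` object.
#' @export
read_study_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    true_fractions = as_flow_fractions(x$true_fractions),
    config = sim_config(x$config$total_population, x$config$start_age,
                        x$config$end_age, x$config$initial_allocation),
    endpoint_table = unlist(x$endpoint_table)[compartment_names()],
    noise_sd = x$noise_sd,
    seed = as.integer(x$seed)),
    class = "synthetic_study")
}
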