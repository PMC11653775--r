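#' Compartment names of the caries model
#'
#' The five stocks, in reporting order: caries-free, untreated caries,
#' restoration, endodontic treatment, missing teeth.
#'
#' @return Character vector of the five compartment names.
#' @export
compartment_names <- function() {
  c("no_caries", "untreated_caries", "restoration", "endodontic",
    "missing_teeth")
}

#' Cohort state at one age
#'
#' A stock state holds the person counts in the five compartments at an
#' integer age. Counts are nonnegative reals (the model is cohort-level,
#' not individual-level, so fractional persons are admissible).
#'
#' @param age Integer age in years.
#' @param no_caries,untreated_caries,restoration,endodontic,missing_teeth
#'   Person counts in each compartment.
#' @return An object of class `stock_state`.
#' @examples
#' stock_state(6, no_caries = 678243)
#' @export
stock_state <- function(age, no_caries = 0, untreated_caries = 0,
                        restoration = 0, endodontic = 0, missing_teeth = 0) {
  structure(
    list(age = as.integer(age),
         counts = c(no_caries = no_caries,
                    untreated_caries = untreated_caries,
                    restoration = restoration,
                    endodontic = endodontic,
                    missing_teeth = missing_teeth)),
    class = "stock_state")
}

#' @export
print.stock_state <- function(x, ...) {
  cat(sprintf("Stock state at age %d (total %.2f persons):\n",
              x$age, sum(x$counts)))
  print(x$counts, ...)
  invisible(x)
}

validate_state <- function(state, total_population = NULL) {
  if (!inherits(state, "stock_state")) stop("not a stock_state", call. = FALSE)
  if (any(!is.finite(state$counts))) {
    stop("stock state contains non-finite counts", call. = FALSE)
  }
  if (any(state$counts < 0)) {
    bad <- names(state$counts)[state$counts < 0]
    stop("negative compartment counts: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(total_population)) {
    rel <- abs(sum(state$counts) - total_population) / total_population
    if (rel > 1e-9) {
      stop(sprintf("conservation violated: compartments sum to %.6f, expected %.6f",
                   sum(state$counts), total_population), call. = FALSE)
    }
  }
  state
}

#' Simulation configuration
#'
#' Describes the cohort and time horizon: total population, start and end
#' ages (annual steps), and the allocation of the cohort across compartments
#' at the start age. The default places the entire cohort in the caries-free
#' compartment at age 6 — the onset of the permanent dentition.
#'
#' @param total_population Cohort size in persons. The default 678,243 is
#'   the Thai birth cohort of 2021 used throughout the reference analysis.
#' @param start_age,end_age Simulation window in integer years (annual
#'   steps; default ages 6 to 15, i.e. nine annual transitions).
#' @param initial_allocation Numeric vector of five proportions (in
#'   compartment order, see [compartment_names()]) summing to 1, applied to
#'   `total_population` at `start_age`. Default: everyone caries-free.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(total_population = 678243, start_age = 6,
                       end_age = 15,
                       initial_allocation = c(1, 0, 0, 0, 0)) {
  if (total_population <= 0) stop("total_population must be positive", call. = FALSE)
  if (start_age >= end_age) stop("start_age must be below end_age", call. = FALSE)
  if ((end_age - start_age) %% 1 != 0) {
    stop("end_age - start_age must be a whole number of annual steps", call. = FALSE)
  }
  if (length(initial_allocation) != 5 || any(initial_allocation < 0) ||
      abs(sum(initial_allocation) - 1) > 1e-9) {
    stop("initial_allocation must be 5 nonnegative proportions summing to 1",
         call. = FALSE)
  }
  structure(list(total_population = total_population,
                 start_age = as.integer(start_age),
                 end_age = as.integer(end_age),
                 initial_allocation = initial_allocation),
            class = "sim_config")
}

#' Initial stock state of a configuration
#'
#' @param config A [sim_config()].
#' @return The `stock_state` at `config$start_age`.
#' @export
initial_state <- function(config) {
  counts <- config$total_population * config$initial_allocation
  names(counts) <- compartment_names()
  structure(list(age = config$start_age, counts = counts),
            class = "stock_state")
}

#' One annual step of the stock-and-flow model
#'
#' Advances the cohort by one year. All six flows are computed from the
#' start-of-year stocks (a discrete Euler update with dt = 1 year):
#' caries development moves persons out of the caries-free stock (reduced
#' by the intervention's adjusted efficacy while an intervention is
#' active); restoration, endodontic treatment, and tooth loss are competing
#' outflows of the untreated-caries stock; recurrent caries returns persons
#' from the two treated stocks to untreated caries. Missing teeth is
#' absorbing.
#'
#' Under the fraction invariants (each in \[0, 1\],
#' `f_restore + f_endo + f_loss <= 1`) the update preserves nonnegativity
#' and conserves the cohort total exactly.
#'
#' @param state A [stock_state()].
#' @param fractions A [flow_fractions()] set.
#' @param efficacy_multiplier Adjusted intervention efficacy as a proportion
#'   in \[0, 1\]; it scales down the caries-development flow. 0 means no
#'   intervention.
#' @return The `stock_state` one year later.
#' @examples
#' s <- stock_state(6, no_caries = 1000)
#' step_state(s, flow_fractions(f_dev = 0.2))
#' @export
step_state <- function(state, fractions, efficacy_multiplier = 0) {
  validate_state(state)
  fractions <- validate_fractions(fractions)
  if (!is.finite(efficacy_multiplier) || efficacy_multiplier < 0 ||
      efficacy_multiplier > 1) {
    stop("efficacy_multiplier must be a proportion in [0, 1]", call. = FALSE)
  }
  k <- state$counts
  f <- unclass(fractions)

  dev   <- f[["f_dev"]] * (1 - efficacy_multiplier) * k[["no_caries"]]
  rest  <- f[["f_restore"]] * k[["untreated_caries"]]
  endo  <- f[["f_endo"]]    * k[["untreated_caries"]]
  loss  <- f[["f_loss"]]    * k[["untreated_caries"]]
  rec_r <- f[["f_rec_restore"]] * k[["restoration"]]
  rec_e <- f[["f_rec_endo"]]    * k[["endodontic"]]

  out <- c(
    no_caries        = k[["no_caries"]] - dev,
    untreated_caries = k[["untreated_caries"]] + dev + rec_r + rec_e -
                       rest - endo - loss,
    restoration      = k[["restoration"]] + rest - rec_r,
    endodontic       = k[["endodontic"]] + endo - rec_e,
    missing_teeth    = k[["missing_teeth"]] + loss)

  # tiny negative values can only arise from floating-point cancellation;
  # anything materially negative means the fraction invariants were bypassed
  if (any(out < -1e-9 * max(sum(k), 1))) {
    stop("internal consistency error: negative compartment after step",
         call. = FALSE)
  }
  out[out < 0] <- 0

  structure(list(age = state$age + 1L, counts = out), class = "stock_state")
}

#' Simulate the cohort trajectory
#'
#' Runs the annual stock-and-flow update from `start_age` to `end_age`.
#' When an intervention is supplied, its adjusted efficacy (as a
#' proportion) multiplies down the caries-development flow for every step
#' whose *starting* age falls inside the intervention's age window; all
#' other steps run unmodified. With the default configuration and the
#' ages-6-to-12 window this is nine steps, seven of them under
#' intervention.
#'
#' @param config A [sim_config()].
#' @param fractions A [flow_fractions()] set.
#' @param intervention An [intervention_spec()] or `NULL` (base case).
#' @return A `caries_trajectory`: a data.frame with one row per age from
#'   `start_age` to `end_age` and columns `age` plus the five compartments.
#' @examples
#' fr <- flow_fractions(f_dev = 0.18, f_restore = 0.12, f_endo = 0.01,
#'                      f_loss = 0.15)
#' traj <- simulate_cohort(sim_config(), fr)
#' tail(traj, 1)
#' @export
simulate_cohort <- function(config, fractions, intervention = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config", call. = FALSE)
  fractions <- validate_fractions(fractions)
  mult <- 0
  window <- c(-Inf, -Inf)
  if (!is.null(intervention)) {
    if (!inherits(intervention, "intervention_spec")) {
      stop("intervention must be an intervention_spec or NULL", call. = FALSE)
    }
    if (intervention$start_age < config$start_age ||
        intervention$end_age > config$end_age) {
      stop("intervention age window must lie within the simulation window",
           call. = FALSE)
    }
    mult <- intervention$adjusted_efficacy_pct / 100
    window <- c(intervention$start_age, intervention$end_age)
  }

  state <- initial_state(config)
  ages <- seq.int(config$start_age, config$end_age)
  rows <- vector("list", length(ages))
  rows[[1]] <- state$counts
  for (i in seq_along(ages)[-1]) {
    m <- if (state$age >= window[1] && state$age <= window[2]) mult else 0
    state <- step_state(state, fractions, m)
    rows[[i]] <- state$counts
  }
  traj <- data.frame(age = ages, do.call(rbind, rows))
  rownames(traj) <- NULL
  class(traj) <- c("caries_trajectory", "data.frame")
  traj
}

#' Endpoint of a trajectory
#'
#' @param trajectory A `caries_trajectory` from [simulate_cohort()].
#' @return Named numeric vector of the five compartment counts at the final
#'   age.
#' @export
endpoint_counts <- function(trajectory) {
  last <- trajectory[nrow(trajectory), compartment_names()]
  stats::setNames(as.numeric(last), compartment_names())
}

#' Closed-form caries-free stock
#'
#' The caries-free compartment has no inflows, so its trajectory admits a
#' closed form: starting from `n0` persons, each annual step multiplies the
#' stock by `1 - f_dev * (1 - multiplier_t)`. This serves as an analytic
#' oracle for the simulated caries-free trace.
#'
#' @param n0 Initial caries-free persons.
#' @param f_dev Annual caries-development fraction.
#' @param multipliers Numeric vector of per-step intervention multipliers
#'   (proportions in \[0, 1\]), one per annual step.
#' @return Caries-free persons after `length(multipliers)` steps.
#' @examples
#' closed_form_no_caries(1000, 0.5, c(0, 0))  # 250
#' @export
closed_form_no_caries <- function(n0, f_dev, multipliers) {
  if (f_dev < 0 || f_dev > 1) stop("f_dev must be in [0, 1]", call. = FALSE)
  if (any(multipliers < 0 | multipliers > 1)) {
    stop("multipliers must be proportions in [0, 1]", call. = FALSE)
  }
  n0 * prod(1 - f_dev * (1 - multipliers))
}
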