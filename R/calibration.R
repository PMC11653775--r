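#' Calibration problem for the flow fractions
#'
#' The annual flow fractions driving the model are not published; they are
#' recovered by fitting the no-intervention endpoint (the compartment
#' counts at the final age) to a target column. With the two
#' recurrent-caries fractions pinned (default 0), the four remaining
#' fractions are exactly identified by the four independent endpoint
#' targets (five compartments minus the conservation constraint).
#'
#' @param targets Named numeric vector of endpoint compartment counts at
#'   `config$end_age`; names must be the five compartments and the counts
#'   must sum to `config$total_population` (conservation), within 0.5
#'   persons to accommodate published rounding.
#' @param config A [sim_config()].
#' @param fixed Named numeric vector pinning a subset of the six fractions;
#'   default fixes both recurrent fractions at 0.
#' @param bounds Named list of `c(lower, upper)` boxes for the free
#'   fractions; defaults to \[0, 1\] for each.
#' @param tolerance Maximum acceptable per-compartment relative residual
#'   for the fit to count as converged. Default 1e-3.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(targets, config = sim_config(),
                                fixed = c(f_rec_restore = 0, f_rec_endo = 0),
                                bounds = NULL, tolerance = 1e-3) {
  miss <- setdiff(compartment_names(), names(targets))
  if (length(miss) > 0) {
    stop("targets missing compartments: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  targets <- targets[compartment_names()]
  if (abs(sum(targets) - config$total_population) > 0.5) {
    stop(sprintf(
      "targets sum to %.1f but the configured cohort is %.1f persons: inconsistent with conservation",
      sum(targets), config$total_population), call. = FALSE)
  }
  bad <- setdiff(names(fixed), fraction_names())
  if (length(bad) > 0) {
    stop("unknown fixed fractions: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(fixed < 0 | fixed > 1)) {
    stop("fixed fraction values must lie in [0, 1]", call. = FALSE)
  }
  free <- setdiff(fraction_names(), names(fixed))
  if (length(free) > 4) {
    stop("at most 4 free fractions are identifiable from the 4 independent endpoint targets; fix ",
         length(free) - 4, " more", call. = FALSE)
  }
  if (is.null(bounds)) bounds <- list()
  for (nm in free) {
    if (is.null(bounds[[nm]])) bounds[[nm]] <- c(0, 1)
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] < 0 || b[2] > 1 || b[1] >= b[2]) {
      stop("bounds for ", nm, " must be a [lower, upper] box inside [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(targets = targets, config = config, fixed = fixed,
                 free = free, bounds = bounds[free], tolerance = tolerance),
            class = "calibration_problem")
}

# Assemble a full fraction set from free values + pinned values.
assemble_fractions <- function(free_values, problem) {
  x <- stats::setNames(numeric(6), fraction_names())
  x[names(problem$fixed)] <- problem$fixed
  x[problem$free] <- free_values
  structure(x, class = "flow_fractions")
}

#' Calibration objective: sum of squared relative endpoint errors
#'
#' Simulates the no-intervention base case under the given fractions and
#' returns the sum over compartments of squared relative errors against
#' the targets. Relative (not absolute) errors keep the small endodontic
#' compartment (about 2% of the cohort) from being swamped by the large
#' ones.
#'
#' @param fractions A [flow_fractions()] set (all six values).
#' @param problem A [calibration_problem()].
#' @return Nonnegative scalar; 0 iff the endpoint matches the targets
#'   exactly.
#' @export
calibration_objective <- function(fractions, problem) {
  fractions <- validate_fractions(fractions)
  traj <- simulate_cohort(problem$config, fractions)
  ends <- endpoint_counts(traj)
  sum(((ends - problem$targets) / problem$targets)^2)
}

# Objective on the unconstrained (logit) scale with a soft penalty for the
# untreated-stock outflow constraint; used internally by the optimizer.
objective_logit <- function(z, problem) {
  lo <- vapply(problem$bounds, `[`, numeric(1), 1)
  hi <- vapply(problem$bounds, `[`, numeric(1), 2)
  v <- lo + (hi - lo) * stats::plogis(z)
  x <- assemble_fractions(v, problem)
  s <- x[["f_restore"]] + x[["f_endo"]] + x[["f_loss"]]
  if (s > 1) return(1e6 * (1 + (s - 1)))
  calibration_objective(x, problem)
}

#' Calibrate the flow fractions to endpoint targets
#'
#' Bounded derivative-free minimization of [calibration_objective()]:
#' multi-start Nelder-Mead on a logit reparameterization of the free
#' fractions (which enforces the per-fraction boxes), with starting points
#' drawn uniformly over the boxes from a seeded generator, a penalty
#' keeping `f_restore + f_endo + f_loss <= 1`, and the best final objective
#' winning (ties broken by the smallest parameter L2 norm).
#'
#' @param problem A [calibration_problem()].
#' @param seed Integer seed for the multi-start draws.
#' @param n_starts Number of random starts (default 16).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `calibration_result` with elements `fitted`
#'   (a full [flow_fractions()] set), `residuals` (per-compartment relative
#'   errors at the fitted endpoint), `objective_value`, `converged` (TRUE
#'   iff the max absolute relative residual is at or below
#'   `problem$tolerance`), and `n_restarts_used`.
#' @examples
#' truth <- flow_fractions(f_dev = 0.2, f_restore = 0.1, f_endo = 0.01,
#'                         f_loss = 0.12)
#' cfg <- sim_config(total_population = 10000)
#' targets <- endpoint_counts(simulate_cohort(cfg, truth))
#' fit <- calibrate_fractions(calibration_problem(targets, cfg), seed = 1)
#' fit$converged
#' @export
calibrate_fractions <- function(problem, seed = 1, n_starts = 16,
                                maxit = 4000) {
  if (!inherits(problem, "calibration_problem")) {
    stop("problem must be a calibration_problem", call. = FALSE)
  }
  p <- length(problem$free)
  lo <- vapply(problem$bounds, `[`, numeric(1), 1)
  hi <- vapply(problem$bounds, `[`, numeric(1), 2)

  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * p, rep(lo, each = n_starts),
                                rep(hi, each = n_starts)),
                   nrow = n_starts)
  # structure-informed extra start: with an all-caries-free initial
  # allocation the caries-free target pins f_dev analytically (the stock
  # has no inflows), which steers clear of the flat high-f_dev region of
  # the objective where the endpoint is ~0 regardless of f_dev
  if ("f_dev" %in% problem$free &&
      problem$config$initial_allocation[1] == 1) {
    steps <- problem$config$end_age - problem$config$start_age
    f_dev0 <- 1 - (problem$targets[["no_caries"]] /
                     problem$config$total_population)^(1 / steps)
    informed <- (lo + hi) / 2
    i_dev <- match("f_dev", problem$free)
    informed[i_dev] <- min(max(f_dev0, lo[i_dev]), hi[i_dev])
    starts <- rbind(starts, informed)
  }
  # keep starting points feasible for the untreated-stock outflow constraint
  for (i in seq_len(nrow(starts))) {
    v <- assemble_fractions(starts[i, ], problem)
    s <- v[["f_restore"]] + v[["f_endo"]] + v[["f_loss"]]
    if (s > 1) {
      scale_idx <- problem$free %in% c("f_restore", "f_endo", "f_loss")
      starts[i, scale_idx] <- starts[i, scale_idx] * 0.99 / s
    }
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    v0 <- pmin(pmax(starts[i, ], lo + 1e-9), hi - 1e-9)
    z0 <- stats::qlogis((v0 - lo) / (hi - lo))
    fit <- stats::optim(z0, objective_logit, problem = problem,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-14))
    # restart from the solution with a fresh simplex until no improvement
    # (guards against premature Nelder-Mead termination)
    for (round in 1:5) {
      refit <- stats::optim(fit$par, objective_logit, problem = problem,
                            method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = 1e-14))
      if (refit$value >= fit$value - 1e-13) { fit <- refit; break }
      fit <- refit
    }
    v <- lo + (hi - lo) * stats::plogis(fit$par)
    cand <- list(values = v, objective = fit$value)
    if (is.null(best) ||
        cand$objective < best$objective - 1e-15 ||
        (abs(cand$objective - best$objective) <= 1e-15 &&
         sum(v^2) < sum(best$values^2))) {
      best <- cand
    }
  }

  fitted <- assemble_fractions(best$values, problem)
  ends <- endpoint_counts(simulate_cohort(problem$config, fitted))
  residuals <- (ends - problem$targets) / problem$targets
  structure(list(fitted = fitted,
                 residuals = residuals,
                 objective_value = best$objective,
                 converged = max(abs(residuals)) <= problem$tolerance,
                 n_restarts_used = n_starts),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration %s (objective %.3e, max |rel. residual| %.3e, %d starts)\n",
              if (x$converged) "converged" else "did NOT converge",
              x$objective_value, max(abs(x$residuals)), x$n_restarts_used))
  print(x$fitted)
  invisible(x)
}
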