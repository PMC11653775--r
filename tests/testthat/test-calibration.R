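test_that("objective is zero at the generating fractions and positive nearby", {
  truth <- flow_fractions(f_dev = 0.2, f_restore = 0.1, f_endo = 0.01,
                          f_loss = 0.12)
  cfg <- tiny_config()
  targets <- endpoint_counts(simulate_cohort(cfg, truth))
  prob <- calibration_problem(targets, cfg)
  expect_equal(calibration_objective(truth, prob), 0)
  # local scan: perturbing f_dev strictly increases the objective
  for (d in c(-0.02, -0.01, 0.01, 0.02)) {
    perturbed <- flow_fractions(f_dev = 0.2 + d, f_restore = 0.1,
                                f_endo = 0.01, f_loss = 0.12)
    expect_gt(calibration_objective(perturbed, prob), 0)
  }
})

test_that("calibration problems reject inconsistent inputs", {
  cfg <- tiny_config()
  bad_targets <- stats::setNames(c(5000, 3000, 1000, 500, 100),
                                 compartment_names())  # sums to 9600
  expect_error(calibration_problem(bad_targets, cfg), "conservation")

  targets <- endpoint_counts(simulate_cohort(cfg, plausible_fractions()))
  expect_error(calibration_problem(targets, cfg, fixed = c(f_dev = 0.2)),
               "at most 4 free")
  expect_error(calibration_problem(targets, cfg, fixed = c(bogus = 0.1)),
               "unknown fixed")
})

test_that("noiseless synthetic targets are recovered within 1e-3", {
  # recurrent fractions fixed at their true values; the 4 free fractions
  # are exactly identified by the 4 independent endpoint targets
  for (seed in c(3, 7, 11)) {
    truth <- sample_fractions(seed)
    cfg <- tiny_config()
    targets <- endpoint_counts(simulate_cohort(cfg, truth))
    prob <- calibration_problem(
      targets, cfg,
      fixed = c(f_rec_restore = truth[["f_rec_restore"]],
                f_rec_endo = truth[["f_rec_endo"]]))
    fit <- calibrate_fractions(prob, seed = 1, n_starts = 6)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$fitted[prob$free] - truth[prob$free])), 1e-3)
  }
})

test_that("calibration is deterministic given problem and seed", {
  truth <- plausible_fractions()
  cfg <- tiny_config()
  targets <- endpoint_counts(simulate_cohort(cfg, truth))
  prob <- calibration_problem(targets, cfg,
                              fixed = c(f_rec_restore = 0.05,
                                        f_rec_endo = 0.05))
  f1 <- calibrate_fractions(prob, seed = 9, n_starts = 4)
  f2 <- calibrate_fractions(prob, seed = 9, n_starts = 4)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$objective_value, f2$objective_value)
})

test_that("infinite tolerance makes any fit count as converged", {
  truth <- plausible_fractions()
  cfg <- tiny_config()
  targets <- endpoint_counts(simulate_cohort(cfg, truth))
  prob <- calibration_problem(targets, cfg, tolerance = Inf,
                              fixed = c(f_rec_restore = 0.05,
                                        f_rec_endo = 0.05))
  fit <- calibrate_fractions(prob, seed = 1, n_starts = 2, maxit = 50)
  expect_true(fit$converged)
})

test_that("fitted caries-development fraction matches its closed form", {
  # with an all-caries-free start the caries-free endpoint alone pins
  # f_dev: target = N0 * (1 - f_dev)^steps
  fit <- published_fit()
  steps <- 9
  expected <- 1 - (base_case_targets()[["no_caries"]] / 678243)^(1 / steps)
  expect_equal(fit$fitted[["f_dev"]], expected, tolerance = 1e-6)
})

test_that("calibration against the published base-case column converges", {
  fit <- published_fit()
  expect_true(fit$converged)
  expect_lte(max(abs(fit$residuals)), 1e-3)
  ends <- endpoint_counts(simulate_cohort(sim_config(), fit$fitted))
  expect_equal(round(ends[["no_caries"]]), 112405)
})
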