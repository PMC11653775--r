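test_that("zero flows leave the state unchanged except for age", {
  s <- stock_state(6, no_caries = 500, untreated_caries = 300,
                   restoration = 100, endodontic = 50, missing_teeth = 50)
  out <- step_state(s, flow_fractions())
  expect_identical(out$counts, s$counts)
  expect_equal(out$age, 7L)
})

test_that("single annual flows follow the start-of-year-stock arithmetic", {
  # caries development alone
  out <- step_state(stock_state(6, no_caries = 1000),
                    flow_fractions(f_dev = 0.2))
  expect_equal(unname(out$counts),
               c(800, 200, 0, 0, 0))

  # restoration outflow vs recurrent-caries inflow, both from the
  # start-of-year stocks: 100 untreated lose 10 to restoration, 40
  # restored return 20 as recurrent caries
  s <- stock_state(8, untreated_caries = 100, restoration = 40)
  out <- step_state(s, flow_fractions(f_restore = 0.1, f_rec_restore = 0.5))
  expect_equal(out$counts[["untreated_caries"]], 110)
  expect_equal(out$counts[["restoration"]], 30)
})

test_that("stepping rejects invalid inputs", {
  s <- stock_state(6, no_caries = 100)
  expect_error(step_state(s, flow_fractions(f_dev = 1.5)), "out of \\[0, 1\\]")
  expect_error(step_state(s, flow_fractions(f_restore = 0.5, f_endo = 0.4,
                                            f_loss = 0.3)),
               "exceeds 1")
  expect_error(step_state(s, flow_fractions(), efficacy_multiplier = 2),
               "proportion")
  neg <- stock_state(6, no_caries = -5)
  expect_error(step_state(neg, flow_fractions()), "negative")
})

test_that("trajectories conserve the cohort and stay nonnegative", {
  for (seed in 1:20) {
    fr <- sample_fractions(seed)
    cfg <- sim_config(total_population = 678243)
    traj <- simulate_cohort(cfg, fr)
    sums <- rowSums(traj[compartment_names()])
    expect_true(all(abs(sums - cfg$total_population) <=
                      1e-9 * cfg$total_population))
    expect_true(all(as.matrix(traj[compartment_names()]) >= 0))
  }
})

test_that("caries-free stock is non-increasing and missing teeth non-decreasing", {
  for (seed in 1:10) {
    fr <- sample_fractions(seed + 100)
    traj <- simulate_cohort(tiny_config(), fr)
    expect_true(all(diff(traj$no_caries) <= 1e-9))
    expect_true(all(diff(traj$missing_teeth) >= -1e-9))
  }
})

test_that("simulated caries-free trace matches the closed-form oracle", {
  cfg <- sim_config()
  interv <- intervention_spec("x", base_efficacy_pct = 50, coverage_pct = 40)
  for (seed in 1:20) {
    fr <- sample_fractions(seed + 200)
    # no intervention: all multipliers zero
    traj <- simulate_cohort(cfg, fr)
    for (k in seq_len(nrow(traj))) {
      expect_equal(traj$no_caries[k],
                   closed_form_no_caries(cfg$total_population,
                                         fr[["f_dev"]],
                                         rep(0, k - 1)),
                   tolerance = 1e-12)
    }
    # with intervention: multiplier active for steps starting at ages 6-12
    traj_i <- simulate_cohort(cfg, fr, interv)
    mult <- ifelse(6:14 >= interv$start_age & 6:14 <= interv$end_age,
                   interv$adjusted_efficacy_pct / 100, 0)
    expect_equal(traj_i$no_caries[nrow(traj_i)],
                 closed_form_no_caries(cfg$total_population, fr[["f_dev"]],
                                       mult),
                 tolerance = 1e-12)
  }
})

test_that("intervention is active for the seven steps starting at ages 6-12", {
  cfg <- sim_config()  # ages 6 to 15: nine annual steps
  fr <- flow_fractions(f_dev = 0.2)
  interv <- intervention_spec("full", base_efficacy_pct = 100,
                              coverage_pct = 100, start_age = 6, end_age = 12)
  traj <- simulate_cohort(cfg, fr, interv)
  # full protection freezes the caries-free stock through the age-12 step;
  # only the two unprotected steps (ages 13 and 14) deplete it
  expect_equal(traj$no_caries[traj$age <= 13], rep(cfg$total_population, 8))
  expect_equal(traj$no_caries[traj$age == 15],
               cfg$total_population * (1 - 0.2)^2)
})

test_that("endpoint caries-free count is monotone in the efficacy multiplier", {
  fr <- plausible_fractions()
  cfg <- tiny_config()
  for (seed in 1:10) {
    set.seed(seed)
    effs <- sort(runif(2, 0, 100))
    ends <- vapply(effs, function(e) {
      iv <- intervention_spec("x", base_efficacy_pct = e, coverage_pct = 100)
      endpoint_counts(simulate_cohort(cfg, fr, iv))[["no_caries"]]
    }, numeric(1))
    expect_true(ends[2] >= ends[1])
  }
})

test_that("simulation is deterministic", {
  fr <- plausible_fractions()
  t1 <- simulate_cohort(sim_config(), fr)
  t2 <- simulate_cohort(sim_config(), fr)
  expect_identical(t1, t2)
})

test_that("malformed intervention windows and configs are rejected", {
  expect_error(sim_config(start_age = 15, end_age = 6), "start_age")
  expect_error(sim_config(initial_allocation = c(0.5, 0.5)), "initial_allocation")
  iv <- intervention_spec("x", 10, 100, start_age = 3, end_age = 12)
  expect_error(simulate_cohort(sim_config(), flow_fractions(), iv),
               "window")
  expect_error(intervention_spec("x", 10, 100, start_age = 12, end_age = 6),
               "malformed")
})
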