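test_that("risk-ratio and coverage arithmetic reproduces the national figures", {
  expect_equal(efficacy_from_rr(0.9), 10)
  expect_equal(efficacy_from_rr(0.29), 71)
  expect_equal(efficacy_from_rr(1), 0)
  expect_error(efficacy_from_rr(1.2), "not protective")

  expect_equal(all_teeth_efficacy(0.82, 71, 0), 58.22)
  expect_equal(round(all_teeth_efficacy(0.82, 71, 0)), 58)
  expect_equal(all_teeth_efficacy(1, 71, 0), 71)
  expect_equal(all_teeth_efficacy(0, 71, 0), 0)

  expect_equal(adjusted_efficacy(10, 92.5), 9.25)
  expect_equal(round(adjusted_efficacy(58, 27), 1), 15.7)
  expect_equal(adjusted_efficacy(60, 33), 19.8)
})

test_that("adjusted efficacy is monotone in both arguments and bounded by base", {
  set.seed(42)
  for (i in 1:20) {
    e <- runif(1, 0, 100); cvg <- runif(1, 0, 100)
    expect_lte(adjusted_efficacy(e, cvg), e)
    expect_gte(adjusted_efficacy(e + 1, cvg), adjusted_efficacy(e, cvg))
    expect_gte(adjusted_efficacy(e, min(cvg + 1, 100)),
               adjusted_efficacy(e, cvg))
  }
})

test_that("the four national scenarios carry the published parameters", {
  sc <- moph_scenarios()
  expect_named(sc, c("base_case", "stb", "sealant", "stb_sealant"))
  expect_equal(sc$base_case$adjusted_efficacy_pct, 0)
  expect_equal(sc$stb$adjusted_efficacy_pct, 9.25)
  expect_equal(round(sc$sealant$adjusted_efficacy_pct, 1), 15.7)
  expect_equal(sc$stb_sealant$adjusted_efficacy_pct, 19.8)
  expect_equal(sc$stb_sealant$base_efficacy_pct, 60)
  for (s in sc) {
    expect_equal(c(s$start_age, s$end_age), c(6L, 12L))
  }
})

test_that("intervention_spec rejects published values inconsistent with the product", {
  expect_error(intervention_spec("x", 10, 92.5, adjusted_efficacy_pct = 12),
               "inconsistent")
  # published rounding within 0.05 points is accepted
  s <- intervention_spec("sealant", 58, 27, adjusted_efficacy_pct = 15.7)
  expect_equal(s$adjusted_efficacy_pct, 15.7)
})

test_that("percent change matches the published worked examples", {
  expect_equal(round(percent_change(153042, 112405), 1), 36.2)
  expect_equal(round(percent_change(257655, 280244), 1), -8.1)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(10, 0), "undefined")
})

test_that("the published endpoint table is conserved column by column", {
  tab <- published_endpoints()
  for (nm in c("base_case", "stb", "sealant", "stb_sealant")) {
    expect_equal(sum(tab[[nm]]), 678243)
  }
  expect_equal(unname(base_case_targets()),
               c(112405, 280244, 119813, 12822, 152959))
})

test_that("scenario report has conserved percentages and zero base-case changes", {
  fr <- plausible_fractions()
  cfg <- tiny_config()
  scens <- moph_scenarios()
  trajs <- lapply(scens, function(s) {
    simulate_cohort(cfg, fr, if (s$adjusted_efficacy_pct > 0) s else NULL)
  })
  rep <- scenario_report(trajs)
  expect_equal(nrow(rep), 20)  # 5 compartments x 4 scenarios
  for (nm in names(scens)) {
    expect_lte(abs(sum(rep$percent[rep$scenario == nm]) - 100), 0.05)
  }
  expect_equal(rep$pct_change[rep$scenario == "base_case"], rep(0, 5))
  expect_error(scenario_report(trajs["stb"]), "base_case")
})

test_that("endpoint caries-free ordering follows adjusted efficacy for any admissible fractions", {
  cfg <- tiny_config()
  scens <- moph_scenarios()
  for (seed in 1:10) {
    fr <- sample_fractions(seed + 300)
    ends <- vapply(scens, function(s) {
      iv <- if (s$adjusted_efficacy_pct > 0) s else NULL
      endpoint_counts(simulate_cohort(cfg, fr, iv))[["no_caries"]]
    }, numeric(1))
    expect_true(ends[["base_case"]] <= ends[["stb"]])
    expect_true(ends[["stb"]] <= ends[["sealant"]])
    expect_true(ends[["sealant"]] <= ends[["stb_sealant"]])
  }
})
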