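test_that("samplers honour their families and parameter constraints", {
  set.seed(5)
  b <- sample_value(list(family = "beta", alpha = 13, beta = 986), n = 2000)
  expect_true(all(b > 0 & b < 1))
  expect_equal(mean(b), 13 / 999, tolerance = 0.1)
  p <- sample_value(list(family = "beta_pert", min = 5270, mode = 15836,
                         max = 26401), n = 2000)
  expect_true(all(p >= 5270 & p <= 26401))
  expect_equal(sample_value(list(family = "beta_pert", min = 7, mode = 7, max = 7)), 7)
  d <- sample_value(list(family = "dirichlet", alpha = c(3, 5, 9)), n = 50)
  expect_equal(rowSums(d), rep(1, 50))
  ln <- sample_value(list(family = "log_normal", base = 2.37, se = 0.46), n = 2000)
  expect_true(all(ln > 0))
  expect_equal(median(ln), 2.37, tolerance = 0.1)
  expect_equal(sample_value(list(family = "fixed", base = 42)), 42)
  expect_error(sample_value(list(family = "beta", alpha = -1, beta = 2)),
               class = "cea_validation_error")
  expect_error(sample_value(list(family = "beta_pert", min = 5, mode = 3, max = 4)),
               class = "cea_validation_error")
  expect_error(sample_value(list(family = "gamma", base = 1)),
               "unknown distribution", class = "cea_validation_error")
})

test_that("parameter-set draws are reproducible and respect bounds", {
  params <- cea_parameters()
  set.seed(123)
  d1 <- sample_parameter_set(params)
  set.seed(123)
  d2 <- sample_parameter_set(params)
  expect_equal(d1$costs, d2$costs)
  expect_equal(d1$utilities, d2$utilities)
  expect_equal(d1$transitions, d2$transitions)
  # utilities stay probabilities; costs non-negative; HRs positive
  set.seed(42)
  for (i in 1:50) {
    d <- sample_parameter_set(params)
    expect_true(all(unclass(d$utilities) >= 0 & unclass(d$utilities) <= 1))
    expect_true(all(d$transitions$death_hr > 0))
    expect_true(d$transitions$recurrence_prob >= 0 &&
                  d$transitions$recurrence_prob <= 1)
    ws <- d$transitions$worse_split
    expect_equal(lengths(ws), c(5, 4, 3, 2, 1, 0))
    for (w in ws[1:5]) expect_equal(sum(w), 1)
  }
})

test_that("range-matched utility draws keep the base mean", {
  params <- cea_parameters()
  row <- params$dist[params$dist$id == "utility_mrs4", ]
  set.seed(8)
  draws <- sample_value(row, n = 1e4)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_equal(mean(draws), 0.30, tolerance = 0.02 / 0.30)
})

test_that("PSA with everything fixed reproduces the deterministic run exactly", {
  cfg <- fixture_base_case()
  params <- all_fixed(cfg$params)
  sg <- cfg$subgroups[[1]]
  det <- run_deterministic(sg, params, cfg$life_table, cfg$settings)
  psa <- run_psa(sg, params, cfg$life_table, cfg$settings, draws = 3,
                 sample_efficacy = FALSE)
  for (col in c("cost_mt", "qaly_mt", "cost_smc", "qaly_smc")) {
    expect_equal(length(unique(psa$draws[[col]])), 1L)
  }
  expect_equal(psa$draws$cost_mt[1],
               det$outcomes$cost[det$outcomes$strategy == "MT_SMC"])
  expect_equal(psa$draws$qaly_smc[1],
               det$outcomes$qaly[det$outcomes$strategy == "SMC"])
  expect_equal(psa$summary$mean[psa$summary$quantity == "delta_qaly"],
               det$econ$delta_qaly)
})

test_that("drawn efficacy vectors are valid mRS distributions", {
  cfg <- fixture_base_case(psa_draws = 30)
  psa <- run_psa(cfg$subgroups[[1]], cfg$params, cfg$life_table, cfg$settings)
  expect_equal(psa$n_draws, 30)
  expect_equal(nrow(psa$draws), 30)
  # per-draw reproducibility: rerunning gives identical results
  psa2 <- run_psa(cfg$subgroups[[1]], cfg$params, cfg$life_table, cfg$settings)
  expect_equal(psa$draws, psa2$draws)
})

test_that("the acceptability curve is the per-draw NMB exceedance fraction", {
  cfg <- fixture_base_case(psa_draws = 80)
  psa <- run_psa(cfg$subgroups[[2]], cfg$params, cfg$life_table, cfg$settings)
  cc <- psa$ceac
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # independent recomputation from the raw draws
  for (i in sample(nrow(cc), 10)) {
    manual <- mean(cc$wtp[i] * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
    expect_equal(cc$probability[i], manual)
  }
  # wtp = 0 reduces to the cost-saving fraction
  expect_equal(ceac(psa, 0)$probability, mean(psa$draws$delta_cost < 0))
  # when every draw gains QALYs the curve converges to 1 as wtp grows
  if (all(psa$draws$delta_qaly > 0)) {
    expect_equal(ceac(psa, 1e9)$probability, 1)
    expect_true(all(diff(cc$probability) >= 0))
  }
  expect_equal(prob_cost_effective(psa, c(5e4, 1e5)),
               c(ceac(psa, 5e4)$probability, ceac(psa, 1e5)$probability))
})

test_that("percentile intervals bracket the mean for the fixture draws", {
  cfg <- fixture_base_case(psa_draws = 80)
  psa <- run_psa(cfg$subgroups[[1]], cfg$params, cfg$life_table, cfg$settings)
  s <- psa$summary
  expect_true(all(s$ci_low <= s$mean & s$mean <= s$ci_high))
})
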