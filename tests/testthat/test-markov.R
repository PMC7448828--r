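test_that("background death probability matches the rate-scale closed form", {
  lt <- flat_life_table(qx = 0.04)
  expect_equal(background_death_prob(70, 0.5, lt, hr = 1),
               1 - 0.96^0.25, tolerance = 1e-12)
  expect_equal(background_death_prob(70, 0.5, lt, hr = 2.37),
               1 - exp(-2.37 * (-log(0.96)) / 4), tolerance = 1e-12)
  expect_equal(background_death_prob(70, 0.5, flat_life_table(qx = 0), hr = 3), 0)
  # sexes mixed on the annual probability before rate conversion
  lt2 <- dplyr::bind_rows(
    tibble::tibble(age = 60:80, sex = "male", qx = 0.06),
    tibble::tibble(age = 60:80, sex = "female", qx = 0.02)
  )
  expect_equal(background_death_prob(70, 0.25, lt2, hr = 1),
               1 - exp(log1p(-(0.25 * 0.06 + 0.75 * 0.02)) / 4),
               tolerance = 1e-12)
  expect_warning(background_death_prob(200, 0.5, lt), "clamping")
})

test_that("post-recurrence outcomes split equally among worse states", {
  tr <- cea_transitions()
  d0 <- recurrence_outcome_distribution(0, tr)
  expect_equal(unname(d0[paste0("mrs", 1:5)]), rep((1 - 0.0513) / 5, 5))
  expect_equal(d0[["dead"]], 0.0513)
  expect_equal(d0[["mrs0"]], 0)
  d3 <- recurrence_outcome_distribution(3, tr)
  expect_equal(unname(d3[c("mrs4", "mrs5")]), rep((1 - 0.0513) / 2, 2))
  d4 <- recurrence_outcome_distribution(4, tr)
  expect_equal(d4[["mrs5"]], 1 - 0.0513)
  # no worse alive state exists for mRS 5: non-fatal recurrences stay put
  d5 <- recurrence_outcome_distribution(5, tr)
  expect_equal(d5[["mrs5"]], 1 - 0.0513)
  expect_equal(sum(d5), 1)
  for (s in 0:5) {
    expect_equal(sum(recurrence_outcome_distribution(s, tr)), 1)
  }
})

test_that("cycle_step is the identity without mortality or recurrence", {
  params <- cea_parameters(transitions = cea_transitions(recurrence_prob = 0))
  state <- setNames(c(0.2, 0.2, 0.2, 0.1, 0.2, 0.1, 0), c(paste0("mrs", 0:5), "dead"))
  out <- cycle_step(state, 70, params, flat_life_table(qx = 0), 0.5,
                    recurrent_cost = 30000, recurrence_utility = 0.4)
  expect_equal(out$state, state)
  expect_equal(out$recurrence, 0)
  # and the accruals are the plain occupancy-weighted sums
  expect_equal(out$cost, sum(state[1:6] * params$costs$longterm_3mo))
  expect_equal(out$qaly, 0.25 * sum(state[1:6] * unclass(params$utilities)))
})

test_that("recurrence deaths accumulate as the single-path product", {
  params <- cea_parameters()
  state <- setNames(c(0, 0, 0, 0, 0, 1, 0), c(paste0("mrs", 0:5), "dead"))
  out <- cycle_step(state, 70, params, flat_life_table(qx = 0), 0.5,
                    recurrent_cost = 30000, recurrence_utility = 0.4)
  expect_equal(out$state[["dead"]], 0.013 * 0.0513, tolerance = 1e-12)
  expect_equal(out$state[["mrs5"]], 1 - 0.013 * 0.0513, tolerance = 1e-12)
})

test_that("run_markov handles degenerate cohorts", {
  params <- cea_parameters()
  settings <- cea_settings()
  lt <- flat_life_table()
  dead <- c(0, 0, 0, 0, 0, 0, 1)
  mk <- run_markov(dead, params, lt, settings, 70, 0.5, 30000, 0.4)
  expect_equal(mk$totals$cost, 0)
  expect_equal(mk$totals$qaly, 0)
  expect_equal(mk$totals$cycles, 0L)
})

test_that("no-death no-recurrence QALYs equal the geometric discount sum", {
  params <- cea_parameters(
    costs = cea_costs(longterm_3mo = setNames(rep(0, 6), paste0("mrs", 0:5))),
    utilities = cea_utilities(setNames(rep(1, 6), paste0("mrs", 0:5))),
    transitions = cea_transitions(recurrence_prob = 0)
  )
  settings <- cea_settings(discount_rate = 0.03)
  lt <- flat_life_table(qx = 0, ages = 18:115)
  init <- c(1, 0, 0, 0, 0, 0, 0)
  mk <- suppressWarnings(
    run_markov(init, params, lt, settings, 70, 0.5, 0, 0)
  )
  # cycles run while age = 70.25 + (k-1)/4 < 110
  K <- sum(70.25 + (seq_len(10000) - 1) * 0.25 < 110)
  analytic <- sum(0.25 * 1.03^(-(0.25 * seq_len(K))))
  expect_equal(mk$totals$cycles, K)
  expect_equal(mk$totals$qaly, analytic, tolerance = 1e-12)
  expect_equal(mk$totals$cost, 0)
})

test_that("cohort trace conserves probability and absorbs into death", {
  set.seed(11)
  lt <- synth_life_table()
  settings <- cea_settings()
  for (i in 1:25) {
    params <- random_params()
    init <- random_mrs()
    mk <- suppressWarnings(
      run_markov(init, params, lt, settings, runif(1, 55, 85), runif(1),
                 runif(1, 2e4, 5e4), runif(1))
    )
    tr <- tidy(mk)
    occ <- as.matrix(tr[, c(paste0("mrs", 0:5), "dead")])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(occ >= -1e-15))
    expect_true(all(diff(tr$dead) >= -1e-12))
  }
})

test_that("higher excess mortality or recurrence weakly lowers lifetime QALYs", {
  lt <- synth_life_table()
  settings <- cea_settings()
  init <- c(0.15, 0.2, 0.2, 0.15, 0.15, 0.15, 0)
  base <- cea_parameters()
  run_q <- function(p) {
    suppressWarnings(
      run_markov(init, p, lt, settings, 70, 0.5, 30000, 0.4, trace = FALSE)
    )$totals$qaly
  }
  q0 <- run_q(base)
  for (s in paste0("death_hr_mrs", c(0, 2, 5))) {
    expect_lte(run_q(set_cea_param(base, s, cea_param_value(base, s) * 1.5)), q0)
  }
  expect_lte(run_q(set_cea_param(base, "recurrence_prob", 0.05)), q0)
})

test_that("discounting can only shrink lifetime totals", {
  lt <- synth_life_table()
  init <- c(0.15, 0.2, 0.2, 0.15, 0.15, 0.15, 0)
  params <- cea_parameters()
  disc <- suppressWarnings(run_markov(init, params, lt, cea_settings(), 70, 0.5,
                                      30000, 0.4, trace = FALSE))$totals
  undisc <- suppressWarnings(run_markov(init, params, lt,
                                        cea_settings(discount_rate = 0), 70, 0.5,
                                        30000, 0.4, trace = FALSE))$totals
  expect_lt(disc$qaly, undisc$qaly)
  expect_lt(disc$cost, undisc$cost)
  expect_equal(disc$qaly_undisc, undisc$qaly)
})

test_that("run_strategy combines acute and long-run phases coherently", {
  params <- cea_parameters()
  settings <- cea_settings()
  lt <- synth_life_table()
  sg <- fixed_subgroup()
  out <- run_strategy(sg, "MT_SMC", params, lt, settings, trace = TRUE)
  tree <- evaluate_decision_tree(sg, params)
  leaf <- tree[tree$strategy == "MT_SMC", ]
  mk <- attr(out, "markov")
  s <- 1 - leaf$mrs6
  expect_equal(out$cost, leaf$cost_90d + s * mk$totals$cost)
  expect_equal(out$qaly, 0.25 * leaf$utility_90d + s * mk$totals$qaly)
  # acute QALY accrual switchable
  no_acute <- cea_settings(include_acute_qaly = FALSE)
  out2 <- run_strategy(sg, "MT_SMC", params, lt, no_acute)
  expect_equal(out$qaly - out2$qaly, 0.25 * leaf$utility_90d)
})

test_that("half-cycle correction removes half of the first cycle's accrual", {
  params <- cea_parameters()
  lt <- synth_life_table()
  init <- c(0.15, 0.2, 0.2, 0.15, 0.15, 0.15, 0)
  plain <- run_markov(init, params, lt, cea_settings(), 76, 0.5, 30000, 0.4)
  hc <- run_markov(init, params, lt, cea_settings(half_cycle = TRUE), 76, 0.5,
                   30000, 0.4)
  first <- plain$trace[1, ]
  expect_equal(plain$totals$cost - hc$totals$cost, 0.5 * first$cost)
  expect_equal(plain$totals$qaly - hc$totals$qaly, 0.5 * first$qaly)
})

test_that("cohort engine agrees with a per-patient microsimulation oracle", {
  # single moderate-size check; the acceptance suite runs the full version
  params <- cea_parameters()
  settings <- cea_settings()
  lt <- synth_life_table()
  init6 <- c(0.1, 0.2, 0.2, 0.2, 0.15, 0.15)
  mk <- suppressWarnings(
    run_markov(c(init6, 0), params, lt, settings, 78, 0.5, 35000, 0.45,
               trace = FALSE)
  )
  ms <- microsim_oracle(init6, params, lt, settings, 78, 0.5, 35000, 0.45,
                        n_patients = 5e4, seed = 99)
  expect_lt(abs(mk$totals$cost - ms$cost), 3 * ms$se_cost)
  expect_lt(abs(mk$totals$qaly - ms$qaly), 3 * ms$se_qaly)
})
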