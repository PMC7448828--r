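test_that("default parameter set carries the literature base-case values", {
  p <- cea_parameters()
  expect_equal(p$transitions$recurrence_prob, 0.013)
  expect_equal(p$transitions$post_recurrence_death, 0.0513)
  expect_equal(unname(p$transitions$death_hr), c(1, 1, 1.11, 1.27, 1.71, 2.37))
  expect_equal(unname(p$costs$imaging), c(198, 774, 625, 1023, 836, 89))
  expect_equal(p$costs$tpa, 8004)
  expect_equal(p$costs$mt_procedure, 15836)
  expect_equal(p$costs$mt_physician, 2749)
  expect_equal(unname(p$costs$acute_90d), c(14382, 17879, 23498))
  expect_equal(unname(p$costs$longterm_3mo),
               c(2836, 2741, 3378, 5801, 11742, 17262))
  expect_equal(unname(unclass(p$utilities)), c(0.85, 0.80, 0.70, 0.51, 0.30, 0.15))
  # every uncertain input appears exactly once in the registry
  expect_equal(anyDuplicated(p$dist$id), 0L)
  expect_equal(nrow(p$dist), 34L)
})

test_that("bundled base-case config loads and matches the defaults", {
  cfg_path <- system.file("extdata", "base_case.yaml", package = "strokecea")
  loaded <- load_parameters(cfg_path)
  ref <- cea_parameters()
  for (id in ref$dist$id) {
    expect_equal(cea_param_value(loaded$params, id), cea_param_value(ref, id),
                 info = id)
  }
  expect_equal(loaded$params$dist, ref$dist)
  expect_equal(loaded$settings$discount_rate, 0.03)
  expect_equal(loaded$settings$cohort_size, 1000)
  expect_equal(loaded$settings$psa_draws, 2000L)
  expect_equal(loaded$trial_defaults$DAWN$prop_male[["MT_SMC"]], 0.393)
  expect_equal(loaded$trial_defaults$DEFUSE3$prop_male[["SMC"]], 0.489)
})

test_that("config round-trips load -> write -> load unchanged", {
  cfg_path <- system.file("extdata", "base_case.yaml", package = "strokecea")
  first <- load_parameters(cfg_path)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_cea_config(first$params, first$settings, tmp,
                   trial_defaults = first$trial_defaults)
  second <- load_parameters(tmp)
  expect_equal(second$params$dist, first$params$dist)
  expect_equal(second$params$costs, first$params$costs)
  expect_equal(second$params$utilities, first$params$utilities)
  expect_equal(second$params$transitions, first$params$transitions)
  expect_equal(unclass(second$settings), unclass(first$settings))
})

test_that("validation errors name the offending field", {
  expect_error(cea_utilities(c(mrs0 = 0.85, mrs1 = 0.8, mrs2 = 1.2, mrs3 = 0.51,
                               mrs4 = 0.3, mrs5 = 0.15)),
               "utility.*\\[0,1\\]", class = "cea_validation_error")
  expect_error(cea_utilities(c(mrs0 = 0.5, mrs1 = 0.8, mrs2 = 0.7, mrs3 = 0.51,
                               mrs4 = 0.3, mrs5 = 0.15)),
               "non-increasing", class = "cea_validation_error")
  expect_error(cea_transitions(recurrence_prob = 1.2), "recurrence_prob",
               class = "cea_validation_error")
  expect_error(cea_transitions(death_hr = c(mrs0 = 1, mrs1 = 1, mrs2 = 1.11,
                                            mrs3 = 1.27, mrs4 = 1.71)),
               "death_hr.*mrs5", class = "cea_validation_error")
  expect_error(set_cea_param(cea_parameters(), "utility_mrs2", 1.2),
               "utility_mrs2", class = "cea_validation_error")
  expect_error(load_parameters("no/such/file.yaml"), "config_path",
               class = "cea_validation_error")
})

test_that("a config missing a required parameter entry fails by name", {
  cfg_path <- system.file("extdata", "base_case.yaml", package = "strokecea")
  cfg <- yaml::read_yaml(cfg_path)
  cfg$parameters$death_hr_mrs5 <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(cfg), tmp)
  expect_error(load_parameters(tmp), "death_hr_mrs5",
               class = "cea_validation_error")
})

test_that("mRS distributions are validated strictly", {
  v <- validate_mrs_distribution(c(0.10, 0.23, 0.18, 0.13, 0.12, 0.09, 0.15))
  expect_equal(sum(v), 1)
  expect_equal(names(v), mrs_cols)
  expect_silent(validate_mrs_distribution(c(1, 0, 0, 0, 0, 0, 0)))
  expect_error(validate_mrs_distribution(rep(0.9 / 7, 7)), "sum to 1",
               class = "cea_validation_error")
  expect_error(validate_mrs_distribution(c(-0.1, 0.3, 0.2, 0.2, 0.2, 0.1, 0.1)),
               "negative", class = "cea_validation_error")
  expect_error(validate_mrs_distribution(rep(0.2, 5)), "7 numeric",
               class = "cea_validation_error")
})

test_that("parameter getter/setter stay in step with the registry", {
  p <- cea_parameters()
  p2 <- set_cea_param(p, "cost_mt_procedure", 20000)
  expect_equal(p2$costs$mt_procedure, 20000)
  expect_equal(p2$dist$base[p2$dist$id == "cost_mt_procedure"], 20000)
  expect_equal(cea_param_value(p2, "cost_mt_procedure"), 20000)
  expect_error(cea_param_value(p, "no_such_param"), "unknown parameter",
               class = "cea_validation_error")
})

test_that("utility PSA betas preserve the base mean and the printed spread", {
  p <- cea_parameters()
  row <- p$dist[p$dist$id == "utility_mrs4", ]
  expect_equal(row$alpha / (row$alpha + row$beta), 0.30, tolerance = 1e-6)
  width <- qbeta(0.975, row$alpha, row$beta) - qbeta(0.025, row$alpha, row$beta)
  expect_equal(width, 0.40 - 0.10, tolerance = 1e-6)
})

test_that("life tables are validated for shape and completeness", {
  lt <- flat_life_table()
  expect_silent(validate_life_table(lt))
  expect_error(validate_life_table(lt[lt$sex == "male", ]), "female",
               class = "cea_validation_error")
  gappy <- lt[!(lt$age == 50 & lt$sex == "male"), ]
  expect_error(validate_life_table(gappy), "contiguous",
               class = "cea_validation_error")
  bad <- lt
  bad$qx[1] <- 1.5
  expect_error(validate_life_table(bad), "qx", class = "cea_validation_error")
})

test_that("subgroup construction enforces its invariants", {
  sg <- fixed_subgroup()
  expect_s3_class(sg, "cea_subgroup")
  expect_setequal(sg$arms$strategy, c("MT_SMC", "SMC"))
  one_arm <- sg$arms[1, ]
  expect_error(cea_subgroup("DEFUSE3", "bad", one_arm), "two arms",
               class = "cea_validation_error")
  old <- sg$arms
  old$mean_age <- 101
  expect_error(cea_subgroup("DEFUSE3", "bad", old), "mean_age",
               class = "cea_validation_error")
  expect_error(cea_subgroup("TRIAL_X", "bad", sg$arms), "trial",
               class = "cea_validation_error")
})

test_that("combined mRS 5/6 rows are split against the reference at build", {
  arms <- fixed_subgroup()$arms
  # fold mrs6 into mrs5, mark combined
  arms$mrs5 <- arms$mrs5 + arms$mrs6
  arms$mrs6 <- NA_real_
  ref <- c(0.1, 0.1, 0.2, 0.2, 0.16, 0.08, 0.16) # p5:p6 = 1:2
  sg <- cea_subgroup("DAWN", "combined", arms, mrs56_reference = ref)
  expect_equal(sg$arms$mrs5 / sg$arms$mrs6, rep(0.5, 2))
  expect_equal(sg$arms$mrs5 + sg$arms$mrs6, arms$mrs5)
  expect_error(cea_subgroup("DAWN", "combined", arms), "mrs56_reference",
               class = "cea_validation_error")
})
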