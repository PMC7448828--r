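# Fixtures built in code; no data files.

mrs_cols <- paste0("mrs", 0:6)

# a plausible pair of 90-day distributions (control worse than intervention)
MT_EFF <- c(0.10, 0.23, 0.18, 0.13, 0.12, 0.09, 0.15)
SMC_EFF <- c(0.02, 0.06, 0.10, 0.15, 0.22, 0.19, 0.26)

fixed_subgroup <- function(trial = "DEFUSE3", label = "fixture",
                           mt = MT_EFF, smc = SMC_EFF,
                           mean_age = 70, n = 100,
                           tpa = c(0.10, 0.10), prop_male = c(0.5, 0.5)) {
  arms <- tibble::tibble(
    strategy = c("MT_SMC", "SMC"),
    mrs0 = c(mt[1], smc[1]), mrs1 = c(mt[2], smc[2]), mrs2 = c(mt[3], smc[3]),
    mrs3 = c(mt[4], smc[4]), mrs4 = c(mt[5], smc[5]), mrs5 = c(mt[6], smc[6]),
    mrs6 = c(mt[7], smc[7]),
    n = n, mean_age = mean_age, tpa_frequency = tpa, prop_male = prop_male
  )
  cea_subgroup(trial, label, arms)
}

flat_life_table <- function(qx = 0.04, ages = 18:115) {
  dplyr::bind_rows(
    tibble::tibble(age = ages, sex = "male", qx = qx),
    tibble::tibble(age = ages, sex = "female", qx = qx)
  )
}

all_fixed <- function(params) {
  params$dist$family <- "fixed"
  params$transitions$split_family <- "fixed"
  params
}

random_mrs <- function() {
  x <- rgamma(7, shape = 1)
  x / sum(x)
}

# random but valid parameter perturbation for property tests
random_params <- function() {
  tr <- cea_transitions(
    recurrence_prob = runif(1, 0, 0.05),
    post_recurrence_death = runif(1, 0, 0.3),
    death_hr = setNames(sort(runif(6, 0.8, 3)), paste0("mrs", 0:5))
  )
  u <- sort(runif(6, 0, 1), decreasing = TRUE)
  cea_parameters(utilities = cea_utilities(setNames(u, paste0("mrs", 0:5))),
                 transitions = tr)
}
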