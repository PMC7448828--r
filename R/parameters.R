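#' Validate a 90-day mRS outcome distribution
#'
#' A 90-day outcome distribution assigns a probability to each modified
#' Rankin Scale level 0..6 (mRS 6 = death). Probabilities must be
#' non-negative and sum to one (within 1e-9).
#'
#' @param p Numeric vector of length 7 (mRS 0..6), optionally named
#'   `mrs0`..`mrs6`.
#' @param field Label used in error messages.
#' @return The validated distribution as a named numeric vector.
#' @examples
#' validate_mrs_distribution(c(0.10, 0.23, 0.18, 0.13, 0.12, 0.09, 0.15))
#' @export
validate_mrs_distribution <- function(p, field = "mrs_distribution") {
  p <- unlist(p, use.names = FALSE)
  if (length(p) != 7 || anyNA(p) || !is.numeric(p)) {
    abort_validation(field, "must be 7 numeric probabilities (mRS 0..6)")
  }
  if (any(p < 0)) {
    abort_validation(field, "has a negative entry")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort_validation(field, sprintf("must sum to 1 (got %.10f)", sum(p)))
  }
  stats::setNames(as.numeric(p), MRS_ALL)
}

#' Cost inputs for the acute decision tree and the Markov model
#'
#' Defaults are literature-derived US inputs in 2019 USD: imaging charges per
#' modality, IV-tPA acquisition and administration, thrombectomy procedure
#' (devices, room personnel, overhead) and physician costs, severity-tiered
#' acute 90-day costs, and mRS-specific 3-monthly long-term costs.
#'
#' @param imaging Named vector of imaging costs: `ct`, `cta`, `mri`, `mra`,
#'   `ctp`, `software`.
#' @param freq_cta_vs_mra,freq_ctp_vs_mri Probability that CTA (vs MRA) and
#'   CTP (vs MRI) are used in the thrombectomy work-up.
#' @param tpa IV-tPA cost.
#' @param mt_procedure,mt_physician Thrombectomy procedure and physician costs.
#' @param acute_90d Acute first-3-month cost per severity tier
#'   (`mrs0_2`, `mrs3_5`, `death`).
#' @param longterm_3mo 3-monthly long-term cost per mRS 0..5.
#' @return A validated list of class `cea_costs`.
#' @export
cea_costs <- function(imaging = c(ct = 198, cta = 774, mri = 625, mra = 1023,
                                  ctp = 836, software = 89),
                      freq_cta_vs_mra = 0.5,
                      freq_ctp_vs_mri = 0.5,
                      tpa = 8004,
                      mt_procedure = 15836,
                      mt_physician = 2749,
                      acute_90d = c(mrs0_2 = 14382, mrs3_5 = 17879, death = 23498),
                      longterm_3mo = c(mrs0 = 2836, mrs1 = 2741, mrs2 = 3378,
                                       mrs3 = 5801, mrs4 = 11742, mrs5 = 17262)) {
  need <- c("ct", "cta", "mri", "mra", "ctp", "software")
  if (!all(need %in% names(imaging))) {
    abort_validation("imaging", paste("missing modality:",
                                      paste(setdiff(need, names(imaging)), collapse = ", ")))
  }
  check_nonneg(imaging, "imaging")
  check_prob(freq_cta_vs_mra, "freq_cta_vs_mra")
  check_prob(freq_ctp_vs_mri, "freq_ctp_vs_mri")
  check_nonneg(tpa, "tpa")
  check_nonneg(mt_procedure, "mt_procedure")
  check_nonneg(mt_physician, "mt_physician")
  if (!all(c("mrs0_2", "mrs3_5", "death") %in% names(acute_90d))) {
    abort_validation("acute_90d", "needs tiers mrs0_2, mrs3_5, death")
  }
  check_nonneg(acute_90d, "acute_90d")
  if (!all(MRS_ALIVE %in% names(longterm_3mo))) {
    abort_validation("longterm_3mo", "needs mrs0..mrs5")
  }
  check_nonneg(longterm_3mo, "longterm_3mo")
  structure(list(imaging = imaging[need],
                 freq_cta_vs_mra = freq_cta_vs_mra,
                 freq_ctp_vs_mri = freq_ctp_vs_mri,
                 tpa = tpa, mt_procedure = mt_procedure,
                 mt_physician = mt_physician,
                 acute_90d = acute_90d[c("mrs0_2", "mrs3_5", "death")],
                 longterm_3mo = longterm_3mo[MRS_ALIVE]),
            class = "cea_costs")
}

#' Health-state utilities per mRS level
#'
#' Time-trade-off utilities for mRS 0..5; death (mRS 6) carries utility 0.
#' Utilities must lie in `[0, 1]` and be non-increasing in severity.
#'
#' @param utility Named vector `mrs0`..`mrs5`.
#' @return Validated named numeric vector of class `cea_utilities`.
#' @export
cea_utilities <- function(utility = c(mrs0 = 0.85, mrs1 = 0.80, mrs2 = 0.70,
                                      mrs3 = 0.51, mrs4 = 0.30, mrs5 = 0.15)) {
  if (!all(MRS_ALIVE %in% names(utility))) {
    abort_validation("utility", paste("missing:",
                                      paste(setdiff(MRS_ALIVE, names(utility)), collapse = ", ")))
  }
  utility <- utility[MRS_ALIVE]
  if (any(utility < 0) || any(utility > 1)) {
    abort_validation("utility", "out of [0,1]")
  }
  if (any(diff(utility) > 1e-12)) {
    abort_validation("utility", "must be non-increasing in mRS severity")
  }
  structure(utility, class = "cea_utilities")
}

#' Markov transition inputs
#'
#' @param recurrence_prob Per-3-month probability of recurrent stroke,
#'   assumed equal across mRS states.
#' @param post_recurrence_death Probability that a recurrent stroke is fatal
#'   within the cycle.
#' @param death_hr Hazard ratio on background mortality per mRS 0..5.
#' @param worse_split Optional list of 6 vectors giving, for each origin
#'   state mRS 0..5, the split of the non-fatal recurrence mass over the
#'   strictly worse alive states (defaults to an equal split; the entry for
#'   mRS 5 is empty because no worse alive state exists).
#' @param split_family `"dirichlet"` (the default: [sample_parameter_set()]
#'   redraws the worse-state split from a flat Dirichlet per PSA draw) or
#'   `"fixed"` (the split stays at its equal-split/default value).
#' @return Validated list of class `cea_transitions`.
#' @export
cea_transitions <- function(recurrence_prob = 0.013,
                            post_recurrence_death = 0.0513,
                            death_hr = c(mrs0 = 1, mrs1 = 1, mrs2 = 1.11,
                                         mrs3 = 1.27, mrs4 = 1.71, mrs5 = 2.37),
                            worse_split = NULL,
                            split_family = c("dirichlet", "fixed")) {
  split_family <- match.arg(split_family)
  check_prob(recurrence_prob, "recurrence_prob")
  check_prob(post_recurrence_death, "post_recurrence_death")
  if (!all(MRS_ALIVE %in% names(death_hr))) {
    abort_validation("death_hr", paste("missing:",
                                       paste(setdiff(MRS_ALIVE, names(death_hr)), collapse = ", ")))
  }
  check_pos(death_hr, "death_hr")
  if (!is.null(worse_split)) {
    if (length(worse_split) != 6) {
      abort_validation("worse_split", "needs one entry per origin state mRS 0..5")
    }
    for (i in 1:5) {
      w <- worse_split[[i]]
      if (length(w) != 6 - i || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
        abort_validation("worse_split",
                         sprintf("entry for mRS %d must be %d shares summing to 1", i - 1, 6 - i))
      }
    }
  }
  structure(list(recurrence_prob = recurrence_prob,
                 post_recurrence_death = post_recurrence_death,
                 death_hr = death_hr[MRS_ALIVE],
                 worse_split = worse_split,
                 split_family = split_family),
            class = "cea_transitions")
}

#' Model settings
#'
#' @param cycle_length Cycle length in years (3 months).
#' @param discount_rate Annual discount rate for costs and QALYs.
#' @param cohort_size Hypothetical cohort size; per-patient results do not
#'   depend on it.
#' @param psa_draws Number of probabilistic sensitivity analysis draws.
#' @param max_age Age at which the Markov model is truncated.
#' @param wtp Willingness-to-pay threshold (USD/QALY) used for net monetary
#'   benefit summaries.
#' @param wtp_grid Grid of thresholds for the acceptability curve.
#' @param seed Master random seed.
#' @param include_acute_qaly Accrue 0.25 x expected 90-day utility as acute
#'   QALYs at time zero (default), or start QALY accrual at Markov entry.
#' @param half_cycle Apply a half-cycle correction to Markov accruals.
#' @param extinction_tol Alive fraction below which the cohort is considered
#'   extinct.
#' @return List of class `cea_settings`.
#' @export
cea_settings <- function(cycle_length = 0.25,
                         discount_rate = 0.03,
                         cohort_size = 1000,
                         psa_draws = 2000,
                         max_age = 110,
                         wtp = 1e5,
                         wtp_grid = seq(0, 2e5, by = 2500),
                         seed = 1L,
                         include_acute_qaly = TRUE,
                         half_cycle = FALSE,
                         extinction_tol = 1e-6) {
  check_pos(cycle_length, "cycle_length")
  check_nonneg(discount_rate, "discount_rate")
  if (psa_draws < 1) abort_validation("psa_draws", "must be >= 1")
  check_pos(cohort_size, "cohort_size")
  check_pos(max_age, "max_age")
  check_nonneg(wtp, "wtp")
  check_nonneg(wtp_grid, "wtp_grid")
  structure(list(cycle_length = cycle_length, discount_rate = discount_rate,
                 cohort_size = cohort_size, psa_draws = as.integer(psa_draws),
                 max_age = max_age, wtp = wtp, wtp_grid = wtp_grid,
                 seed = as.integer(seed),
                 include_acute_qaly = isTRUE(include_acute_qaly),
                 half_cycle = isTRUE(half_cycle),
                 extinction_tol = extinction_tol),
            class = "cea_settings")
}

# ---- uncertain-parameter registry ---------------------------------------

registry_row <- function(id, family, base, alpha = NA_real_, beta = NA_real_,
                         min = NA_real_, mode = NA_real_, max = NA_real_,
                         se = NA_real_, low = NA_real_, high = NA_real_) {
  tibble::tibble(id = id, family = family, base = base, alpha = alpha,
                 beta = beta, min = min, mode = mode, max = max, se = se,
                 low = low, high = high)
}

pert_row <- function(id, min, mode, max) {
  registry_row(id, "beta_pert", base = mode, min = min, mode = mode, max = max,
               low = min, high = max)
}

beta_ab_row <- function(id, base, alpha, beta) {
  registry_row(id, "beta", base = base, alpha = alpha, beta = beta,
               low = qbeta(0.025, alpha, beta), high = qbeta(0.975, alpha, beta))
}

beta_range_row <- function(id, base, low, high) {
  ab <- solve_beta_range(base, low, high, field = id)
  registry_row(id, "beta", base = base, alpha = ab[["alpha"]], beta = ab[["beta"]],
               low = low, high = high)
}

lognormal_row <- function(id, base, se) {
  registry_row(id, "log_normal", base = base, se = se,
               low = qlnorm(0.025, log(base), se), high = qlnorm(0.975, log(base), se))
}

uniform_row <- function(id, base, min, max) {
  registry_row(id, "uniform", base = base, min = min, max = max,
               low = min, high = max)
}

default_registry <- function() {
  dplyr::bind_rows(
    pert_row("cost_ct", 168, 198, 228),
    pert_row("cost_cta", 658, 774, 890),
    pert_row("cost_mri", 531, 625, 718),
    pert_row("cost_mra", 870, 1023, 1176),
    pert_row("cost_ctp", 711, 836, 961),
    pert_row("cost_software", 44, 89, 520),
    uniform_row("freq_cta_vs_mra", 0.5, 0, 1),
    uniform_row("freq_ctp_vs_mri", 0.5, 0, 1),
    pert_row("cost_tpa", 6403, 8004, 9605),
    pert_row("cost_mt_procedure", 5270, 15836, 26401),
    pert_row("cost_mt_physician", 1262, 2749, 4236),
    pert_row("cost_acute_mrs0_2", 14210, 14382, 14554),
    pert_row("cost_acute_mrs3_5", 17660, 17879, 18097),
    pert_row("cost_acute_death", 22614, 23498, 24382),
    pert_row("cost_longterm_mrs0", 2269, 2836, 3403),
    pert_row("cost_longterm_mrs1", 2336, 2741, 3504),
    pert_row("cost_longterm_mrs2", 2703, 3378, 4054),
    pert_row("cost_longterm_mrs3", 4641, 5801, 6961),
    pert_row("cost_longterm_mrs4", 9393, 11742, 14090),
    pert_row("cost_longterm_mrs5", 13809, 17262, 20714),
    beta_range_row("utility_mrs0", 0.85, 0.80, 1.00),
    beta_range_row("utility_mrs1", 0.80, 0.80, 0.95),
    beta_range_row("utility_mrs2", 0.70, 0.68, 0.90),
    beta_range_row("utility_mrs3", 0.51, 0.45, 0.65),
    beta_range_row("utility_mrs4", 0.30, 0.10, 0.40),
    beta_range_row("utility_mrs5", 0.15, 0.00, 0.32),
    beta_ab_row("recurrence_prob", 0.013, 13, 986),
    beta_ab_row("post_recurrence_death", 0.0513, 5.1, 94.9),
    lognormal_row("death_hr_mrs0", 1, 0.076),
    lognormal_row("death_hr_mrs1", 1, 0.46),
    lognormal_row("death_hr_mrs2", 1.11, 0.46),
    lognormal_row("death_hr_mrs3", 1.27, 0.46),
    lognormal_row("death_hr_mrs4", 1.71, 0.46),
    lognormal_row("death_hr_mrs5", 2.37, 0.46)
  )
}

param_paths <- function() {
  p <- list(
    cost_ct = c("costs", "imaging", "ct"),
    cost_cta = c("costs", "imaging", "cta"),
    cost_mri = c("costs", "imaging", "mri"),
    cost_mra = c("costs", "imaging", "mra"),
    cost_ctp = c("costs", "imaging", "ctp"),
    cost_software = c("costs", "imaging", "software"),
    freq_cta_vs_mra = c("costs", "freq_cta_vs_mra"),
    freq_ctp_vs_mri = c("costs", "freq_ctp_vs_mri"),
    cost_tpa = c("costs", "tpa"),
    cost_mt_procedure = c("costs", "mt_procedure"),
    cost_mt_physician = c("costs", "mt_physician"),
    cost_acute_mrs0_2 = c("costs", "acute_90d", "mrs0_2"),
    cost_acute_mrs3_5 = c("costs", "acute_90d", "mrs3_5"),
    cost_acute_death = c("costs", "acute_90d", "death"),
    recurrence_prob = c("transitions", "recurrence_prob"),
    post_recurrence_death = c("transitions", "post_recurrence_death")
  )
  for (s in MRS_ALIVE) {
    p[[paste0("cost_longterm_", s)]] <- c("costs", "longterm_3mo", s)
    p[[paste0("utility_", s)]] <- c("utilities", s)
    p[[paste0("death_hr_", s)]] <- c("transitions", "death_hr", s)
  }
  p
}

.param_paths <- param_paths()

#' Assemble a complete model parameter set
#'
#' Bundles costs, utilities and transition inputs together with the registry
#' of uncertain parameters (distribution family, parameters and one-way
#' bounds per input) that drives both the probabilistic and the one-way
#' sensitivity analyses.
#'
#' @param costs A [cea_costs()] object.
#' @param utilities A [cea_utilities()] object.
#' @param transitions A [cea_transitions()] object.
#' @return A list of class `cea_params` with elements `costs`, `utilities`,
#'   `transitions` and `dist` (a tibble registry of uncertain parameters).
#' @examples
#' params <- cea_parameters()
#' params$transitions$recurrence_prob
#' @export
cea_parameters <- function(costs = cea_costs(),
                           utilities = cea_utilities(),
                           transitions = cea_transitions()) {
  stopifnot(inherits(costs, "cea_costs"), inherits(utilities, "cea_utilities"),
            inherits(transitions, "cea_transitions"))
  params <- structure(list(costs = unclass(costs),
                           utilities = unclass(utilities),
                           transitions = unclass(transitions),
                           dist = default_registry()),
                      class = "cea_params")
  # keep registry base values in step with (possibly user-overridden) inputs
  params$dist$base <- vapply(params$dist$id, function(id) cea_param_value(params, id),
                             numeric(1), USE.NAMES = FALSE)
  params
}

#' Read or overwrite one uncertain parameter by registry id
#'
#' @param params A `cea_params` object.
#' @param id Registry id, e.g. `"cost_mt_procedure"` or `"utility_mrs3"`.
#' @param value Replacement value.
#' @return `cea_param_value()` returns the scalar value; `set_cea_param()`
#'   the modified parameter set. Bounds appropriate to the parameter
#'   (probabilities in `[0,1]`, costs non-negative, hazard ratios positive)
#'   are enforced; cross-parameter constraints such as utility monotonicity
#'   are checked only at [cea_parameters()] construction so that sampled
#'   values may cross.
#' @export
cea_param_value <- function(params, id) {
  path <- .param_paths[[id]]
  if (is.null(path)) abort_validation(id, "unknown parameter id")
  unname(params[[path]])
}

#' @rdname cea_param_value
#' @export
set_cea_param <- function(params, id, value) {
  path <- .param_paths[[id]]
  if (is.null(path)) abort_validation(id, "unknown parameter id")
  if (grepl("^(freq_|recurrence_prob|post_recurrence_death|utility_)", id)) {
    check_prob(value, id)
  } else if (grepl("^death_hr_", id)) {
    check_pos(value, id)
  } else {
    check_nonneg(value, id)
  }
  params[[path]] <- value
  i <- match(id, params$dist$id)
  if (!is.na(i)) params$dist$base[i] <- value
  params
}

# ---- configuration files -------------------------------------------------

#' Default per-trial arm composition
#'
#' Proportion of men per arm (printed trial values) and IV-tPA usage
#' frequency per arm. The tPA frequencies are synthetic placeholders (the
#' per-arm trial frequencies are not published in the sources bundled here)
#' and should be overridden when real values are available.
#'
#' @return Nested list keyed by trial then field then strategy.
#' @export
trial_defaults <- function() {
  list(
    DAWN = list(prop_male = c(MT_SMC = 0.393, SMC = 0.515),
                tpa_frequency = c(MT_SMC = 0.10, SMC = 0.10)),
    DEFUSE3 = list(prop_male = c(MT_SMC = 0.500, SMC = 0.489),
                   tpa_frequency = c(MT_SMC = 0.10, SMC = 0.10))
  )
}

#' Write and read the model configuration file
#'
#' The configuration is a single human-editable YAML file mirroring the
#' input-parameter table: one entry per uncertain parameter carrying its
#' base value and distribution specification, plus model settings and
#' per-trial arm composition defaults. Life tables and 90-day efficacy
#' distributions live in separate CSV files (see [read_life_table()] and
#' [read_efficacy()]).
#'
#' @param params A `cea_params` object.
#' @param settings A `cea_settings` object.
#' @param path File path.
#' @param trial_defaults Per-trial arm composition, see [trial_defaults()].
#' @return `write_cea_config()` returns `path` invisibly; `load_parameters()`
#'   returns `list(params, settings, trial_defaults)`.
#' @export
write_cea_config <- function(params, settings, path,
                             trial_defaults = strokecea::trial_defaults()) {
  reg <- params$dist
  entries <- lapply(seq_len(nrow(reg)), function(i) {
    row <- as.list(reg[i, setdiff(names(reg), "id")])
    row[!vapply(row, function(x) is.na(x), logical(1))]
  })
  names(entries) <- reg$id
  cfg <- list(settings = unclass(settings),
              parameters = entries,
              trial_defaults = lapply(trial_defaults, function(t) lapply(t, as.list)))
  writeLines(yaml::as.yaml(cfg, precision = 12L), path)
  invisible(path)
}

#' @rdname write_cea_config
#' @param config_path Path to a YAML configuration written by
#'   [write_cea_config()] (or edited by hand).
#' @export
load_parameters <- function(config_path) {
  if (!file.exists(config_path)) {
    abort_validation("config_path", paste("no such file:", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  for (section in c("settings", "parameters")) {
    if (is.null(cfg[[section]])) abort_validation(section, "missing config section")
  }
  settings <- do.call(cea_settings, cfg$settings[names(cfg$settings) %in%
                                                   names(formals(cea_settings))])
  params <- cea_parameters()
  missing <- setdiff(params$dist$id, names(cfg$parameters))
  if (length(missing) > 0) {
    abort_validation(missing[1], "missing from config parameters")
  }
  reg <- params$dist
  for (id in reg$id) {
    entry <- cfg$parameters[[id]]
    if (is.null(entry$base) || is.null(entry$family)) {
      abort_validation(id, "config entry needs base and family")
    }
    params <- set_cea_param(params, id, entry$base)
    i <- match(id, reg$id)
    for (col in c("family", "alpha", "beta", "min", "mode", "max", "se", "low", "high")) {
      if (!is.null(entry[[col]])) reg[i, col] <- entry[[col]]
    }
  }
  reg$base <- vapply(reg$id, function(id) cea_param_value(params, id), numeric(1),
                     USE.NAMES = FALSE)
  validate_registry(reg)
  params$dist <- reg
  # re-validate cross-field constraints on the loaded values
  cea_parameters(costs = do.call(cea_costs, params$costs[names(params$costs)]),
                 utilities = cea_utilities(params$utilities),
                 transitions = do.call(cea_transitions,
                                       params$transitions[c("recurrence_prob",
                                                            "post_recurrence_death",
                                                            "death_hr")]))
  td <- cfg$trial_defaults
  if (!is.null(td)) {
    td <- lapply(td, function(t) lapply(t, function(x) unlist(x)))
  } else {
    td <- trial_defaults()
  }
  params$dist <- reg
  list(params = params, settings = settings, trial_defaults = td)
}

validate_registry <- function(reg) {
  for (i in seq_len(nrow(reg))) {
    row <- reg[i, ]
    switch(row$family,
      beta_pert = {
        if (anyNA(c(row$min, row$mode, row$max)) ||
            !(row$min <= row$mode && row$mode <= row$max)) {
          abort_validation(row$id, "beta_pert needs min <= mode <= max")
        }
      },
      beta = {
        if (anyNA(c(row$alpha, row$beta)) || row$alpha <= 0 || row$beta <= 0) {
          abort_validation(row$id, "beta needs alpha, beta > 0")
        }
      },
      log_normal = {
        if (is.na(row$se) || row$se <= 0 || row$base <= 0) {
          abort_validation(row$id, "log_normal needs positive base and se")
        }
      },
      uniform = {
        if (anyNA(c(row$min, row$max)) || row$min > row$max) {
          abort_validation(row$id, "uniform needs min <= max")
        }
      },
      fixed = NULL,
      abort_validation(row$id, paste("unknown distribution family:", row$family))
    )
  }
  invisible(reg)
}

# ---- life tables ---------------------------------------------------------

#' Read and validate a life table
#'
#' A life table gives the annual probability of death `qx` by integer `age`
#' and `sex` (`male`/`female`). Ages must be contiguous within each sex and
#' both sexes must be present.
#'
#' @param path CSV file with columns `age`, `sex`, `qx`.
#' @return A validated tibble.
#' @export
read_life_table <- function(path) {
  validate_life_table(tibble::as_tibble(utils::read.csv(path)))
}

#' @rdname read_life_table
#' @param life_table A data frame with columns `age`, `sex`, `qx`.
#' @export
validate_life_table <- function(life_table) {
  if (isTRUE(attr(life_table, "cea_validated"))) {
    return(life_table)
  }
  lt <- tibble::as_tibble(life_table)
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    abort_validation("life_table", "needs columns age, sex, qx")
  }
  check_prob(lt$qx, "qx")
  if (!all(c("male", "female") %in% lt$sex)) {
    abort_validation("sex", "both male and female rows required")
  }
  for (s in c("male", "female")) {
    ages <- sort(lt$age[lt$sex == s])
    if (length(ages) == 0 || any(diff(ages) != 1)) {
      abort_validation("age", paste("ages must be contiguous for sex", s))
    }
  }
  out <- dplyr::arrange(lt, .data$sex, .data$age)
  attr(out, "cea_validated") <- TRUE
  out
}

# ---- efficacy tables and subgroups ---------------------------------------

#' Read a 90-day efficacy table
#'
#' One row per subgroup x trial x arm with the 90-day mRS probabilities
#' (`mrs0`..`mrs6`), the arm sample size `n` and `mean_age`. Rows in the
#' combined-mRS-5/6 dialect (as reported by DAWN) carry the combined
#' probability in `mrs5` and `NA` in `mrs6`; they are split against a
#' reference distribution when subgroups are constructed
#' (see [split_mrs56()]).
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_efficacy <- function(path) {
  eff <- tibble::as_tibble(utils::read.csv(path))
  need <- c("subgroup", "trial", "arm", MRS_ALL, "n", "mean_age")
  if (!all(need %in% names(eff))) {
    abort_validation("efficacy", paste("missing columns:",
                                       paste(setdiff(need, names(eff)), collapse = ", ")))
  }
  eff
}

#' Construct a subgroup for analysis
#'
#' A subgroup pairs one thrombectomy (`MT_SMC`) and one control (`SMC`) arm,
#' each with its own 90-day mRS distribution, sample size, mean age, IV-tPA
#' frequency and sex composition.
#'
#' @param trial `"DAWN"` or `"DEFUSE3"`.
#' @param label Subgroup label.
#' @param arms A data frame with one row per strategy and columns `strategy`,
#'   `mrs0`..`mrs6`, `n`, `mean_age`, `tpa_frequency`, `prop_male`. An `NA`
#'   in `mrs6` marks a combined-mRS-5/6 row; `mrs5` then holds the combined
#'   probability and `mrs56_reference` must be supplied.
#' @param mrs56_reference A full 7-level mRS distribution whose relative
#'   mRS-5/mRS-6 proportions are used to split combined rows.
#' @return A list of class `cea_subgroup`.
#' @export
cea_subgroup <- function(trial, label, arms, mrs56_reference = NULL) {
  if (!trial %in% TRIALS) abort_validation("trial", "must be DAWN or DEFUSE3")
  arms <- tibble::as_tibble(arms)
  if (!setequal(arms$strategy, STRATEGIES) || nrow(arms) != 2) {
    abort_validation("arms", "exactly two arms required, one MT_SMC and one SMC")
  }
  arms <- dplyr::arrange(arms, match(.data$strategy, STRATEGIES))
  for (i in 1:2) {
    if (is.na(arms$mrs6[i])) {
      if (is.null(mrs56_reference)) {
        abort_validation("mrs56_reference",
                         "required to split a combined mRS 5/6 probability")
      }
      ref <- validate_mrs_distribution(mrs56_reference, "mrs56_reference")
      p56 <- split_mrs56(arms$mrs5[i], ref)
      arms$mrs5[i] <- p56[["p5"]]
      arms$mrs6[i] <- p56[["p6"]]
    }
    validate_mrs_distribution(unlist(arms[i, MRS_ALL]),
                              paste0(label, "/", arms$strategy[i]))
    if (arms$mean_age[i] < 18 || arms$mean_age[i] > 100) {
      abort_validation("mean_age", "must be in [18, 100]")
    }
    if (arms$n[i] < 1) abort_validation("n", "must be >= 1")
    check_prob(arms$tpa_frequency[i], "tpa_frequency")
    check_prob(arms$prop_male[i], "prop_male")
  }
  structure(list(trial = trial, label = label, arms = arms),
            class = "cea_subgroup")
}

#' Build subgroups from an efficacy table
#'
#' @param efficacy A tibble as returned by [read_efficacy()] or
#'   [synth_efficacy()].
#' @param mrs56_reference Reference distribution for splitting combined
#'   mRS 5/6 rows (applied uniformly, conventionally the DEFUSE 3 total
#'   population proportions).
#' @param defaults Per-trial arm composition used to fill `tpa_frequency`
#'   and `prop_male` when the table lacks those columns.
#' @return A named list of `cea_subgroup` objects.
#' @export
as_subgroups <- function(efficacy, mrs56_reference = NULL,
                         defaults = trial_defaults()) {
  eff <- tibble::as_tibble(efficacy)
  if (!"tpa_frequency" %in% names(eff)) {
    eff$tpa_frequency <- purrr::map2_dbl(eff$trial, eff$arm,
                                         ~ defaults[[.x]]$tpa_frequency[[.y]])
  }
  if (!"prop_male" %in% names(eff)) {
    eff$prop_male <- purrr::map2_dbl(eff$trial, eff$arm,
                                     ~ defaults[[.x]]$prop_male[[.y]])
  }
  keys <- dplyr::distinct(eff, .data$trial, .data$subgroup)
  out <- purrr::pmap(keys, function(trial, subgroup) {
    rows <- dplyr::filter(eff, .data$trial == !!trial, .data$subgroup == !!subgroup)
    arms <- dplyr::transmute(rows, strategy = .data$arm,
                             dplyr::across(dplyr::all_of(MRS_ALL)),
                             n = .data$n, mean_age = .data$mean_age,
                             tpa_frequency = .data$tpa_frequency,
                             prop_male = .data$prop_male)
    cea_subgroup(trial, subgroup, arms, mrs56_reference = mrs56_reference)
  })
  stats::setNames(out, paste(keys$trial, keys$subgroup, sep = "/"))
}
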