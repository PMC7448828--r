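# Lifetime Markov cohort model: mRS 0..5 alive states plus an absorbing
# dead state, 3-month cycles, stroke recurrence and hazard-ratio-adjusted
# life-table background mortality.

mixed_qx <- function(life_table, prop_male) {
  lt <- validate_life_table(life_table)
  m <- lt[lt$sex == "male", ]
  f <- lt[lt$sex == "female", ]
  ages <- intersect(m$age, f$age)
  a0 <- min(ages)
  a1 <- max(ages)
  list(a0 = a0, a1 = a1,
       qx = prop_male * m$qx[match(a0:a1, m$age)] +
         (1 - prop_male) * f$qx[match(a0:a1, f$age)])
}

qx_lookup <- function(life_table, prop_male) {
  mq <- mixed_qx(life_table, prop_male)
  clamped <- FALSE
  function(age) {
    a <- floor(age)
    if (a > mq$a1 && !clamped) {
      clamped <<- TRUE
      warn(sprintf("age %.1f beyond life table (max %d); clamping to last row",
                   age, mq$a1))
    }
    mq$qx[pmin(pmax(a, mq$a0), mq$a1) - mq$a0 + 1]
  }
}

#' Per-cycle background death probability
#'
#' Annual death probabilities are mixed across sexes by the cohort's male
#' proportion, converted to a rate `r = -log(1 - qx)`, scaled by the mRS
#' state's mortality hazard ratio, and converted back to a per-cycle
#' probability `1 - exp(-hr * r * cycle_length)`.
#'
#' @param age Age in years (looked up at its integer floor; ages beyond the
#'   table are clamped to the last row with a warning).
#' @param prop_male Fraction of the cohort that is male, in `[0, 1]`.
#' @param life_table A life table, see [read_life_table()].
#' @param hr Hazard ratio(s) applied on the rate scale.
#' @param cycle_length Cycle length in years.
#' @return Per-cycle death probability, vectorised over `hr`.
#' @examples
#' lt <- synth_life_table()
#' background_death_prob(70, 0.5, lt, hr = 2.37)
#' @export
background_death_prob <- function(age, prop_male, life_table, hr = 1,
                                  cycle_length = 0.25) {
  check_prob(prop_male, "prop_male")
  check_pos(hr, "hr")
  qx <- qx_lookup(life_table, prop_male)(age)
  1 - exp(-hr * (-log1p(-qx)) * cycle_length)
}

#' Outcome distribution after a recurrent stroke
#'
#' A recurrent stroke is fatal with probability `post_recurrence_death`;
#' otherwise the patient transitions to a strictly worse alive mRS state,
#' with the non-fatal mass split equally among the worse states (or per the
#' `worse_split` override drawn during PSA). A patient recurring from mRS 5
#' has no worse alive state and remains in mRS 5 if the recurrence is not
#' fatal.
#'
#' @param state Current mRS state, an integer 0..5.
#' @param transitions A [cea_transitions()] object.
#' @return Named probability vector over `mrs0`..`mrs5`, `dead`.
#' @examples
#' recurrence_outcome_distribution(0, cea_transitions())
#' @export
recurrence_outcome_distribution <- function(state, transitions) {
  stopifnot(state %in% 0:5)
  d <- transitions$post_recurrence_death
  out <- stats::setNames(numeric(7), STATES)
  out[["dead"]] <- d
  if (state == 5) {
    out[["mrs5"]] <- 1 - d
  } else {
    worse <- paste0("mrs", (state + 1):5)
    split <- transitions$worse_split[[state + 1]] %||%
      rep(1 / length(worse), length(worse))
    out[worse] <- (1 - d) * split
  }
  out
}

recurrence_matrix <- function(transitions) {
  t(vapply(0:5, recurrence_outcome_distribution, numeric(7),
           transitions = transitions))
}

cycle_core <- function(state, qx, params, rec_matrix, recurrent_cost,
                       recurrence_utility, cycle_length) {
  alive <- state[1:6]
  hr <- params$transitions$death_hr
  p_bg <- 1 - exp(-hr * (-log1p(-qx)) * cycle_length)
  bg_dead <- sum(alive * p_bg)
  surv <- alive * (1 - p_bg)
  rec <- surv * params$transitions$recurrence_prob
  stay <- surv - rec
  redist <- as.numeric(rec %*% rec_matrix)
  new_state <- c(stay + redist[1:6], state[7] + bg_dead + redist[7])
  util <- c(unclass(params$utilities)[MRS_ALIVE])
  cost <- sum(stay * params$costs$longterm_3mo) + sum(rec) * recurrent_cost
  utility <- sum(stay * util) + sum(rec) * recurrence_utility
  list(state = stats::setNames(new_state, STATES), cost = cost,
       qaly = utility * cycle_length, recurrence = sum(rec))
}

#' One Markov cycle
#'
#' Applies, in order: hazard-ratio-adjusted background mortality, then
#' recurrence among survivors (probability `recurrence_prob`, equal across
#' states, at most one recurrence per cycle) with redistribution per
#' [recurrence_outcome_distribution()]. Non-recurrent survivors accrue
#' their state's 3-monthly long-term cost and utility; recurrent patients
#' instead accrue the strategy's recurrent-stroke cost and recurrence
#' utility for the cycle; patients dying of background causes accrue
#' nothing that cycle. Accruals are undiscounted.
#'
#' @param state Named occupancy vector over `mrs0`..`mrs5`, `dead`,
#'   summing to 1.
#' @param age Cohort age during the cycle (drives the life-table lookup).
#' @param params A [cea_parameters()] object.
#' @param life_table A life table.
#' @param prop_male Male fraction for the sex mix.
#' @param recurrent_cost,recurrence_utility Strategy-specific cost and
#'   utility of a recurrent-stroke cycle, from the 90-day decision tree.
#' @param cycle_length Cycle length in years.
#' @return List with the next `state`, the cycle's `cost`, `qaly` and
#'   `recurrence` incidence (all per member of the cohort entering the
#'   cycle).
#' @export
cycle_step <- function(state, age, params, life_table, prop_male,
                       recurrent_cost, recurrence_utility,
                       cycle_length = 0.25) {
  if (abs(sum(state) - 1) > 1e-9 || any(state < 0)) {
    abort_validation("state", "occupancy must be non-negative and sum to 1")
  }
  qx <- qx_lookup(life_table, prop_male)(age)
  cycle_core(stats::setNames(as.numeric(state), STATES), qx, params,
             recurrence_matrix(params$transitions), recurrent_cost,
             recurrence_utility, cycle_length)
}

#' Run the lifetime Markov cohort model
#'
#' Propagates the 90-day survivor cohort through 3-month cycles until the
#' alive fraction falls below `settings$extinction_tol` or the cohort
#' reaches `settings$max_age`, accruing discounted costs and QALYs.
#' The cohort enters at age `mean_age + cycle_length` (the life table
#' applies from the end of month 3 onward) and cycle accruals are
#' discounted to time zero at `settings$discount_rate` from their cycle
#' start time. All totals are per 90-day survivor; scale by the surviving
#' fraction when combining with the acute phase (done by [run_strategy()]).
#'
#' @param initial 90-day mRS distribution: either a 7-level vector (its
#'   death mass is removed and the alive part renormalised) or a 6-level
#'   alive distribution summing to 1.
#' @param params A [cea_parameters()] object.
#' @param life_table A life table.
#' @param settings A [cea_settings()] object.
#' @param mean_age Cohort mean age at the initial stroke.
#' @param prop_male Male fraction.
#' @param recurrent_cost,recurrence_utility Strategy-specific recurrent
#'   stroke accruals from the decision tree.
#' @param trace Keep the cycle-by-cycle cohort trace (disable inside large
#'   PSA loops).
#' @return An object of class `cea_markov`: list with `totals` (one-row
#'   tibble: discounted/undiscounted cost and QALYs, life years, cycles)
#'   and `trace` (tibble of cycle, age, state occupancy and accruals, or
#'   `NULL`).
#' @export
run_markov <- function(initial, params, life_table, settings, mean_age,
                       prop_male, recurrent_cost, recurrence_utility,
                       trace = TRUE) {
  initial <- as.numeric(unlist(initial))
  if (length(initial) == 7) {
    s <- sum(initial[1:6])
    alive0 <- if (s > 0) initial[1:6] / s else rep(0, 6)
  } else if (length(initial) == 6) {
    if (abs(sum(initial) - 1) > 1e-9) {
      abort_validation("initial", "6-level survivor distribution must sum to 1")
    }
    alive0 <- initial
    s <- 1
  } else {
    abort_validation("initial", "must have 6 or 7 levels")
  }
  empty_totals <- tibble::tibble(cost = 0, qaly = 0, cost_undisc = 0,
                                 qaly_undisc = 0, life_years = 0, cycles = 0L)
  if (sum(alive0) == 0) {
    return(structure(list(totals = empty_totals, trace = NULL),
                     class = "cea_markov"))
  }
  cl <- settings$cycle_length
  mq <- mixed_qx(life_table, prop_male)
  rec_m <- recurrence_matrix(params$transitions)
  hr <- unname(params$transitions$death_hr)
  p_rec <- params$transitions$recurrence_prob
  d_rate <- settings$discount_rate
  longterm <- unname(params$costs$longterm_3mo)
  util <- unname(unclass(params$utilities)[MRS_ALIVE])
  age0 <- mean_age + cl
  n_max <- max(1L, ceiling((settings$max_age - age0) / cl) + 1L)
  rows <- matrix(NA_real_, nrow = n_max, ncol = 12,
                 dimnames = list(NULL, c("cycle", "age", STATES, "recurrence",
                                         "cost", "qaly")))
  alive <- alive0
  dead <- 0
  cost_d <- qaly_d <- cost_u <- qaly_u <- ly <- 0
  acc_cost1 <- acc_qaly1 <- NA_real_
  k <- 0L
  while (sum(alive) > settings$extinction_tol && k < n_max) {
    k <- k + 1L
    age <- age0 + (k - 1L) * cl
    if (age >= settings$max_age) {
      k <- k - 1L
      if (sum(alive) > 1e-2) {
        warn(sprintf("%.2g of the cohort still alive at max_age %g; truncating",
                     sum(alive), settings$max_age))
      }
      break
    }
    qx <- mq$qx[pmin(pmax(floor(age), mq$a0), mq$a1) - mq$a0 + 1]
    p_bg <- 1 - exp(hr * log1p(-qx) * cl)
    surv <- alive * (1 - p_bg)
    rec <- surv * p_rec
    stay <- surv - rec
    redist <- drop(rec %*% rec_m)
    step_cost <- sum(stay * longterm) + sum(rec) * recurrent_cost
    step_qaly <- (sum(stay * util) + sum(rec) * recurrence_utility) * cl
    disc <- (1 + d_rate)^(-(k * cl))
    if (k == 1L) {
      acc_cost1 <- step_cost
      acc_qaly1 <- step_qaly
    }
    cost_d <- cost_d + disc * step_cost
    qaly_d <- qaly_d + disc * step_qaly
    cost_u <- cost_u + step_cost
    qaly_u <- qaly_u + step_qaly
    ly <- ly + sum(alive) * cl
    rows[k, ] <- c(k, age, alive, dead, sum(rec), disc * step_cost,
                   disc * step_qaly)
    dead <- dead + sum(alive * p_bg) + redist[7]
    alive <- stay + redist[1:6]
  }
  if (settings$half_cycle && k >= 1L) {
    cost_d <- cost_d - 0.5 * acc_cost1 * (1 + settings$discount_rate)^(-cl)
    qaly_d <- qaly_d - 0.5 * acc_qaly1 * (1 + settings$discount_rate)^(-cl)
    cost_u <- cost_u - 0.5 * acc_cost1
    qaly_u <- qaly_u - 0.5 * acc_qaly1
  }
  totals <- tibble::tibble(cost = cost_d, qaly = qaly_d, cost_undisc = cost_u,
                           qaly_undisc = qaly_u, life_years = ly, cycles = k)
  tr <- NULL
  if (trace && k >= 1L) {
    tr <- tibble::as_tibble(as.data.frame(rows[seq_len(k), , drop = FALSE]))
  }
  structure(list(totals = totals, trace = tr), class = "cea_markov")
}

#' Write a cohort trace to CSV
#'
#' @param markov A `cea_markov` object run with `trace = TRUE`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_trace <- function(markov, path) {
  stopifnot(inherits(markov, "cea_markov"), !is.null(markov$trace))
  utils::write.csv(markov$trace, path, row.names = FALSE)
  invisible(path)
}

#' Lifetime outcome of one strategy arm
#'
#' Evaluates the 90-day decision tree for the subgroup, conditions the
#' 90-day mRS distribution on survival, runs the Markov model, and combines
#' the two phases: the acute cost (and, by default, 0.25 x the expected
#' 90-day utility as acute QALYs) is added undiscounted at time zero, and
#' Markov totals are scaled by the 90-day survivor fraction.
#'
#' @param subgroup A [cea_subgroup()] object.
#' @param strategy `"MT_SMC"` or `"SMC"`.
#' @param params A [cea_parameters()] object.
#' @param life_table A life table.
#' @param settings A [cea_settings()] object.
#' @param tree Optional pre-computed [evaluate_decision_tree()] result.
#' @param trace Keep the Markov trace.
#' @return One-row tibble: `strategy`, discounted `cost` and `qaly`,
#'   `cost_undisc`, `qaly_undisc`, `life_years`; the `cea_markov` object is
#'   attached as attribute `"markov"` when `trace = TRUE`.
#' @export
run_strategy <- function(subgroup, strategy, params, life_table, settings,
                         tree = NULL, trace = FALSE) {
  tree <- tree %||% evaluate_decision_tree(subgroup, params)
  leaf <- dplyr::filter(tree, .data$strategy == !!strategy)
  arm <- dplyr::filter(subgroup$arms, .data$strategy == !!strategy)
  stopifnot(nrow(leaf) == 1)
  mrs <- unlist(leaf[MRS_ALL])
  s <- 1 - mrs[["mrs6"]]
  mk <- run_markov(mrs, params, life_table, settings, mean_age = arm$mean_age,
                   prop_male = arm$prop_male, recurrent_cost = leaf$cost_90d,
                   recurrence_utility = leaf$utility_90d, trace = trace)
  acute_qaly <- if (settings$include_acute_qaly) {
    settings$cycle_length * leaf$utility_90d
  } else {
    0
  }
  out <- tibble::tibble(
    strategy = strategy,
    cost = leaf$cost_90d + s * mk$totals$cost,
    qaly = acute_qaly + s * mk$totals$qaly,
    cost_undisc = leaf$cost_90d + s * mk$totals$cost_undisc,
    qaly_undisc = acute_qaly + s * mk$totals$qaly_undisc,
    life_years = settings$cycle_length * s + s * mk$totals$life_years
  )
  if (trace) attr(out, "markov") <- mk
  out
}

#' Deterministic model run for a subgroup
#'
#' @inheritParams run_strategy
#' @return A list of class `cea_det` with `outcomes` (one row per strategy)
#'   and `econ` (the [econ_result()] comparison at `settings$wtp`).
#' @export
run_deterministic <- function(subgroup, params, life_table, settings,
                              trace = FALSE) {
  tree <- evaluate_decision_tree(subgroup, params)
  outcomes <- dplyr::bind_rows(
    run_strategy(subgroup, "MT_SMC", params, life_table, settings, tree, trace),
    run_strategy(subgroup, "SMC", params, life_table, settings, tree, trace)
  )
  structure(list(outcomes = outcomes,
                 econ = econ_result(outcomes, wtp = settings$wtp),
                 tree = tree,
                 subgroup = subgroup$label, trial = subgroup$trial),
            class = "cea_det")
}
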