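# Independent per-patient stochastic microsimulation of the same disease
# process (background death first, then recurrence among survivors, one
# recurrence per cycle, equal-split redistribution to worse states). Used
# as an oracle for the cohort-expectation engine; shares no code with it.

microsim_oracle <- function(init_alive6, params, life_table, settings,
                            mean_age, prop_male, rec_cost, rec_util,
                            n_patients = 2e5, seed = 1) {
  set.seed(seed)
  lt <- dplyr::arrange(tibble::as_tibble(life_table), sex, age)
  m <- lt[lt$sex == "male", ]
  f <- lt[lt$sex == "female", ]
  a0 <- min(m$age)
  a1 <- max(m$age)
  qx_mix <- prop_male * m$qx + (1 - prop_male) * f$qx[match(m$age, f$age)]

  hr <- unname(params$transitions$death_hr)
  p_rec <- params$transitions$recurrence_prob
  d <- params$transitions$post_recurrence_death
  longterm <- unname(params$costs$longterm_3mo)
  util <- unname(unclass(params$utilities)[paste0("mrs", 0:5)])
  cl <- settings$cycle_length
  r <- settings$discount_rate

  state <- sample.int(6, n_patients, replace = TRUE, prob = init_alive6)
  alive <- rep(TRUE, n_patients)
  cost <- qaly <- numeric(n_patients)
  k <- 0L
  repeat {
    k <- k + 1L
    age <- mean_age + cl * k
    if (age >= settings$max_age || !any(alive)) break
    qx <- qx_mix[min(max(floor(age), a0), a1) - a0 + 1]
    idx <- which(alive)
    pbg <- 1 - exp(hr[state[idx]] * log1p(-qx) * cl)
    dies_bg <- runif(length(idx)) < pbg
    surv <- idx[!dies_bg]
    rec <- runif(length(surv)) < p_rec
    stay_idx <- surv[!rec]
    rec_idx <- surv[rec]
    disc <- (1 + r)^(-(cl * k))
    cost[stay_idx] <- cost[stay_idx] + disc * longterm[state[stay_idx]]
    qaly[stay_idx] <- qaly[stay_idx] + disc * util[state[stay_idx]] * cl
    cost[rec_idx] <- cost[rec_idx] + disc * rec_cost
    qaly[rec_idx] <- qaly[rec_idx] + disc * rec_util * cl
    alive[idx[dies_bg]] <- FALSE
    rdie <- runif(length(rec_idx)) < d
    alive[rec_idx[rdie]] <- FALSE
    move <- rec_idx[!rdie]
    s <- state[move]
    can_worsen <- s < 6
    worse <- s[can_worsen] + 1L +
      as.integer(floor(runif(sum(can_worsen)) * (6L - s[can_worsen])))
    state[move[can_worsen]] <- worse
  }
  list(cost = mean(cost), qaly = mean(qaly),
       se_cost = sd(cost) / sqrt(n_patients),
       se_qaly = sd(qaly) / sqrt(n_patients))
}
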