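# Probabilistic sensitivity analysis: per-draw sampling of the full
# parameter set and end-to-end model evaluation for both strategies.

#' Sample one value from a distribution specification
#'
#' Families: `beta` (`alpha`, `beta`), `beta_pert` (classic PERT with shape
#' 4 on `min`/`mode`/`max`), `dirichlet` (concentration vector `alpha`,
#' returns a probability vector), `log_normal` (median = `base`, standard
#' error `se` on the log scale), `uniform` (`min`, `max`) and `fixed`
#' (returns `base`).
#'
#' @param spec A list or one-row data frame with a `family` field and the
#'   family's parameters. Uses the current RNG state.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws (a matrix with `n` rows for
#'   `dirichlet`).
#' @examples
#' set.seed(1)
#' sample_value(list(family = "beta", alpha = 13, beta = 986), n = 5)
#' @export
sample_value <- function(spec, n = 1) {
  spec <- as.list(spec)
  switch(spec$family,
    beta = {
      if (is.null(spec$alpha) || is.na(spec$alpha) || spec$alpha <= 0 ||
          is.null(spec$beta) || is.na(spec$beta) || spec$beta <= 0) {
        abort_validation(spec$id %||% "beta", "needs alpha, beta > 0")
      }
      rbeta(n, spec$alpha, spec$beta)
    },
    beta_pert = {
      if (!(spec$min <= spec$mode && spec$mode <= spec$max)) {
        abort_validation(spec$id %||% "beta_pert", "needs min <= mode <= max")
      }
      rpert(n, spec$min, spec$mode, spec$max)
    },
    dirichlet = {
      if (any(spec$alpha < 0)) {
        abort_validation(spec$id %||% "dirichlet", "needs non-negative concentration")
      }
      rdirichlet(n, spec$alpha)
    },
    log_normal = {
      if (spec$base <= 0 || spec$se <= 0) {
        abort_validation(spec$id %||% "log_normal", "needs positive base and se")
      }
      exp(rnorm(n, log(spec$base), spec$se))
    },
    uniform = runif(n, spec$min, spec$max),
    fixed = rep(spec$base, n),
    abort_validation(spec$id %||% "family",
                     paste("unknown distribution family:", spec$family))
  )
}

#' Draw a complete parameter set for one PSA iteration
#'
#' Every entry of the uncertain-parameter registry is redrawn from its
#' distribution; the non-fatal post-recurrence redistribution over worse
#' mRS states is redrawn from a flat Dirichlet conditional on the drawn
#' death share. The strategy-specific recurrent-stroke cost and recurrence
#' utility are deliberately not sampled here: they are recomputed from the
#' drawn decision tree during [run_psa()].
#'
#' @param params A [cea_parameters()] object (base values and registry).
#' @return A `cea_params` object with all uncertain values replaced by
#'   draws. Uses the current RNG state.
#' @export
sample_parameter_set <- function(params) {
  reg <- params$dist
  out <- params
  for (i in seq_len(nrow(reg))) {
    v <- sample_value(reg[i, ], n = 1)
    out <- set_cea_param(out, reg$id[i], v)
  }
  # flat Dirichlet over strictly worse alive states, conditional on the
  # (already drawn) death share; mRS 4 has a single worse state and mRS 5 none
  if (identical(params$transitions$split_family, "dirichlet")) {
    out$transitions$worse_split <- lapply(0:5, function(s) {
      k <- 5 - s
      if (k <= 0) {
        numeric(0)
      } else if (k == 1) {
        1
      } else {
        as.numeric(rdirichlet(1, rep(1, k)))
      }
    })
  }
  out
}

draw_seed <- function(seed, d) {
  as.integer((as.numeric(seed) * 48271 + d * 7919) %% 2147483629)
}

sample_arm_efficacy <- function(arms) {
  for (i in seq_len(nrow(arms))) {
    p <- as.numeric(unlist(arms[i, MRS_ALL]))
    conc <- arms$n[i] * p
    draw <- as.numeric(rdirichlet(1, conc))
    arms[i, MRS_ALL] <- as.list(draw)
  }
  arms
}

#' Probabilistic sensitivity analysis for one subgroup
#'
#' For each draw, a complete parameter set is sampled
#' ([sample_parameter_set()]; shared between the two strategies as common
#' random numbers), each arm's 90-day mRS distribution is redrawn from a
#' Dirichlet with concentration equal to the observed arm counts
#' (`n * p`), the decision tree and Markov model are evaluated end-to-end
#' for both strategies, and per-draw costs, QALYs and increments are
#' recorded. Draws failing validation are rejected and redrawn (counted in
#' the result). Each draw runs under its own deterministic sub-seed derived
#' from `settings$seed`, so any draw is reproducible in isolation.
#'
#' @param subgroup A [cea_subgroup()] object.
#' @param params A [cea_parameters()] object.
#' @param life_table A life table.
#' @param settings A [cea_settings()] object (`psa_draws`, `seed`, `wtp`,
#'   `wtp_grid`).
#' @param draws Number of draws (defaults to `settings$psa_draws`).
#' @param sample_efficacy Redraw each arm's 90-day mRS distribution per
#'   draw (the default); set `FALSE` to hold efficacy at its point
#'   estimates, e.g. to isolate cost/utility/transition uncertainty.
#' @return An object of class `cea_psa`: list with `draws` (per-draw
#'   tibble), `summary` (means and percentile 95% credibility intervals),
#'   `ceac` (acceptability curve on `settings$wtp_grid`), `wtp`,
#'   `n_draws`, `n_rejected`, `trial` and `subgroup`.
#' @export
run_psa <- function(subgroup, params, life_table, settings,
                    draws = settings$psa_draws, sample_efficacy = TRUE) {
  stopifnot(inherits(subgroup, "cea_subgroup"))
  life_table <- validate_life_table(life_table)
  rejected <- 0L
  one_draw <- function(d) {
    for (attempt in 1:100) {
      set.seed(draw_seed(settings$seed, d) + (attempt - 1L))
      res <- tryCatch({
        p_d <- sample_parameter_set(params)
        sg_d <- subgroup
        if (sample_efficacy) {
          sg_d$arms <- sample_arm_efficacy(subgroup$arms)
        }
        tree <- evaluate_decision_tree(sg_d, p_d)
        mt <- run_strategy(sg_d, "MT_SMC", p_d, life_table, settings, tree,
                           trace = FALSE)
        smc <- run_strategy(sg_d, "SMC", p_d, life_table, settings, tree,
                            trace = FALSE)
        tibble::tibble(draw = d, cost_mt = mt$cost, qaly_mt = mt$qaly,
                       cost_smc = smc$cost, qaly_smc = smc$qaly,
                       delta_cost = mt$cost - smc$cost,
                       delta_qaly = mt$qaly - smc$qaly)
      }, cea_validation_error = function(e) NULL)
      if (!is.null(res)) {
        return(res)
      }
      rejected <<- rejected + 1L
    }
    abort("PSA draw failed validation 100 times", class = "cea_psa_error")
  }
  tab <- purrr::map_dfr(seq_len(draws), one_draw)
  if (rejected > 0L) {
    inform(sprintf("run_psa: %d draw(s) rejected and redrawn", rejected))
  }
  out <- structure(list(draws = tab, wtp = settings$wtp, n_draws = draws,
                        n_rejected = rejected, trial = subgroup$trial,
                        subgroup = subgroup$label),
                   class = "cea_psa")
  out$summary <- summarise_psa(tab, settings$wtp)
  out$ceac <- ceac(out, settings$wtp_grid)
  out
}

summarise_psa <- function(tab, wtp) {
  q <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  quantities <- list(cost_MT_SMC = tab$cost_mt, qaly_MT_SMC = tab$qaly_mt,
                     cost_SMC = tab$cost_smc, qaly_SMC = tab$qaly_smc,
                     delta_cost = tab$delta_cost, delta_qaly = tab$delta_qaly,
                     nmb = nmb(tab$delta_cost, tab$delta_qaly, wtp))
  purrr::imap_dfr(quantities, function(x, nm) {
    ci <- q(x)
    tibble::tibble(quantity = nm, mean = mean(x), ci_low = ci[1], ci_high = ci[2])
  })
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA draws in which
#' thrombectomy with standard care has positive net monetary benefit over
#' standard care alone.
#'
#' @param psa A `cea_psa` object (or its per-draw tibble with columns
#'   `delta_cost`, `delta_qaly`).
#' @param wtp_grid Willingness-to-pay grid (USD/QALY).
#' @return Tibble with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e5, by = 2500)) {
  tab <- if (inherits(psa, "cea_psa")) psa$draws else tibble::as_tibble(psa)
  if (nrow(tab) == 0) abort_validation("psa", "no draws")
  tibble::tibble(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) {
      mean(nmb(tab$delta_cost, tab$delta_qaly, w) > 0)
    }, numeric(1))
  )
}

#' Probability that thrombectomy is cost-effective at a threshold
#'
#' @param psa A `cea_psa` object.
#' @param wtp Willingness-to-pay threshold(s).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp) {
  vapply(wtp, function(w) {
    mean(nmb(psa$draws$delta_cost, psa$draws$delta_qaly, w) > 0)
  }, numeric(1))
}
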