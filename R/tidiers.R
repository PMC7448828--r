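# broom-style tidiers for fitted/result objects.

#' Tidy a Markov cohort result
#'
#' @param x A `cea_markov` object.
#' @param ... Unused.
#' @return `tidy()` returns the cycle-by-cycle cohort trace; `glance()` the
#'   one-row lifetime totals.
#' @method tidy cea_markov
#' @export
tidy.cea_markov <- function(x, ...) {
  x$trace %||% abort_validation("trace", "markov run executed with trace = FALSE")
}

#' @rdname tidy.cea_markov
#' @method glance cea_markov
#' @export
glance.cea_markov <- function(x, ...) {
  x$totals
}

#' Tidy a deterministic subgroup run
#'
#' @param x A `cea_det` object from [run_deterministic()].
#' @param ... Unused.
#' @return `tidy()` returns per-strategy lifetime outcomes; `glance()` a
#'   one-row tibble with the incremental comparison.
#' @method tidy cea_det
#' @export
tidy.cea_det <- function(x, ...) {
  x$outcomes
}

#' @rdname tidy.cea_det
#' @method glance cea_det
#' @export
glance.cea_det <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(trial = x$trial, subgroup = x$subgroup), x$econ)
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `cea_psa` object.
#' @param ... Unused.
#' @return `tidy()` returns the summary tibble (mean and percentile 95%
#'   credibility interval per quantity); `glance()` a one-row overview with
#'   the expected increments, the ICER of the expected values, the mean NMB
#'   and the probability of cost-effectiveness at the result's threshold.
#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) {
  x$summary
}

#' @rdname tidy.cea_psa
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  m <- function(qty) x$summary$mean[x$summary$quantity == qty]
  dplyr::bind_cols(
    tibble::tibble(trial = x$trial, subgroup = x$subgroup, n_draws = x$n_draws,
                   n_rejected = x$n_rejected),
    icer(m("delta_cost"), m("delta_qaly")),
    tibble::tibble(nmb = m("nmb"), wtp = x$wtp,
                   prob_ce = prob_cost_effective(x, x$wtp))
  )
}
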