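# ggplot2 views of result objects.

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A `cea_psa` object or a CEAC tibble from [ceac()].
#' @param ... Additional CEAC tibbles or `cea_psa` objects to overlay,
#'   named for the legend.
#' @return A ggplot.
#' @export
plot_ceac <- function(x, ...) {
  curves <- c(list(x), list(...))
  if (is.null(names(curves)) || any(names(curves) == "")) {
    labels <- purrr::imap_chr(curves, function(c, i) {
      if (inherits(c, "cea_psa")) paste(c$trial, c$subgroup, sep = "/")
      else paste0("curve ", i)
    })
    nm <- names(curves) %||% labels
    nm[nm == ""] <- labels[nm == ""]
    names(curves) <- nm
  }
  tab <- purrr::imap_dfr(curves, function(c, nm) {
    cc <- if (inherits(c, "cea_psa")) c$ceac else tibble::as_tibble(c)
    dplyr::mutate(cc, group = nm)
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability MT+SMC is cost-effective",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, ...) {
  wtp <- object$wtp
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = sprintf("%s / %s (%d draws)", object$trial,
                                  object$subgroup, object$n_draws)) +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param x A `cea_tornado` tibble from [tornado_analysis()].
#' @param top Number of parameters shown (largest spread first).
#' @return A ggplot.
#' @export
plot_tornado <- function(x, top = 15) {
  stopifnot(inherits(x, "cea_tornado"))
  base <- attr(x, "base")
  tab <- head(tibble::as_tibble(x), top) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter))) |>
    tidyr::pivot_longer(c("icer_low", "icer_high"), names_to = "bound",
                        values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = base, xend = .data$value,
                                       yend = .data$parameter,
                                       colour = .data$bound),
                          linewidth = 4) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = toupper(attr(x, "metric")), y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot cea_tornado
#' @export
autoplot.cea_tornado <- function(object, ...) {
  plot_tornado(object, ...)
}

#' Plot a cohort trace
#'
#' Stacked state occupancy over the cohort's remaining lifetime.
#'
#' @param x A `cea_markov` object run with `trace = TRUE`.
#' @return A ggplot.
#' @export
plot_trace <- function(x) {
  stopifnot(inherits(x, "cea_markov"), !is.null(x$trace))
  tab <- tidyr::pivot_longer(x$trace, dplyr::all_of(STATES),
                             names_to = "state", values_to = "occupancy") |>
    dplyr::mutate(state = factor(.data$state, levels = STATES))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                    fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "Fraction of 90-day survivors") +
    ggplot2::theme_minimal()
}

#' @method autoplot cea_markov
#' @export
autoplot.cea_markov <- function(object, ...) {
  plot_trace(object)
}
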