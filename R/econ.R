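#' Incremental cost-effectiveness ratio with dominance semantics
#'
#' The ICER is the incremental cost per incremental QALY of thrombectomy
#' with standard care over standard care alone. When the intervention is
#' cheaper and more effective the signed (negative) ratio is still reported
#' alongside a `"dominant"` label, mirroring how such cells are printed in
#' published tables; the mirror case is `"dominated"`. A near-zero QALY
#' difference yields an `NA` ratio with an `"undefined"` label.
#'
#' @param delta_cost Incremental cost (USD), intervention minus comparator.
#' @param delta_qaly Incremental QALYs.
#' @return A tibble with columns `delta_cost`, `delta_qaly`, `icer`,
#'   `dominance` (`"dominant"`, `"dominated"`, `"undefined"` or `NA`).
#' @examples
#' icer(1380, 2.085)
#' icer(-24340, 1.968) # dominant
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(length(delta_cost) == length(delta_qaly))
  ratio <- ifelse(abs(delta_qaly) < 1e-12, NA_real_, delta_cost / delta_qaly)
  dominance <- dplyr::case_when(
    abs(delta_qaly) < 1e-12 ~ "undefined",
    delta_cost < 0 & delta_qaly > 0 ~ "dominant",
    delta_cost > 0 & delta_qaly < 0 ~ "dominated",
    TRUE ~ NA_character_
  )
  tibble::tibble(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icer = ratio, dominance = dominance)
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_qaly - delta_cost` at a willingness-to-pay threshold
#' `wtp` (USD per QALY).
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness to pay per QALY, `>= 0`.
#' @return Numeric NMB in USD.
#' @examples
#' nmb(1380, 2.085, 1e5)
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  check_nonneg(wtp, "wtp")
  wtp * delta_qaly - delta_cost
}

#' Comparative economics of two strategy outcomes
#'
#' @param outcomes A data frame with one row per strategy and columns
#'   `strategy`, `cost`, `qaly` (e.g. from [run_strategy()]).
#' @param wtp Willingness-to-pay threshold for the NMB.
#' @return One-row tibble: incremental cost, incremental QALY, ICER,
#'   dominance label and NMB for MT_SMC vs SMC.
#' @export
econ_result <- function(outcomes, wtp = 1e5) {
  mt <- dplyr::filter(outcomes, .data$strategy == "MT_SMC")
  smc <- dplyr::filter(outcomes, .data$strategy == "SMC")
  stopifnot(nrow(mt) == 1, nrow(smc) == 1)
  res <- icer(mt$cost - smc$cost, mt$qaly - smc$qaly)
  res$nmb <- nmb(res$delta_cost, res$delta_qaly, wtp)
  res$wtp <- wtp
  res
}
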