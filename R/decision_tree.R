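#' Split a combined mRS 5/6 probability
#'
#' Trials reporting a combined "mRS 5 or 6" category at 90 days are split
#' into separate mRS 5 and mRS 6 probabilities according to the relative
#' proportions of those two levels in a reference distribution
#' (conventionally the DEFUSE 3 results).
#'
#' @param p56_combined Combined probability mass for mRS 5 and 6.
#' @param reference A full 7-level mRS distribution with `p5 + p6 > 0`.
#' @return Named vector `c(p5, p6)` summing exactly to `p56_combined`.
#' @examples
#' split_mrs56(0.24, c(0.2, 0.2, 0.1, 0.1, 0.16, 0.08, 0.16))
#' @export
split_mrs56 <- function(p56_combined, reference) {
  check_prob(p56_combined, "p56_combined")
  reference <- validate_mrs_distribution(reference, "reference")
  tot <- reference[["mrs5"]] + reference[["mrs6"]]
  if (tot <= 0) {
    abort_validation("reference", "has zero mass on mRS 5 and 6; split ratio undefined")
  }
  p5 <- p56_combined * reference[["mrs5"]] / tot
  c(p5 = p5, p6 = p56_combined - p5) # complement: conserves mass exactly
}

#' Expected imaging cost per strategy
#'
#' Control patients receive CT and CTA. Thrombectomy patients receive CT,
#' then CTA or MRA (frequency `freq_cta_vs_mra`), CTP or MRI (frequency
#' `freq_ctp_vs_mri`), plus the infarct-volume software cost.
#'
#' @param strategy `"MT_SMC"` or `"SMC"`.
#' @param costs A [cea_costs()] object (or its unclassed list).
#' @return Expected imaging cost in USD.
#' @export
imaging_cost <- function(strategy, costs) {
  img <- costs$imaging
  if (strategy == "SMC") {
    return(unname(img[["ct"]] + img[["cta"]]))
  }
  f <- costs$freq_cta_vs_mra
  g <- costs$freq_ctp_vs_mri
  unname(img[["ct"]] +
           f * img[["cta"]] + (1 - f) * img[["mra"]] +
           g * img[["ctp"]] + (1 - g) * img[["mri"]] +
           img[["software"]])
}

acute_tier_cost <- function(costs) {
  c(rep(costs$acute_90d[["mrs0_2"]], 3), rep(costs$acute_90d[["mrs3_5"]], 3),
    costs$acute_90d[["death"]])
}

#' Expected 90-day cost of one strategy arm
#'
#' Imaging, IV-tPA (weighted by per-arm usage frequency), the thrombectomy
#' procedure and physician costs for the MT arm, plus the severity-tiered
#' acute cost expected over the arm's 90-day mRS distribution
#' (mRS 0-2, mRS 3-5 and death tiers).
#'
#' @param arm One-row data frame or named list with `strategy`,
#'   `mrs0`..`mrs6` and `tpa_frequency`.
#' @param costs A [cea_costs()] object.
#' @return Expected per-patient cost of the first 90 days, in USD.
#' @export
acute_expected_cost <- function(arm, costs) {
  p <- validate_mrs_distribution(unlist(arm[MRS_ALL]), "efficacy")
  cost <- imaging_cost(arm$strategy, costs) + arm$tpa_frequency * costs$tpa
  if (arm$strategy == "MT_SMC") {
    cost <- cost + costs$mt_procedure + costs$mt_physician
  }
  unname(cost + sum(p * acute_tier_cost(costs)))
}

#' Expected 90-day utility of an mRS distribution
#'
#' @param efficacy A 7-level mRS distribution.
#' @param utilities A [cea_utilities()] object (mRS 6 carries utility 0).
#' @return Expected utility in `[0, 1]`.
#' @examples
#' acute_expected_utility(c(0.10, 0.23, 0.18, 0.13, 0.12, 0.09, 0.15),
#'                        cea_utilities())
#' @export
acute_expected_utility <- function(efficacy, utilities) {
  p <- validate_mrs_distribution(efficacy, "efficacy")
  unname(sum(p * c(unclass(utilities)[MRS_ALIVE], 0)))
}

#' Evaluate the 90-day decision tree for a subgroup
#'
#' Computes, per strategy, the expected acute-phase (first 90 days) cost and
#' expected utility over the arm's 90-day mRS distribution. These two
#' scalars double as the strategy-specific recurrent-stroke cost and
#' recurrence utility applied in the Markov model, and the mRS distribution
#' initialises the Markov cohort.
#'
#' @param subgroup A [cea_subgroup()] object.
#' @param params A [cea_parameters()] object.
#' @return A tibble with one row per strategy: `strategy`, `cost_90d`,
#'   `utility_90d`, and `mrs0`..`mrs6`.
#' @export
evaluate_decision_tree <- function(subgroup, params) {
  stopifnot(inherits(subgroup, "cea_subgroup"))
  arms <- subgroup$arms
  # plain loop: validation errors must propagate with their own class
  leaves <- lapply(seq_len(nrow(arms)), function(i) {
    arm <- arms[i, ]
    dplyr::bind_cols(
      tibble::tibble(
        strategy = arm$strategy,
        cost_90d = acute_expected_cost(arm, params$costs),
        utility_90d = acute_expected_utility(unlist(arm[MRS_ALL]),
                                             params$utilities)
      ),
      arm[MRS_ALL]
    )
  })
  dplyr::bind_rows(leaves)
}
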