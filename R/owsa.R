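# One-way deterministic sensitivity analysis (tornado).

#' Published low/high thrombectomy efficacy scenarios
#'
#' The composite "MT+SMC efficacy" tornado entry replaces the thrombectomy
#' arm's 90-day mRS distribution with a low- or high-efficacy vector
#' (reported alongside the DAWN-based one-way sensitivity analysis):
#' low = (7, 20, 15, 14, 14.5, 11.5, 18)% and
#' high = (10, 23, 18, 13, 12, 9, 15)% over mRS 0..6.
#'
#' @return List with elements `low` and `high`, each a 7-level mRS
#'   distribution.
#' @export
mt_efficacy_scenarios <- function() {
  list(low = c(mrs0 = 0.07, mrs1 = 0.20, mrs2 = 0.15, mrs3 = 0.14,
               mrs4 = 0.145, mrs5 = 0.115, mrs6 = 0.18),
       high = c(mrs0 = 0.10, mrs1 = 0.23, mrs2 = 0.18, mrs3 = 0.13,
                mrs4 = 0.12, mrs5 = 0.09, mrs6 = 0.15))
}

tornado_metric <- function(subgroup, params, life_table, settings, nmb_based) {
  det <- run_deterministic(subgroup, params, life_table, settings)
  if (nmb_based) det$econ$nmb else det$econ$icer
}

#' One-way (tornado) sensitivity analysis
#'
#' Each uncertain parameter is set, one at a time, to its low and high
#' bound (the printed range for PERT/uniform/range-based beta parameters,
#' the central 95% quantiles for parameters specified by distribution
#' parameters) while all other inputs stay at base case, and the
#' deterministic ICER is recomputed. A composite `mt_efficacy` entry
#' replaces the thrombectomy arm's whole 90-day mRS distribution with the
#' low/high scenario vectors. Entries whose bound fails validation are
#' skipped with a message. An NMB-based tornado (`nmb_based = TRUE`) is
#' available for dominance-heavy subgroups where ICER endpoints are
#' unstable.
#'
#' @param subgroup A [cea_subgroup()] object.
#' @param params A [cea_parameters()] object; ranges come from its
#'   registry (`params$dist`).
#' @param life_table A life table.
#' @param settings A [cea_settings()] object.
#' @param ids Registry ids to vary (default: all).
#' @param efficacy_scenarios Low/high efficacy vectors for the composite
#'   entry, or `NULL` to omit it.
#' @param nmb_based Report NMB endpoints instead of ICER endpoints.
#' @return A tibble of class `cea_tornado`, sorted by decreasing `spread`:
#'   `parameter`, `low`, `high` (parameter bounds), `icer_low`,
#'   `icer_high`, `spread`. The base-case metric is attached as attribute
#'   `"base"`.
#' @export
tornado_analysis <- function(subgroup, params, life_table, settings,
                             ids = NULL,
                             efficacy_scenarios = mt_efficacy_scenarios(),
                             nmb_based = FALSE) {
  life_table <- validate_life_table(life_table)
  reg <- params$dist
  ids <- ids %||% reg$id
  base_metric <- tornado_metric(subgroup, params, life_table, settings, nmb_based)
  entries <- purrr::map_dfr(ids, function(id) {
    row <- reg[reg$id == id, ]
    if (nrow(row) != 1) abort_validation(id, "not in parameter registry")
    vals <- vapply(c(row$low, row$high), function(bound) {
      tryCatch({
        overridden <- set_cea_param(params, id, bound)
        tornado_metric(subgroup, overridden, life_table, settings, nmb_based)
      }, cea_validation_error = function(e) {
        inform(sprintf("tornado: skipping %s bound %.4g (%s)", id, bound,
                       conditionMessage(e)))
        NA_real_
      })
    }, numeric(1))
    tibble::tibble(parameter = id, low = row$low, high = row$high,
                   icer_low = unname(vals[1]), icer_high = unname(vals[2]))
  })
  if (!is.null(efficacy_scenarios)) {
    vals <- vapply(efficacy_scenarios[c("low", "high")], function(eff) {
      sg <- subgroup
      i <- which(sg$arms$strategy == "MT_SMC")
      sg$arms[i, MRS_ALL] <- as.list(validate_mrs_distribution(eff, "mt_efficacy"))
      tornado_metric(sg, params, life_table, settings, nmb_based)
    }, numeric(1))
    entries <- dplyr::bind_rows(entries,
                                tibble::tibble(parameter = "mt_efficacy",
                                               low = NA_real_, high = NA_real_,
                                               icer_low = unname(vals[1]),
                                               icer_high = unname(vals[2])))
  }
  entries <- entries |>
    dplyr::filter(!is.na(.data$icer_low) | !is.na(.data$icer_high)) |>
    dplyr::mutate(spread = abs(.data$icer_high - .data$icer_low)) |>
    dplyr::arrange(dplyr::desc(.data$spread))
  structure(entries, base = base_metric, metric = if (nmb_based) "nmb" else "icer",
            class = c("cea_tornado", class(entries)))
}
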