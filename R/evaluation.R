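# Scenario-level aggregation: RMSE of estimate distributions, RMSE ratios
# between designs, HDIs of the empirical estimate distributions, exclusion
# counts and true/spurious threshold-model selection rates.

#' Root-mean-square error of an estimate distribution
#'
#' \code{sqrt(mean((estimate - truth)^2))}. Computed from the distribution
#' of point estimates across datasets, so it reflects both bias and
#' precision. Scale-free in the sense that inputs and output share units;
#' scenario summaries report it on the percent scale.
#'
#' @param estimates Numeric vector of point estimates (>= 1, NA dropped).
#' @param truth True parameter value.
#' @return Non-negative scalar.
#' @export
rmse <- function(estimates, truth) {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) == 0L)
    stop("no finite estimates to compute an RMSE from", call. = FALSE)
  sqrt(mean((estimates - truth)^2))
}

#' RMSE ratio between the two designs
#'
#' \code{RMSE_categorical / RMSE_continuous} for the same scenario
#' coordinates, method and target; values above 1 favor the continuous
#' design (the denominator).
#'
#' @param rmse_categorical,rmse_continuous RMSEs of the two designs.
#' @return The ratio.
#' @export
rmse_ratio <- function(rmse_categorical, rmse_continuous) {
  if (rmse_continuous == 0)
    stop("zero denominator RMSE", call. = FALSE)
  rmse_categorical / rmse_continuous
}

#' True or apparent threshold for a scenario
#'
#' NEC scenarios have a true threshold (c = 0.20). Log-logistic scenarios
#' have none; accuracy is judged against an apparent threshold, by default
#' equal to the NEC threshold (0.20). The alternative EC5-referenced
#' apparent threshold is available but off by default, because it would
#' inherently favor ECx analysis.
#'
#' @param scn A \code{scenario} object.
#' @param apparent \code{"nec"} (0.20) or \code{"ec5"} (the scenario
#'   curve's true EC5) for log-logistic scenarios.
#' @return Threshold value on the concentration-fraction scale.
#' @export
apparent_threshold_truth <- function(scn, apparent = c("nec", "ec5")) {
  apparent <- match.arg(apparent)
  stopifnot(inherits(scn, "scenario"))
  if (scn$curve_family == "nec") return(scn$truth$threshold)
  if (apparent == "nec") 0.20 else ecx(scn$truth, 0.05)
}

#' Threshold-model selection rates for a scenario
#'
#' @param results List of \code{selection_result} objects (one per
#'   dataset).
#' @return Named vector: \code{rate_selected} (fraction with the threshold
#'   model at the lower criterion value) and \code{rate_strong_weight}
#'   (fraction with threshold-model weight >= 0.9). On NEC scenarios these
#'   are true-selection rates; on log-logistic scenarios, spurious ones.
#' @export
selection_rates <- function(results) {
  if (length(results) == 0L)
    stop("no selection results", call. = FALSE)
  sel <- vapply(results, function(r) r$selected == "threshold", logical(1))
  strong <- vapply(results, function(r) isTRUE(r$strong_evidence),
                   logical(1))
  c(rate_selected = mean(sel), rate_strong_weight = mean(strong))
}

#' Summarize one scenario/method/target cell
#'
#' Aggregates the point estimates of one method for one target across the
#' datasets of a scenario: RMSE on the percent scale, the 95 percent HDI of
#' the empirical estimate distribution, mean estimate and exclusion
#' bookkeeping (excluded fits are dropped from RMSE/HDI but always
#' counted, so survivorship stays visible).
#'
#' @param estimates Point estimates on the concentration-fraction scale
#'   (one per dataset; NA for excluded/failed fits).
#' @param truth True (or apparent) target value, fraction scale.
#' @param scenario_id,method,target Labels for the output row.
#' @param n_excluded Number of excluded fits (defaults to the NA count).
#' @return One-row data frame with columns scenario_id, method, target,
#'   n_fitted, n_excluded, mean_estimate_pct, rmse_pct, hdi_lower_pct,
#'   hdi_upper_pct.
#' @export
summarize_scenario <- function(estimates, truth, scenario_id = NA,
                               method = NA, target = NA,
                               n_excluded = sum(!is.finite(estimates))) {
  ok <- estimates[is.finite(estimates)]
  hdi_est <- if (length(ok) >= 100) hdi(ok) else c(lower = NA_real_,
                                                   upper = NA_real_)
  data.frame(
    scenario_id = scenario_id, method = method, target = target,
    n_fitted = length(ok), n_excluded = n_excluded,
    mean_estimate_pct = if (length(ok)) mean(ok) * 100 else NA_real_,
    rmse_pct = if (length(ok)) rmse(ok, truth) * 100 else NA_real_,
    hdi_lower_pct = unname(hdi_est[1]) * 100,
    hdi_upper_pct = unname(hdi_est[2]) * 100,
    stringsAsFactors = FALSE
  )
}
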