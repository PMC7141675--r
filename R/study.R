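# Study orchestration: configuration presets, the simulate -> fit ->
# select -> evaluate pipeline over the scenario grid, and result
# persistence.

#' Study configuration
#'
#' \code{"desk"} is a reduced-budget preset for interactive use and tests;
#' \code{"paper"} enumerates the full study (36 scenarios x 1000 datasets,
#' full MCMC budget) and runs for hours.
#'
#' @param preset \code{"desk"} or \code{"paper"}.
#' @param ... Overrides: \code{n_datasets}, \code{scenarios} (list of
#'   \code{scenario} objects; NULL means the full grid), \code{methods}
#'   (subset of \code{c("ll3", "nec_mle", "nec_bayes", "piecewise")}),
#'   \code{mcmc}, \code{master_seed}, \code{out_dir}, \code{apparent}.
#' @return Named configuration list.
#' @export
study_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_datasets = if (preset == "paper") 1000L else 20L,
    scenarios = NULL,
    methods = c("ll3", "nec_mle", "nec_bayes", "piecewise"),
    mcmc = mcmc_config(if (preset == "paper") "paper" else "desk"),
    master_seed = 20200408L,
    out_dir = NULL,
    apparent = "nec"
  )
  modifyList(cfg, list(...))
}

fit_one_dataset <- function(ds, scn, config, seed) {
  rows <- list(); k <- 0L
  add <- function(method, target, estimate, lo = NA, hi = NA,
                  excluded = FALSE, reason = NA_character_,
                  criterion = NA_character_, crit_threshold = NA_real_,
                  crit_null = NA_real_, weight_threshold = NA_real_,
                  selected = NA_character_) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      method = method, target = target,
      estimate = estimate, ci_lower = lo, ci_upper = hi,
      excluded = excluded, exclusion_reason = reason,
      criterion = criterion, crit_threshold = crit_threshold,
      crit_null = crit_null, weight_threshold = weight_threshold,
      selected = selected, stringsAsFactors = FALSE)
  }
  safely <- function(expr) tryCatch(expr, error = function(e) {
    warning(sprintf("dataset %s (%s): %s", attr(ds, "seed"), scn$id,
                    conditionMessage(e)), call. = FALSE)
    NULL
  })

  ll3 <- if ("ll3" %in% config$methods) safely(fit_loglogistic3(ds))
  nec <- if ("nec_mle" %in% config$methods) safely(fit_nec_mle(ds))
  pw <- if ("piecewise" %in% config$methods) safely(fit_piecewise(ds))
  bay <- if ("nec_bayes" %in% config$methods)
    safely(fit_nec_bayes(ds, config$mcmc, seed = seed))

  if (!is.null(ll3)) {
    for (tgt in names(ll3$ecx)) {
      z <- ll3$ecx[[tgt]]
      add("ll3", tgt, unname(z["point"]), unname(z["lower"]),
          unname(z["upper"]), ll3$excluded, ll3$exclusion_reason)
    }
  }
  if (!is.null(nec)) {
    selc <- NULL
    if (!is.null(ll3) && !nec$excluded && !ll3$excluded &&
        is.finite(nec$loglik) && is.finite(ll3$loglik))
      selc <- selection_result(aic(nec$loglik, 3), aic(ll3$loglik, 3),
                               "AIC")
    add("nec_mle", "threshold", unname(nec$estimates[["c"]]),
        nec$threshold_ci[1], nec$threshold_ci[2],
        nec$excluded, nec$exclusion_reason,
        criterion = if (!is.null(selc)) "AIC" else NA_character_,
        crit_threshold = if (!is.null(selc)) selc$value_threshold_model
                         else NA_real_,
        crit_null = if (!is.null(selc)) selc$value_null_model else NA_real_,
        weight_threshold = if (!is.null(selc)) selc$weight_threshold_model
                           else NA_real_,
        selected = if (!is.null(selc)) selc$selected else NA_character_)
  }
  if (!is.null(bay)) {
    selc <- NULL
    if (!bay$excluded) {
      bll3 <- safely(fit_ll3_bayes(ds, config$mcmc, seed = seed + 1L))
      if (!is.null(bll3) && !bll3$excluded)
        selc <- selection_result(dic(bay)$dic, dic(bll3)$dic, "DIC")
    }
    add("nec_bayes", "threshold", unname(bay$estimates[["c"]]),
        unname(bay$hdi_c[1]), unname(bay$hdi_c[2]),
        bay$excluded, bay$exclusion_reason,
        criterion = if (!is.null(selc)) "DIC" else NA_character_,
        crit_threshold = if (!is.null(selc)) selc$value_threshold_model
                         else NA_real_,
        crit_null = if (!is.null(selc)) selc$value_null_model else NA_real_,
        weight_threshold = if (!is.null(selc)) selc$weight_threshold_model
                           else NA_real_,
        selected = if (!is.null(selc)) selc$selected else NA_character_)
  }
  if (!is.null(pw)) {
    selc <- NULL
    if (!pw$excluded && is.finite(pw$loglik) &&
        is.finite(pw$null_fit$loglik)) {
      n_units <- nrow(ds)
      selc <- selection_result(aicc(pw$loglik, 3, n_units),
                               aicc(pw$null_fit$loglik, 2, n_units),
                               "AICc")
    }
    add("piecewise", "threshold", unname(pw$estimates[["psi"]]),
        pw$threshold_ci[1], pw$threshold_ci[2],
        pw$excluded, pw$exclusion_reason,
        criterion = if (!is.null(selc)) "AICc" else NA_character_,
        crit_threshold = if (!is.null(selc)) selc$value_threshold_model
                         else NA_real_,
        crit_null = if (!is.null(selc)) selc$value_null_model else NA_real_,
        weight_threshold = if (!is.null(selc)) selc$weight_threshold_model
                           else NA_real_,
        selected = if (!is.null(selc)) selc$selected else NA_character_)
  }
  if (k == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Run the simulation study
#'
#' Executes simulate -> fit (all enabled methods) -> select -> evaluate
#' for every scenario in the configuration. Deterministic given the master
#' seed: each dataset receives a recorded child seed derived from the
#' master seed and its scenario/dataset indices, so scenarios can be run
#' separately or jointly with identical results. Partial failures are
#' recorded per dataset and never abort the grid.
#'
#' @param config A \code{study_config()} list.
#' @return List with \code{results} (per-dataset tidy data frame),
#'   \code{summary} (per-scenario aggregation), and \code{config}. When
#'   \code{config$out_dir} is set, writes \code{results.csv},
#'   \code{summary.csv} and a \code{manifest.json} there.
#' @export
run_study <- function(config = study_config()) {
  scenarios <- config$scenarios
  if (is.null(scenarios)) scenarios <- scenario_grid(config$n_datasets)
  all_rows <- list()
  for (si in seq_along(scenarios)) {
    scn <- scenarios[[si]]
    nd <- if (!is.null(config$n_datasets)) config$n_datasets
          else scn$n_datasets
    for (di in seq_len(nd)) {
      seed <- child_seed(config$master_seed, scn$id, di)
      ds <- simulate_dataset(scn, seed)
      rows <- fit_one_dataset(ds, scn, config, seed)
      if (is.null(rows)) next
      rows <- cbind(data.frame(dataset_id = sprintf("%s_%04d", scn$id, di),
                               scenario_id = scn$id,
                               curve_family = scn$curve_family,
                               slope_class = scn$slope_class,
                               mortality_class = scn$mortality_class,
                               design_name = scn$design_name,
                               seed = seed,
                               stringsAsFactors = FALSE),
                    rows)
      all_rows[[length(all_rows) + 1L]] <- rows
    }
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  summary <- summarize_study(results, scenarios,
                             apparent = config$apparent)
  out <- list(results = results, summary = summary, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(config$out_dir, "results.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    manifest <- list(config = config[setdiff(names(config), "scenarios")],
                     n_scenarios = length(scenarios),
                     package_version =
                       as.character(utils::packageVersion("necbench")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  invisible(out)
}

#' Aggregate per-dataset results into per-scenario summaries
#'
#' @param results Per-dataset results data frame from \code{run_study}.
#' @param scenarios List of the \code{scenario} objects that produced it.
#' @param apparent Apparent-threshold convention for log-logistic
#'   scenarios (see \code{apparent_threshold_truth}).
#' @return Data frame with one row per scenario x method x target: RMSE
#'   (percent), mean estimate, HDI of the estimate distribution, exclusion
#'   counts and selection rates.
#' @export
summarize_study <- function(results, scenarios, apparent = "nec") {
  scn_by_id <- setNames(scenarios,
                        vapply(scenarios, `[[`, character(1), "id"))
  cells <- split(results,
                 list(results$scenario_id, results$method, results$target),
                 drop = TRUE)
  out <- lapply(cells, function(cell) {
    scn <- scn_by_id[[cell$scenario_id[1]]]
    target <- cell$target[1]
    truth <- if (target == "threshold")
      apparent_threshold_truth(scn, apparent)
    else ecx(scn$truth, as.numeric(sub("ec", "", target)) / 100)
    est <- ifelse(cell$excluded, NA_real_, cell$estimate)
    s <- summarize_scenario(est, truth, scenario_id = cell$scenario_id[1],
                            method = cell$method[1], target = target,
                            n_excluded = sum(cell$excluded))
    sel_ok <- !is.na(cell$selected)
    s$n_selection <- sum(sel_ok)
    s$rate_selected <- if (any(sel_ok))
      mean(cell$selected[sel_ok] == "threshold") else NA_real_
    s$rate_strong_weight <- if (any(sel_ok))
      mean(cell$weight_threshold[sel_ok] >= 0.9 - 1e-9) else NA_real_
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$scenario_id, out$method, out$target), ]
}
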