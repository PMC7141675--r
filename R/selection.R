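# Information-criterion comparison of threshold vs non-threshold models:
# AIC (NEC MLE vs LL3 MLE), AICc (piecewise vs no-threshold Firth logistic,
# the one pair with different parameter counts), DIC (Bayesian pair), and
# evidence weights with the 0.9 strong-evidence cutoff.

#' Akaike information criterion
#'
#' @param loglik Log-likelihood at the optimum.
#' @param k Number of free parameters.
#' @return \code{2k - 2 loglik}.
#' @export
aic <- function(loglik, k) 2 * k - 2 * loglik

#' Small-sample corrected AIC
#'
#' @inheritParams aic
#' @param n Sample size; here the number of experimental units (18), since
#'   the binomial likelihood is specified over units.
#' @return \code{AIC + 2k(k+1)/(n-k-1)}.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined for n <= k + 1", call. = FALSE)
  aic(loglik, k) + 2 * k * (k + 1) / (n - k - 1)
}

#' Deviance information criterion
#'
#' Spiegelhalter's DIC: posterior mean deviance plus the effective number
#' of parameters \code{pD = Dbar - D(posterior mean)}.
#'
#' @param fit A converged Bayesian \code{fit_result} (from
#'   \code{fit_nec_bayes} or \code{fit_ll3_bayes}).
#' @return List with \code{dic}, \code{pD}, \code{Dbar}, \code{Dhat}.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "fit_result"), !is.null(fit$loglik_draws))
  if (!fit$converged)
    stop("DIC requires converged chains", call. = FALSE)
  Dbar <- mean(-2 * fit$loglik_draws)
  Dhat <- -2 * bayes_loglik_at(fit, fit$estimates)
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Information-criterion evidence weights
#'
#' @param values Numeric vector of criterion values (lower is better).
#' @return Weights \code{exp(-delta/2)} normalized to sum to 1.
#' @export
ic_weights <- function(values) {
  delta <- values - min(values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Compare a threshold model against its non-threshold comparator
#'
#' @param value_threshold,value_null Criterion values for the threshold
#'   model and the null (non-threshold) model.
#' @param criterion Label: \code{"AIC"}, \code{"AICc"} or \code{"DIC"}.
#' @return A \code{selection_result}: both values, delta, the threshold
#'   model's weight, which model is selected (lower criterion), and the
#'   strong-evidence flag (threshold weight >= 0.9).
#' @export
selection_result <- function(value_threshold, value_null,
                             criterion = c("AIC", "AICc", "DIC")) {
  criterion <- match.arg(criterion)
  stopifnot(is.finite(value_threshold), is.finite(value_null))
  w <- ic_weights(c(value_threshold, value_null))
  structure(list(
    criterion = criterion,
    value_threshold_model = value_threshold,
    value_null_model = value_null,
    delta = value_threshold - value_null,
    weight_threshold_model = w[1],
    selected = if (value_threshold <= value_null) "threshold" else "null",
    # the boundary counts: weight exactly 0.9 is strong evidence, with an
    # epsilon so float round-off cannot flip it
    strong_evidence = w[1] >= 0.9 - 1e-9
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result %s> threshold %.3f vs null %.3f -> %s (w_thr = %.3f%s)\n",
              x$criterion, x$value_threshold_model, x$value_null_model,
              x$selected, x$weight_threshold_model,
              if (x$strong_evidence) ", strong" else ""))
  invisible(x)
}
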