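# Shared fitting infrastructure: binomial log-likelihood, the FitResult
# container, and the confidence-interval-width exclusion rule applied to
# every fitted model.

P_EPS <- 1e-12

binom_loglik <- function(p, y, n) {
  p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
  sum(y * log(p) + (n - y) * log(1 - p))
}

#' Fit result container
#'
#' Common return type of all fitters: point estimates, standard errors,
#' covariance, binomial log-likelihood at the optimum, parameter count and
#' honesty flags. A fit is \code{excluded} when it did not converge or when
#' any reported confidence interval is wider than 100 percentage points on
#' the percent concentration scale (wide intervals proxy for very poor
#' fit, and such models are dropped from downstream accuracy summaries but
#' counted).
#'
#' @param model_tag Short string identifying the model.
#' @param estimates Named numeric vector of parameter estimates.
#' @param se Named numeric vector of standard errors (NA when unavailable).
#' @param vcov Covariance matrix of the estimates or NULL.
#' @param loglik Binomial log-likelihood at the optimum.
#' @param n_params Number of free parameters.
#' @param converged Logical.
#' @param excluded Logical; see Details.
#' @param exclusion_reason NA or a short string.
#' @param extra Optional named list merged into the result.
#' @return An object of class \code{fit_result}.
#' @export
fit_result <- function(model_tag, estimates, se = NULL, vcov = NULL,
                       loglik = NA_real_, n_params = length(estimates),
                       converged = FALSE, excluded = !converged,
                       exclusion_reason = NA_character_, extra = list()) {
  out <- c(list(model_tag = model_tag, estimates = estimates, se = se,
                vcov = vcov, loglik = loglik, n_params = n_params,
                converged = converged, excluded = excluded,
                exclusion_reason = exclusion_reason), extra)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result:", x$model_tag, ">\n")
  est <- rbind(estimate = x$estimates,
               se = if (is.null(x$se)) rep(NA_real_, length(x$estimates))
                    else x$se)
  print(round(est, 4))
  cat("loglik:", format(x$loglik), " k:", x$n_params,
      " converged:", x$converged, " excluded:", x$excluded, "\n")
  if (!is.na(x$exclusion_reason)) cat("reason:", x$exclusion_reason, "\n")
  invisible(x)
}

# CI width rule: width on the percent scale above 100 points -> excluded.
ci_too_wide <- function(lower, upper) {
  !is.finite(lower) || !is.finite(upper) || (upper - lower) * 100 > 100
}

# Mark a fit excluded in place.
exclude_fit <- function(fit, reason) {
  fit$excluded <- TRUE
  fit$exclusion_reason <- reason
  fit
}

dataset_xyn <- function(dataset) {
  d <- as_survival_dataset(as.data.frame(dataset))
  list(x = d$conc_fraction, y = d$n_survived, n = d$n_exposed)
}

# Symmetric-difference Hessian of f at theta; steps scaled to parameter
# magnitude. Used where optimHess would step outside the domain.
num_hessian <- function(f, theta, rel_step = 1e-4) {
  k <- length(theta)
  h <- pmax(abs(theta), 1e-3) * rel_step
  H <- matrix(NA_real_, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(theta + ei + ej) - f(theta + ei - ej) -
             f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Covariance from a Hessian of the *negative* log-likelihood; returns NULL
# when the Hessian is singular or not positive definite (caller decides
# whether that flags or excludes the fit).
vcov_from_hessian <- function(H) {
  if (any(!is.finite(H))) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0)) return(NULL)
  V
}
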