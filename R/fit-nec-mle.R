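# Maximum-likelihood fit of the threshold (NEC) curve. The likelihood is
# piecewise-smooth in the threshold c, with kinks at the observed
# concentrations, so plain quasi-Newton over (l, m, c) is unreliable. The
# fitter profiles c instead: an inner smooth optimization of (l, m) at each
# candidate c (observed concentrations and their midpoints), followed by a
# 1-D refinement of c inside the bracket around the best candidate, where
# the profile likelihood is smooth.

nec_profile_negll <- function(c0, x, y, n, start = NULL) {
  # maximize over (l, m) at fixed threshold c0; theta = (qlogis l, log m)
  negll <- function(th) {
    p <- plogis(th[1]) * exp(-exp(th[2]) * pmax(x - c0, 0))
    -binom_loglik(p, y, n)
  }
  if (is.null(start)) {
    l0 <- min(max(mean(y[x == 0] / n[x == 0]), 0.05), 0.995)
    if (!is.finite(l0)) l0 <- 0.9
    start <- c(qlogis(l0), log(5))
  }
  fit <- tryCatch(
    optim(start, negll, method = "L-BFGS-B",
          lower = c(qlogis(1e-4), log(1e-3)),
          upper = c(qlogis(1 - 1e-7), log(1e4)),
          control = list(maxit = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(value = Inf, par = start))
  fit
}

#' Fit the NEC threshold model by maximum likelihood
#'
#' Maximizes the binomial log-likelihood over (l, m, c) with l in (0, 1],
#' m > 0 and c in [0, max tested concentration]. Optimization is a hybrid
#' profile search over c (see source comments) whose global optimum is
#' checked in the test suite against a dense profile-grid oracle. The
#' delta-method standard error of c comes from the numerically estimated
#' observed information at the optimum; an indefinite Hessian flags the fit
#' (\code{hessian_ok = FALSE}) without excluding it.
#'
#' @param dataset A \code{survival_dataset} or data frame in the same
#'   schema.
#' @return A \code{fit_result} with estimates \code{l, m, c}, the
#'   threshold confidence interval in \code{$threshold_ci}, and ECx values
#'   implied by the fitted curve in \code{$ecx}.
#' @export
fit_nec_mle <- function(dataset) {
  dd <- dataset_xyn(dataset)
  x <- dd$x; y <- dd$y; n <- dd$n
  tag <- "nec_mle"

  if (all(y == n) || all(y == 0) || length(unique(x)) < 3)
    return(exclude_fit(fit_result(tag, c(l = NA, m = NA, c = NA),
                                  converged = FALSE),
                       "no_dose_response_information"))

  xs <- sort(unique(x))
  cand <- sort(unique(c(xs[xs < max(xs)],
                        (xs[-1] + xs[-length(xs)]) / 2)))
  prof <- lapply(cand, function(c0) nec_profile_negll(c0, x, y, n))
  vals <- vapply(prof, `[[`, numeric(1), "value")
  best_i <- which.min(vals)
  warm <- prof[[best_i]]$par

  # smooth 1-D refinement between the data kinks bracketing the best
  # candidate
  lo <- max(c(0, xs[xs < cand[best_i]]))
  hi <- min(c(max(xs), xs[xs > cand[best_i]]))
  refine <- tryCatch(
    optimize(function(c0) nec_profile_negll(c0, x, y, n, start = warm)$value,
             lower = lo, upper = hi, tol = 1e-6),
    error = function(e) NULL)
  if (!is.null(refine) && refine$objective < vals[best_i]) {
    c_hat <- refine$minimum
    negll_min <- refine$objective
  } else {
    c_hat <- cand[best_i]
    negll_min <- vals[best_i]
  }
  inner <- nec_profile_negll(c_hat, x, y, n, start = warm)
  est <- c(l = plogis(inner$par[1]), m = exp(inner$par[2]), c = c_hat)
  ll <- -inner$value

  negll_nat <- function(th) {
    p <- th[1] * exp(-th[2] * pmax(x - th[3], 0))
    -binom_loglik(p, y, n)
  }
  H <- num_hessian(negll_nat, est)
  V <- vcov_from_hessian(H)
  hessian_ok <- !is.null(V)
  se <- if (hessian_ok) setNames(sqrt(diag(V)), names(est))
        else setNames(rep(NA_real_, 3), names(est))

  ci <- if (hessian_ok) c(c_hat - 1.96 * se[["c"]], c_hat + 1.96 * se[["c"]])
        else c(NA_real_, NA_real_)

  fr <- fit_result(tag, est, se = se, vcov = V, loglik = ll, n_params = 3,
                   converged = TRUE, excluded = FALSE,
                   extra = list(threshold_ci = ci, hessian_ok = hessian_ok))
  if (hessian_ok && ci_too_wide(ci[1], ci[2]))
    fr <- exclude_fit(fr, "ci_width_above_100")
  # ECx implied by the fitted threshold curve: c + log(1/(1-q))/m >= c
  fr$ecx <- lapply(c(ec5 = 0.05, ec10 = 0.10, ec50 = 0.50), function(q)
    c(point = c_hat + log(1 / (1 - q)) / est[["m"]]))
  fr
}
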