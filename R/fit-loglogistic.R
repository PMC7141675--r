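# Maximum-likelihood fit of the three-parameter log-logistic curve and
# delta-method ECx estimation (the "ECx analysis" arm of the comparison).

ll3_negll <- function(theta, x, y, n) {
  # theta on transformed scale: (qlogis(d), log b, log e)
  d <- plogis(theta[1]); b <- exp(theta[2]); e <- exp(theta[3])
  p <- ifelse(x == 0, d, d / (1 + exp(b * (log(pmax(x, P_EPS)) - log(e)))))
  -binom_loglik(p, y, n)
}

#' Fit the three-parameter log-logistic model by maximum likelihood
#'
#' Maximizes the binomial log-likelihood over (d, b, e) with a bounded
#' quasi-Newton search on a logit/log-transformed scale and a small
#' multi-start (heuristic start plus perturbations: d from the control
#' mean, e from the concentration nearest 50 percent relative kill, b = 5).
#' Standard errors come from the inverse observed information on the
#' natural scale. ECx estimates with delta-method confidence intervals are
#' attached for the requested effect fractions; the fit is excluded when it
#' does not converge or any ECx interval exceeds 100 percentage points.
#'
#' @param dataset A \code{survival_dataset} (or data frame in the same
#'   schema).
#' @param ecx_q Effect fractions for which ECx estimates are attached.
#' @param n_starts Number of optimizer starts (>= 1).
#' @return A \code{fit_result} with estimates \code{d, b, e} and an
#'   \code{$ecx} list of \code{(point, lower, upper, se)} per effect
#'   fraction.
#' @export
fit_loglogistic3 <- function(dataset, ecx_q = c(0.05, 0.10, 0.50),
                             n_starts = 3L) {
  dd <- dataset_xyn(dataset)
  x <- dd$x; y <- dd$y; n <- dd$n
  tag <- "ll3_mle"

  if (all(y == n) || all(y == 0) || length(unique(x)) < 3)
    return(exclude_fit(fit_result(tag, c(d = NA, b = NA, e = NA),
                                  converged = FALSE),
                       "no_dose_response_information"))

  d0 <- min(max(mean(y[x == 0] / n[x == 0]), 0.05), 0.99)
  if (!is.finite(d0)) d0 <- 0.9
  rel <- (y / n) / d0
  half_idx <- which.min(abs(rel - 0.5) + (x == 0))
  e0 <- max(x[half_idx], min(x[x > 0]))
  # fixed perturbations keep the fit deterministic without touching the
  # caller's RNG stream
  offsets <- list(c(0, 0, 0), c(0.5, -0.7, 0.5), c(-0.5, 0.7, -0.5),
                  c(0.3, 1.2, 0), c(-0.3, -1.2, 0))
  starts <- lapply(offsets[seq_len(min(n_starts, length(offsets)))],
                   function(o) c(qlogis(d0), log(5), log(e0)) + o)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, ll3_negll, x = x, y = y, n = n, method = "L-BFGS-B",
            lower = c(qlogis(1e-4), log(1e-3), log(1e-4)),
            upper = c(qlogis(1 - 1e-6), log(1e3), log(1e2)),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(exclude_fit(fit_result(tag, c(d = NA, b = NA, e = NA),
                                  converged = FALSE), "optimizer_failure"))

  est <- c(d = plogis(best$par[1]), b = exp(best$par[2]),
           e = exp(best$par[3]))
  ll <- -best$value
  converged <- best$convergence == 0

  # observed information on the natural scale
  negll_nat <- function(th) {
    p <- ifelse(x == 0, th[1],
                th[1] / (1 + exp(th[2] * (log(pmax(x, P_EPS)) - log(th[3])))))
    -binom_loglik(p, y, n)
  }
  V <- vcov_from_hessian(num_hessian(negll_nat, est))
  se <- if (is.null(V)) setNames(rep(NA_real_, 3), names(est))
        else setNames(sqrt(diag(V)), names(est))

  fr <- fit_result(tag, est, se = se, vcov = V, loglik = ll, n_params = 3,
                   converged = converged,
                   excluded = !converged,
                   exclusion_reason =
                     if (!converged) "nonconvergence" else NA_character_)
  if (is.null(V) && converged)
    fr <- exclude_fit(fr, "singular_information")

  ecx_list <- lapply(ecx_q, function(q) estimate_ecx(fr, q))
  names(ecx_list) <- paste0("ec", round(ecx_q * 100))
  fr$ecx <- ecx_list
  if (!fr$excluded &&
      any(vapply(ecx_list, function(z) ci_too_wide(z["lower"], z["upper"]),
                 logical(1))))
    fr <- exclude_fit(fr, "ci_width_above_100")
  fr
}

#' Delta-method ECx from a fitted log-logistic model
#'
#' Point estimate \code{e (q/(1-q))^(1/b)} with variance \code{g' V g},
#' where g is the analytic gradient of the ECx formula in (d, b, e) (the
#' gradient with respect to d is zero under the relative-to-intercept ECx
#' definition). The interval is point +/- 1.96 se.
#'
#' @param fit A converged \code{fit_result} from \code{fit_loglogistic3}.
#' @param q Effect fraction in (0, 1).
#' @return Named vector \code{(point, lower, upper, se)} on the
#'   concentration-fraction scale.
#' @export
estimate_ecx <- function(fit, q) {
  check_effect_fraction(q)
  b <- fit$estimates[["b"]]; e <- fit$estimates[["e"]]
  if (!is.finite(b) || !is.finite(e))
    return(c(point = NA_real_, lower = NA_real_, upper = NA_real_,
             se = NA_real_))
  rho <- q / (1 - q)
  point <- e * rho^(1 / b)
  if (is.null(fit$vcov))
    return(c(point = point, lower = NA_real_, upper = NA_real_,
             se = NA_real_))
  g <- c(d = 0,
         b = -point * log(rho) / b^2,
         e = rho^(1 / b))
  v <- drop(t(g) %*% fit$vcov %*% g)
  se <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  c(point = point, lower = point - 1.96 * se, upper = point + 1.96 * se,
    se = se)
}
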