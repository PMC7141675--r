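#' Threshold (NEC) curve parameters
#'
#' Container for the three-parameter no-effect-concentration survival curve
#' \deqn{p(x) = l \exp\{-m (x - c) I(x > c)\},}
#' i.e. survival stays at the control level \code{l} up to the threshold
#' \code{c} and decays exponentially at rate \code{m} beyond it.
#' Concentrations are fractions of full-strength effluent in \code{[0, 1]};
#' percent is a display convention only.
#'
#' @param intercept Survival probability at concentration 0, in (0, 1].
#' @param slope Decay rate per unit concentration fraction, > 0.
#' @param threshold Threshold concentration fraction, in \code{[0, 1)}.
#' @return An object of class \code{nec_params}.
#' @examples
#' p <- nec_params(0.90, 3, 0.20)
#' survival_prob(p, c(0, 0.2, 0.5))
#' @export
nec_params <- function(intercept, slope, threshold) {
  check_number(intercept, "intercept", lower = 0, upper = 1,
               lower_open = TRUE)
  check_number(slope, "slope", lower = 0, lower_open = TRUE)
  check_number(threshold, "threshold", lower = 0, upper = 1,
               upper_open = TRUE)
  structure(list(intercept = intercept, slope = slope,
                 threshold = threshold),
            class = c("nec_params", "drc_params"))
}

#' Three-parameter log-logistic curve parameters
#'
#' Container for the non-threshold comparison curve
#' \deqn{p(x) = d / (1 + \exp\{b(\log x - \log e)\}),}
#' with upper asymptote \code{d} (survival at zero concentration, taken as
#' the x -> 0 limit), slope \code{b} and inflection \code{e} (the EC50).
#'
#' @param intercept Upper asymptote d, in (0, 1].
#' @param slope Unitless slope b, > 0.
#' @param inflection Inflection point e (the EC50), a concentration
#'   fraction > 0.
#' @return An object of class \code{ll3_params}.
#' @examples
#' p <- ll3_params(0.9, 5, 0.3386)
#' survival_prob(p, p$inflection)  # d / 2
#' @export
ll3_params <- function(intercept, slope, inflection) {
  check_number(intercept, "intercept", lower = 0, upper = 1,
               lower_open = TRUE)
  check_number(slope, "slope", lower = 0, lower_open = TRUE)
  check_number(inflection, "inflection", lower = 0, lower_open = TRUE)
  structure(list(intercept = intercept, slope = slope,
                 inflection = inflection),
            class = c("ll3_params", "drc_params"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g outside its admissible range %s%g, %g%s", name, x,
                 if (lower_open) "(" else "[", lower, upper,
                 if (upper_open) ")" else "]"),
         call. = FALSE)
  invisible(x)
}

#' Survival probability of a dose-response curve
#'
#' Evaluates the survival probability at concentration \code{x} for either
#' curve family. Both families are defined on the concentration-fraction
#' scale; \code{x = 0} is handled as the limit for the log-logistic curve.
#'
#' @param params A \code{nec_params} or \code{ll3_params} object.
#' @param x Vector of concentration fractions, all >= 0.
#' @return Vector of survival probabilities in (0, 1].
#' @export
survival_prob <- function(params, x) UseMethod("survival_prob")

#' @export
survival_prob.nec_params <- function(params, x) {
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  excess <- pmax(x - params$threshold, 0)
  params$intercept * exp(-params$slope * excess)
}

#' @export
survival_prob.ll3_params <- function(params, x) {
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  p <- numeric(length(x))
  zero <- x == 0
  p[zero] <- params$intercept
  xp <- x[!zero]
  p[!zero] <- params$intercept /
    (1 + exp(params$slope * (log(xp) - log(params$inflection))))
  p
}

#' Analytic ECx of a dose-response curve
#'
#' Solves the curve for the concentration producing a relative survival
#' reduction of \code{q} (e.g. \code{q = 0.05} for the EC5). ECx is defined
#' relative to the curve's own intercept: survival at the returned
#' concentration equals \code{(1 - q) * intercept}. For the NEC curve this
#' is \code{c + log(1/(1-q))/m}; for the log-logistic curve
#' \code{e * (q/(1-q))^(1/b)}.
#'
#' @param params A \code{nec_params} or \code{ll3_params} object.
#' @param q Effect fraction in (0, 1); may be a vector.
#' @return Concentration fraction(s) at which survival is
#'   \code{(1 - q) * intercept}.
#' @examples
#' ecx(nec_params(0.9, 3, 0.2), 0.5)  # 0.4310, Table of true EC50s
#' @export
ecx <- function(params, q) UseMethod("ecx")

#' @export
ecx.nec_params <- function(params, q) {
  check_effect_fraction(q)
  params$threshold + log(1 / (1 - q)) / params$slope
}

#' @export
ecx.ll3_params <- function(params, q) {
  check_effect_fraction(q)
  params$inflection * (q / (1 - q))^(1 / params$slope)
}

check_effect_fraction <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("effect fraction 'q' must lie strictly in (0, 1)", call. = FALSE)
  invisible(q)
}

#' Log-logistic curve matched to an NEC curve
#'
#' Builds the non-threshold comparison curve for a given NEC curve: same
#' intercept, slope taken from the same slope class, and inflection set to
#' the analytic EC50 of the NEC curve so that both curves halve survival at
#' the same concentration.
#'
#' @param nec A \code{nec_params} object.
#' @param slope_b Slope for the log-logistic curve (the benchmark uses the same
#'   numeric value as the NEC slope class: 3, 5 or 10).
#' @return A \code{ll3_params} object.
#' @export
matched_loglogistic <- function(nec, slope_b = nec$slope) {
  stopifnot(inherits(nec, "nec_params"))
  ll3_params(intercept = nec$intercept, slope = slope_b,
             inflection = ecx(nec, 0.5))
}

#' Round half-up on a given number of decimals
#'
#' Base \code{round()} rounds half to even; printed reference values use
#' conventional half-up rounding, so comparisons against them go through
#' this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
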