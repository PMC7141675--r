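# Test helpers: noise-free dataset construction and independent oracles
# (profile grids, unpenalized IRLS, profile-likelihood CIs) used to check
# the fitters' optima. Oracles deliberately use different optimization
# paths (nlminb on raw parameter scales, dense grids) than the fitters.

make_noisefree_dataset <- function(params, design_name = "continuous") {
  d <- build_design(design_name)
  p <- survival_prob(params, d$conc_fraction)
  as_survival_dataset(data.frame(
    conc_fraction = d$conc_fraction,
    n_exposed = d$n_exposed,
    n_survived = as.integer(round(d$n_exposed * p))
  ))
}

oracle_binom_ll <- function(p, y, n) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (n - y) * log(1 - p))
}

# Profile-grid oracle for the NEC MLE: dense grid over the threshold with
# an inner nlminb over (l, m) on the raw scale from several starts.
oracle_nec_profile <- function(ds, c_grid = seq(0, 0.6, length.out = 201)) {
  x <- ds$conc_fraction; y <- ds$n_survived; n <- ds$n_exposed
  prof_one <- function(c0) {
    obj <- function(th) -oracle_binom_ll(
      th[1] * exp(-th[2] * pmax(x - c0, 0)), y, n)
    starts <- list(c(0.9, 3), c(0.9, 10), c(0.85, 5), c(0.95, 15))
    vals <- vapply(starts, function(s)
      tryCatch(nlminb(s, obj, lower = c(1e-4, 1e-3),
                      upper = c(1 - 1e-9, 1e4))$objective,
               error = function(e) Inf), numeric(1))
    min(vals)
  }
  vals <- vapply(c_grid, prof_one, numeric(1))
  list(c = c_grid[which.min(vals)], loglik = -min(vals), negll = vals)
}

# Profile-grid oracle for the piecewise breakpoint: dense grid over psi,
# each point evaluated with the Firth fit of the constrained model.
oracle_piecewise_profile <- function(ds, grid_size = 201) {
  x <- ds$conc_fraction; y <- ds$n_survived; n <- ds$n_exposed
  grid <- seq(min(x) + 1e-6, max(x) - 1e-6, length.out = grid_size)
  pls <- vapply(grid, function(ps)
    tryCatch(fit_firth_logistic(cbind(1, pmax(x - ps, 0)), y, n)$ploglik,
             error = function(e) -Inf), numeric(1))
  list(psi = grid[which.max(pls)], ploglik = max(pls))
}

# Profile-likelihood CI for the EC50 (= e) of the LL3 model: profile over
# log(e) with an inner nlminb over (d, b); the CI is where the profile
# deviance crosses qchisq(0.95, 1).
oracle_ll3_profile_ci_e <- function(ds, e_hat, ll_hat) {
  x <- ds$conc_fraction; y <- ds$n_survived; n <- ds$n_exposed
  prof <- function(e0) {
    obj <- function(th) {
      p <- ifelse(x == 0, th[1],
                  th[1] / (1 + exp(th[2] * (log(pmax(x, 1e-12)) - log(e0)))))
      -oracle_binom_ll(p, y, n)
    }
    -nlminb(c(0.9, 5), obj, lower = c(1e-4, 1e-3),
            upper = c(1 - 1e-9, 1e3))$objective
  }
  cut <- ll_hat - qchisq(0.95, 1) / 2
  le_grid <- log(e_hat) + seq(-1.5, 1.5, length.out = 121)
  pl <- vapply(exp(le_grid), prof, numeric(1))
  inside <- pl >= cut
  if (!any(inside)) return(c(NA_real_, NA_real_))
  exp(range(le_grid[inside]))
}

# Plain (unpenalized) IRLS logistic fit, as the asymptotic comparator for
# the Firth fit.
oracle_irls_logistic <- function(X, y, n) {
  fit <- glm(cbind(y, n - y) ~ X - 1, family = binomial())
  unname(coef(fit))
}
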