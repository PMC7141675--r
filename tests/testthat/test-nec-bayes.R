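reduced_cfg <- mcmc_config("desk", warmup = 1000L, iter = 3000L, thin = 3L)

test_that("HDI is the shortest contiguous interval", {
  # uniform grid: any 95%-mass window has length ~0.95
  h <- hdi(seq(0, 1, length.out = 2001))
  expect_equal(unname(h["upper"] - h["lower"]), 0.95, tolerance = 1e-3)
  # standard normal: closed-form quantiles
  set.seed(42)
  h <- hdi(rnorm(1e5))
  expect_equal(unname(h["lower"]), -1.96, tolerance = 0.05)
  expect_equal(unname(h["upper"]), 1.96, tolerance = 0.05)
  # bimodal mixture: a single wide interval spanning both modes (no
  # disjoint pieces), hence an overestimated HDI
  set.seed(43)
  bim <- c(rnorm(5e4, -5, 0.3), rnorm(5e4, 5, 0.3))
  h <- hdi(bim)
  expect_lt(unname(h["lower"]), -4)
  expect_gt(unname(h["upper"]), 4)
  expect_error(hdi(rnorm(50)), "100")
})

test_that("prior-only run recovers the uniform intercept prior", {
  dd <- list(x = rep(0, 5), y = rep(9L, 5), n = rep(10L, 5))
  cfg <- mcmc_config("desk", n_chains = 1L, warmup = 2000L, iter = 40000L,
                     thin = 40L)
  ch <- necbench:::run_chains(dd$x, dd$y, dd$n, model = 0L, cfg, seed = 5L,
                              use_lik = FALSE)
  l_draws <- as.vector(ch$draws[, , "l"])
  ks <- suppressWarnings(stats::ks.test(l_draws, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampler recovers a conjugate Beta posterior", {
  # control-only data with slope and threshold fixed: p = l for every
  # unit, so the posterior of l under its U(0,1) prior is
  # Beta(1 + sum(y), 1 + sum(n - y))
  y <- c(9L, 8L, 10L, 9L, 9L, 10L)
  n <- rep(10L, 6)
  a <- 1 + sum(y); b <- 1 + sum(n - y)
  cfg <- mcmc_config("desk", warmup = 2000L, iter = 20000L, thin = 5L)
  ch <- necbench:::run_chains(rep(0, 6), y, n, model = 0L, cfg, seed = 2L,
                              fixed = c(FALSE, TRUE, TRUE),
                              init = c(0.5, 5, 0.3))
  l_draws <- as.vector(ch$draws[, , "l"])
  mc_se <- sd(l_draws) / sqrt(necbench:::ess_basic(
    matrix(l_draws, nrow = 1)))
  expect_lt(abs(mean(l_draws) - a / (a + b)), 4 * mc_se + 1e-4)
  expect_equal(sd(l_draws), sqrt(a * b / ((a + b)^2 * (a + b + 1))),
               tolerance = 0.15)
})

test_that("Bayesian NEC fit respects prior support and converges", {
  scn <- scenario("nec", "steep", "medium", "continuous")
  ds <- simulate_dataset(scn, 31L)
  fit <- fit_nec_bayes(ds, reduced_cfg, seed = 9L)
  expect_true(fit$converged)
  expect_false(fit$excluded)
  draws <- fit$posterior
  expect_true(all(draws[, , "l"] > 0 & draws[, , "l"] < 1))
  expect_true(all(draws[, , "m"] > 0 & draws[, , "m"] < 20))
  expect_true(all(draws[, , "c"] > 0))
  expect_true(all(fit$rhat < 1.05))
  # point estimate near the generating threshold
  expect_lt(abs(fit$estimates[["c"]] - 0.20), 0.08)
  expect_type(fit$posterior_median, "double")
})

test_that("pooled posterior summaries are invariant to chain order", {
  scn <- scenario("nec", "intermediate", "medium", "categorical")
  ds <- simulate_dataset(scn, 8L)
  fit <- fit_nec_bayes(ds, reduced_cfg, seed = 3L)
  perm <- fit$posterior[c(3, 1, 2), , ]
  expect_equal(mean(perm[, , "c"]), unname(fit$estimates[["c"]]))
  expect_equal(unname(hdi(as.vector(perm[, , "c"]))),
               unname(fit$hdi_c))
})

test_that("posterior concentrates where the data place the threshold", {
  # zero mortality at and below 0.5, total kill above: the threshold must
  # sit near 0.5 and the HDI must exclude zero
  d <- build_design("continuous")
  x <- d$conc_fraction
  ds <- as_survival_dataset(data.frame(
    conc_fraction = x, n_exposed = 10L,
    n_survived = ifelse(x <= 0.5, 10L, 0L)))
  fit <- fit_nec_bayes(ds, reduced_cfg, seed = 17L)
  expect_gt(unname(fit$hdi_c["lower"]), 0.3)
  expect_lt(unname(fit$estimates[["c"]]), 0.85)
})

test_that("fits are reproducible given a seed", {
  scn <- scenario("nec", "steep", "low", "categorical")
  ds <- simulate_dataset(scn, 12L)
  f1 <- fit_nec_bayes(ds, reduced_cfg, seed = 77L)
  f2 <- fit_nec_bayes(ds, reduced_cfg, seed = 77L)
  expect_identical(f1$posterior, f2$posterior)
})
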