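test_that("categorical design matches the recommended layout", {
  d <- build_design("categorical")
  expect_equal(nrow(d), 18L)
  expect_equal(sum(d$n_exposed), 180L)
  levels <- sort(unique(d$conc_fraction))
  expect_equal(levels, c(0, 0.0625, 0.125, 0.25, 0.5, 1))
  expect_true(all(table(d$conc_fraction) == 3L))
})

test_that("continuous design is log-spaced and nests the categorical levels", {
  d <- build_design("continuous")
  expect_equal(nrow(d), 18L)
  expect_equal(sum(d$conc_fraction == 0), 3L)
  nz <- sort(d$conc_fraction[d$conc_fraction > 0])
  expect_length(nz, 15L)
  expect_equal(round(min(nz), 4), 0.0394)
  expect_equal(max(nz), 1)
  # equally spaced on the natural-log scale
  expect_equal(diff(log(nz)), rep(log(2) / 3, 14))
  # the five non-zero categorical levels reappear exactly
  expect_true(all(c(0.0625, 0.125, 0.25, 0.5, 1) %in% nz))
  expect_error(build_design("nested"), "arg")
})

test_that("scenario grid enumerates 36 cells with the stated truths", {
  grid <- scenario_grid(n_datasets = 5)
  expect_length(grid, 36L)
  expect_length(unique(vapply(grid, `[[`, character(1), "id")), 36L)
  scn <- scenario("nec", "steep", "low", "categorical")
  expect_equal(scn$truth$intercept, 0.95)
  expect_equal(scn$truth$slope, 10)
  expect_equal(scn$truth$threshold, 0.20)
  lls <- scenario("loglogistic", "intermediate", "high", "continuous")
  expect_s3_class(lls$truth, "ll3_params")
  expect_equal(lls$truth$intercept, 0.85)
  expect_equal(lls$truth$inflection, ecx(nec_params(0.85, 5, 0.2), 0.5))
})

test_that("simulated datasets are reproducible and pass the control filter", {
  scn <- scenario("nec", "steep", "low", "categorical")
  d1 <- simulate_dataset(scn, 99L)
  d2 <- simulate_dataset(scn, 99L)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(nrow(d1), 18L)
  expect_true(all(d1$n_survived >= 0 & d1$n_survived <= d1$n_exposed))
  for (s in 1:50) {
    d <- simulate_dataset(scn, s)
    expect_gte(mean(d$n_survived[d$conc_fraction == 0]), 8)
  }
})

test_that("sub-threshold units follow Binomial(10, intercept)", {
  # steep low-mortality curve: all units at x <= 0.20 have p = l = 0.95
  scn <- scenario("nec", "steep", "low", "categorical")
  counts <- integer(0)
  for (s in 1:300) {
    d <- simulate_dataset(scn, 1000L + s)
    counts <- c(counts, d$n_survived[d$conc_fraction <= 0.20 &
                                       d$conc_fraction > 0])
  }
  # sub-threshold non-control units escape the control filter, so their
  # mean must sit within 3 binomial SEs of 10 * 0.95
  se <- sqrt(10 * 0.95 * 0.05 / length(counts))
  expect_lt(abs(mean(counts) - 9.5), 3 * se)
})

test_that("per-level survival matches the generating curve", {
  scn <- scenario("nec", "shallow", "medium", "continuous")
  truth <- scn$truth
  d <- build_design("continuous")
  tot <- numeric(nrow(d))
  n_rep <- 400L
  for (s in seq_len(n_rep)) tot <- tot +
    simulate_dataset(scn, 5000L + s)$n_survived
  p_hat <- tot / (10 * n_rep)
  p_true <- survival_prob(truth, d$conc_fraction)
  se <- sqrt(p_true * (1 - p_true) / (10 * n_rep))
  # conditioning on control acceptance lifts the control mean slightly,
  # so judge non-control units only
  nc <- d$conc_fraction > 0
  expect_true(all(abs(p_hat[nc] - p_true[nc]) < 3 * se[nc] + 1e-9))
})

test_that("control-filter rejections increase with background mortality", {
  count_rej <- function(mort) {
    scn <- scenario("nec", "shallow", mort, "categorical")
    sum(vapply(1:300, function(s)
      attr(simulate_dataset(scn, 7000L + s), "n_rejected"), integer(1)))
  }
  expect_gt(count_rej("high"), count_rej("low"))
})

test_that("dataset CSV round trip is byte-stable and lossless", {
  scn <- scenario("loglogistic", "steep", "medium", "continuous")
  sets <- lapply(1:3, function(s) simulate_dataset(scn, s))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_datasets_csv(sets, f1)
  write_datasets_csv(sets, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_datasets_csv(f1)
  expect_length(back, 3L)
  expect_equal(back[[1]]$n_survived, sets[[1]]$n_survived)
  expect_equal(back[[2]]$conc_fraction, sets[[2]]$conc_fraction)
  expect_equal(attr(back[[3]], "seed"), 3L)
  unlink(c(f1, f2, paste0(c(f1, f2), ".json")))
})

test_that("schema validation rejects malformed datasets", {
  expect_error(as_survival_dataset(data.frame(conc_fraction = 1)),
               "columns")
  expect_error(as_survival_dataset(data.frame(
    conc_fraction = 0.1, n_exposed = 10, n_survived = 11)), "n_survived")
})
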