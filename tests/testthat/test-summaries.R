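test_that("KLD calibration maps 0 to 0, is monotone and saturates at 1", {
  expect_equal(calibrate_kld(0), 0)
  expect_equal(calibrate_kld(0.5), 2 * ((1 + sqrt(1 - exp(-1))) / 2 - 0.5),
               tolerance = 1e-12)
  expect_equal(calibrate_kld(0.5), 0.7951, tolerance = 1e-4)
  grid <- seq(0, 20, 0.01)
  cal <- calibrate_kld(grid)
  expect_true(all(diff(cal) >= 0))
  expect_true(all(cal >= 0 & cal <= 1))
  expect_gt(calibrate_kld(50), 1 - 1e-12)
  expect_error(calibrate_kld(-0.1), class = "mortraj_domain_error")
})

test_that("KLD estimator matches Gaussian closed forms and vanishes on itself", {
  set.seed(77)
  x <- rnorm(10000)
  expect_lt(as.numeric(kld(x, x)), 0.01)

  y <- rnorm(10000, mean = 1)
  expect_lt(abs(as.numeric(kld(x, y)) - 0.5), 0.05)

  z <- rnorm(10000, sd = 2)
  expect_lt(abs(as.numeric(kld(x, z)) - gauss_kld(0, 1, 0, 2)), 0.05)
  # broad-vs-narrow: the density floor makes the estimator conservative
  # (never below the true discrepancy by more than the usual tolerance)
  expect_gt(as.numeric(kld(z, x)), gauss_kld(0, 2, 0, 1) - 0.05)

  # disjoint posteriors: large finite value, flagged
  far <- kld(rnorm(2000, 0, 0.1), rnorm(2000, 10, 0.1))
  expect_true(is.finite(as.numeric(far)))
  expect_true(isTRUE(attr(far, "disjoint")))
  expect_gt(calibrate_kld(as.numeric(far)), 0.999)
})

test_that("derived posteriors reduce to point values for degenerate chains", {
  # constant hazard 0.5: life expectancy exactly 2, ageing rate 0
  fitc <- fake_fit(degenerate_draws(const_params(0.5)))
  dv <- derived_posteriors(fitc, conf.level = 0.95)
  e0 <- dv[dv$name == "e0", ]
  expect_equal(e0$mean, 2, tolerance = 1e-4)
  expect_equal(e0$se, 0)
  expect_equal(dv$mean[dv$name == "ar_4"], 0, tolerance = 1e-6)

  # pure gompertz: ageing rate is b1 at every age
  pg <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0, b0 = -2, b1 = 0.4)
  dv2 <- derived_posteriors(fake_fit(degenerate_draws(pg)))
  expect_equal(dv2$mean[dv2$name %in% c("ar_2", "ar_4", "ar_6")], rep(0.4, 3),
               tolerance = 1e-8)
})

test_that("posterior summaries report SD as SE and quantile credible bounds", {
  rec <- quick_sim(n = 80, seed = 31)
  fit <- run_mcmc(rec, "gompertz",
                  config = chain_config(n_chains = 2, n_iter = 1000,
                                        burn_in = 301, thin = 4),
                  seed = 4)
  dv <- derived_posteriors(fit, ages = c(2, 4))
  expect_setequal(dv$name, c("a0", "a1", "c", "b0", "b1", "p", "e0",
                             "ar_2", "ar_4"))
  for (i in seq_len(nrow(dv))) {
    s <- dv$samples[[i]]
    expect_equal(dv$se[i], sd(s))
    expect_equal(dv$lower[i], unname(quantile(s, 0.025)))
    expect_equal(dv$upper[i], unname(quantile(s, 0.975)))
    expect_true(dv$lower[i] <= dv$upper[i])
  }
  # the central interval brackets the mean for the identified quantities
  # (heavy-tailed ridge parameters like a1 can have mean beyond the 97.5%
  # quantile, which is genuine, not a summary defect)
  for (nm in c("e0", "ar_2", "p", "c")) {
    i <- which(dv$name == nm)
    expect_true(dv$lower[i] <= dv$mean[i] && dv$mean[i] <= dv$upper[i])
  }
})

test_that("group comparisons flag disjoint posteriors and not identical ones", {
  set.seed(41)
  mk <- function(shift, n = 2000) {
    tibble::tibble(
      name = c("e0", "c"),
      mean = shift, se = 0.1, lower = shift - 0.2, upper = shift + 0.2,
      samples = list(rnorm(n, shift, 0.1), rnorm(n, shift, 0.1))
    )
  }
  same <- compare_posteriors(list(a = mk(1), b = mk(1)), vars = c("e0", "c"))
  expect_true(all(same$cal_mean < 0.2))
  expect_false(any(same$evidence))

  apart <- compare_posteriors(list(a = mk(0), b = mk(10)), vars = c("e0", "c"))
  expect_true(all(apart$cal_mean > 0.99))
  expect_true(all(apart$evidence))

  # identical sample vectors give calibrated 0 (within estimator tolerance)
  g <- mk(1)
  self <- compare_posteriors(list(a = g, b = g), vars = "e0")
  expect_lt(self$cal_mean, 0.15)

  # missing variables are skipped with a message
  expect_message(
    miss <- compare_posteriors(list(a = mk(0), b = mk(1)),
                               vars = c("e0", "nope")),
    "skipped"
  )
  expect_equal(nrow(miss), 1L)
})
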