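# helper: one record over a 2000-2010 window
one_record <- function(birth, death, dets, sex = "female") {
  yrs <- as.character(2000:2010)
  det <- matrix(0L, 1, length(yrs), dimnames = list(NULL, yrs))
  det[1, as.character(dets)] <- 1L
  dplyr::bind_cols(
    tibble::tibble(id = paste0("r", birth, death), sex = sex,
                   birth_min = birth, birth_max = birth,
                   death_min = death, death_max = death),
    tibble::as_tibble(det)
  )
}

test_that("log-likelihood separates mortality and detection terms as specified", {
  p <- mortality_params("gompertz", a0 = -0.5, a1 = 1.5, c = 0.75,
                        b0 = -2.6, b1 = 0.35)
  S <- function(x) survivorship(p, x)

  # detected in every alive year with p = 1: detection term vanishes
  rec <- one_record(2000L, 2001L, c(2000, 2001))
  ll <- cmr_log_likelihood(rec, p, 1, entry = "none")
  expect_equal(ll, log(S(1) - S(2)), tolerance = 1e-12)

  # one alive-year detected, one missed, p = 0.5
  rec2 <- one_record(2000L, 2001L, 2000)
  ll2 <- cmr_log_likelihood(rec2, p, 0.5, entry = "none")
  expect_equal(ll2 - log(S(1) - S(2)), 2 * log(0.5), tolerance = 1e-12)

  # right-censored record without imputation: log S at the censoring age
  # plus Bernoulli detection over the four alive years (2 seen, 2 missed)
  cens <- one_record(2000L, NA_integer_, c(2000, 2003))
  cens$death_min <- 2003L
  ll3 <- cmr_log_likelihood(cens, p, 0.5, entry = "none",
                            impute_censored = FALSE)
  expect_equal(ll3, log(S(3)) + 4 * log(0.5), tolerance = 1e-12)
})

test_that("log-likelihood is additive over individuals", {
  pt <- mortality_params("gompertz", a0 = -0.5, a1 = 1.5, c = 0.75,
                         b0 = -2.6, b1 = 0.35)
  strata <- tibble::tibble(sex = "female", start_year = 1999, end_year = 2006,
                           n = 50L, params = list(pt))
  rec <- simulate_cmr(sim_config(strata, p_detect = 0.6,
                                 frac_death_observed = 1), seed = 9)
  win <- study_window(1999, 2022)
  for (entry in c("none", "detected")) {
    total <- cmr_log_likelihood(rec, pt, 0.6, window = win, entry = entry)
    single <- vapply(seq_len(nrow(rec)), function(i) {
      cmr_log_likelihood(rec[i, ], pt, 0.6, window = win, entry = entry)
    }, numeric(1))
    expect_equal(total, sum(single), tolerance = 1e-10)
  }
})

test_that("recorded deviances equal -2 times the recomputed log-likelihood", {
  pt <- mortality_params("gompertz", a0 = -0.5, a1 = 1.5, c = 0.75,
                         b0 = -2.6, b1 = 0.35)
  strata <- tibble::tibble(sex = "female", start_year = 1999, end_year = 2006,
                           n = 60L, params = list(pt))
  rec <- simulate_cmr(sim_config(strata, p_detect = 0.6,
                                 frac_death_observed = 1), seed = 10)
  win <- study_window(1999, 2022)
  fit <- run_mcmc(rec, "gompertz",
                  config = chain_config(n_chains = 1, n_iter = 800,
                                        burn_in = 201, thin = 20),
                  window = win, seed = 5)
  for (i in c(1, 10, nrow(fit$draws))) {
    row <- fit$draws[i, ]
    ll <- cmr_log_likelihood(rec, row_to_params(c(row, family = "gompertz")),
                             row$p, window = win, entry = "detected")
    expect_equal(row$deviance, -2 * ll, tolerance = 1e-8)
  }
})

test_that("latent times respect their integer bounds and degenerate supports", {
  rec <- quick_sim(n = 60, seed = 12)
  fit <- run_mcmc(rec, "gompertz",
                  config = chain_config(n_chains = 2, n_iter = 600,
                                        burn_in = 201, thin = 4),
                  seed = 2)
  lm <- fit$latent_mode
  expect_equal(lm$birth, rec$birth_min)  # births known in this simulation
  dead <- !is.na(rec$death_max)
  expect_true(all(lm$death[dead] >= rec$death_min[dead]))
  expect_true(all(lm$death[dead] <= rec$death_max[dead]))
  expect_true(all(lm$death[dead] >= lm$birth[dead]))
  # deaths never precede the last detection year
  ds <- rec[as.character(1999:2022)]
  last_det <- apply(ds == 1L, 1, function(z) max(which(z)))
  expect_true(all(lm$death[dead] >= (1999:2022)[last_det][dead]))
})

test_that("chains are reproducible and sized by the thinning arithmetic", {
  rec <- quick_sim(n = 40, seed = 13)
  cfg <- chain_config(n_chains = 2, n_iter = 600, burn_in = 201, thin = 4)
  f1 <- run_mcmc(rec, "gompertz", config = cfg, seed = 3)
  f2 <- run_mcmc(rec, "gompertz", config = cfg, seed = 3)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 2 * n_retained(cfg))
  expect_equal(n_retained(cfg), (600 - 201) %/% 4)
  # every retained draw satisfies the parameter constraints
  expect_true(all(f1$draws$a1 > 0))
  expect_true(all(f1$draws$c >= 0))
  expect_true(all(f1$draws$b1 > 0))
  expect_true(all(f1$draws$p > 0 & f1$draws$p < 1))
})

test_that("sampled posterior matches a dense-grid posterior on a gompertz toy", {
  pg <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0, b0 = -2, b1 = 0.5)
  set.seed(99)
  ages <- simulate_lifespans(pg, 150)
  fit <- fit_lifespans(ages, "gompertz", fixed = list(a0 = -30, a1 = 1, c = 0),
                       config = chain_config(n_chains = 3, n_iter = 8000,
                                             burn_in = 2001, thin = 5),
                       seed = 17)

  # independent oracle: 2-d grid integration over (b0, log b1)
  b0g <- seq(-3.5, -0.5, length.out = 161)
  lb1g <- seq(log(0.05), log(2.5), length.out = 161)
  loglik <- outer(b0g, lb1g, Vectorize(function(b0, lb1) {
    pp <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0,
                           b0 = b0, b1 = exp(lb1))
    sum(log(death_pdf(pp, ages))) +
      sum(dnorm(c(b0, lb1), 0, 10, log = TRUE))
  }))
  w <- exp(loglik - max(loglik))
  w <- w / sum(w)
  b1_grid_mean <- sum(w * outer(rep(1, 161), exp(lb1g)))

  b1_draws <- fit$draws$b1
  nb <- 30
  bm <- tapply(b1_draws, rep(seq_len(nb), length.out = length(b1_draws)), mean)
  mcse <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(b1_draws) - b1_grid_mean), 3 * mcse + 0.01)
})

test_that("gelman_rubin matches its definition in degenerate and clear cases", {
  # identical constant chains
  r <- gelman_rubin(matrix(1, 100, 3))
  expect_equal(as.numeric(r), 1)
  expect_true(isTRUE(attr(r, "degenerate")))

  set.seed(5)
  same <- matrix(rnorm(4000), 1000, 4)
  expect_lt(gelman_rubin(same), 1.1)
  expect_gt(gelman_rubin(same), sqrt(1 - 1 / 1000))  # lower bound at B = 0

  apart <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(gelman_rubin(apart), 2)

  expect_error(gelman_rubin(matrix(1, 100, 1)), class = "mortraj_config_error")
  expect_error(gelman_rubin(matrix(1, 5, 3)), class = "mortraj_config_error")
})

test_that("DIC is mean deviance plus effective parameters, zero pD when degenerate", {
  dd <- degenerate_draws(const_params(0.5), n = 50, deviance = 123.4)
  fit <- fake_fit(dd, dhat = 123.4)
  d <- dic(fit)
  expect_equal(as.numeric(d), 123.4)
  expect_equal(attr(d, "p_d"), 0)

  # negative pD is a warning, not an error
  fit2 <- fake_fit(dd, dhat = 200)
  expect_warning(d2 <- dic(fit2), "negative")
  expect_equal(attr(d2, "p_d"), 123.4 - 200)
})

test_that("model selection takes the lowest DIC with complexity tie-breaks", {
  expect_equal(select_model(c(gompertz = 1254.36, weibull = 1297.02,
                              logistic = 1271.40)), "gompertz")
  expect_equal(select_model(c(gompertz = 657.14, weibull = 652.90,
                              logistic = 649.74)), "logistic")
  expect_equal(select_model(c(logistic = 100, gompertz = 100, weibull = 100)),
               "gompertz")
  expect_equal(select_model(tibble::tibble(family = c("weibull", "gompertz"),
                                           dic = c(90, 95))), "weibull")
})

test_that("pure-mortality posteriors concentrate as 1/sqrt(n)", {
  pg <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0, b0 = -2, b1 = 0.5)
  sds <- vapply(c(250, 4000), function(n) {
    set.seed(n)
    ages <- simulate_lifespans(pg, n)
    fit <- fit_lifespans(ages, "gompertz",
                         fixed = list(a0 = -30, a1 = 1, c = 0),
                         config = chain_config(n_chains = 2, n_iter = 3000,
                                               burn_in = 1001, thin = 5),
                         seed = 23)
    sd(fit$draws$b1)
  }, numeric(1))
  # 16-fold n ratio: SD ratio should be near 4
  expect_gt(sds[1] / sds[2], 2)
  expect_lt(sds[1] / sds[2], 8)
})
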