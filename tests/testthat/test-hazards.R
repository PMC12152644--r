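test_that("adult hazard matches its closed forms and limiting cases", {
  g <- mortality_params("gompertz", a0 = -1, a1 = 1, c = 0.1, b0 = 0, b1 = 0.5)
  expect_equal(adult_hazard(g, 0), 1.0)

  w <- mortality_params("weibull", a0 = -1, a1 = 1, c = 0.1, b0 = 1, b1 = 0.3)
  expect_equal(adult_hazard(w, 2.5), 0.3)
  expect_equal(adult_hazard(w, 0), 0.3)

  # weibull at age zero: 0 above shape 1, divergent below
  w2 <- mortality_params("weibull", a0 = -1, a1 = 1, c = 0.1, b0 = 2, b1 = 0.3)
  expect_equal(adult_hazard(w2, 0), 0)
  w05 <- mortality_params("weibull", a0 = -1, a1 = 1, c = 0.1, b0 = 0.5, b1 = 0.3)
  expect_identical(adult_hazard(w05, 0), Inf)

  # logistic with b2 = 0 collapses to gompertz
  set.seed(11)
  for (i in 1:20) {
    b0 <- runif(1, -4, 1); b1 <- runif(1, 0.1, 1); x <- runif(5, 0, 6)
    pg <- mortality_params("gompertz", a0 = -1, a1 = 1, c = 0.1, b0 = b0, b1 = b1)
    pl <- mortality_params("logistic", a0 = -1, a1 = 1, c = 0.1, b0 = b0,
                           b1 = b1, b2 = 0)
    expect_equal(adult_hazard(pl, x), adult_hazard(pg, x), tolerance = 1e-12)
  }

  expect_error(mortality_params("gumbel"), class = "mortraj_config_error")
  expect_error(mortality_params("gompertz", a1 = -1), class = "mortraj_domain_error")
  expect_error(mortality_params("weibull", b0 = -2), class = "mortraj_domain_error")
})

test_that("total hazard is the sum of juvenile, constant and adult parts", {
  p <- mortality_params("gompertz", a0 = 0, a1 = 1, c = 0.1, b0 = -2, b1 = 0.5)
  expect_equal(total_hazard(p, 0), 1 + 0.1 + exp(-2))
  # juvenile term vanishes at large ages
  expect_equal(total_hazard(p, 40), 0.1 + adult_hazard(p, 40), tolerance = 1e-12)
  # degenerate constant-hazard configuration
  pc <- const_params(0.4)
  expect_equal(total_hazard(pc, seq(0, 6, 0.5)), rep(0.4, 13), tolerance = 1e-8)
  expect_error(total_hazard(p, -1), class = "mortraj_domain_error")
})

test_that("cumulative hazard agrees with quadrature and satisfies boundary laws", {
  p <- mortality_params("gompertz", a0 = 0, a1 = 1, c = 0.1, b0 = -2, b1 = 0.5)
  expect_equal(cumulative_hazard(p, 0), 0)
  expect_equal(cumulative_hazard(const_params(0.4), 2), 0.8, tolerance = 1e-6)

  smooth <- list(
    mortality_params("gompertz", a0 = 0, a1 = 1, c = 0.1, b0 = -2, b1 = 0.5),
    mortality_params("weibull", a0 = -0.5, a1 = 1.5, c = 0.3, b0 = 1.7, b1 = 0.4),
    mortality_params("logistic", a0 = -0.5, a1 = 1.5, c = 0.3, b0 = -2,
                     b1 = 0.5, b2 = 0.3)
  )
  for (pr in smooth) {
    for (x in c(0.7, 3, 6)) {
      expect_equal(cumulative_hazard(pr, x),
                   simpson_oracle(function(t) total_hazard(pr, t), 0, x,
                                  n = 30000),
                   tolerance = 1e-6)
    }
  }

  # weibull shape below 1: the hazard diverges at age 0 but its integral
  # is finite; adaptive quadrature handles the endpoint singularity
  w <- mortality_params("weibull", a0 = -0.5, a1 = 1.5, c = 0.3,
                        b0 = 0.6, b1 = 0.4)
  for (x in c(1, 4)) {
    q <- stats::integrate(function(t) total_hazard(w, t), 0, x,
                          rel.tol = 1e-9)$value
    expect_equal(cumulative_hazard(w, x), q, tolerance = 1e-6)
  }
})

test_that("survivorship and cumulative hazard are monotone for random parameters", {
  set.seed(31)
  xs <- seq(0, 8, 0.25)
  for (i in 1:100) {
    fam <- sample(c("gompertz", "weibull", "logistic"), 1)
    pr <- rand_params(fam)
    S <- survivorship(pr, xs)
    U <- cumulative_hazard(pr, xs)
    expect_equal(S[1], 1)
    expect_equal(U[1], 0)
    expect_true(all(diff(S) <= 1e-12))
    expect_true(all(diff(U) >= -1e-12))
    expect_true(all(S >= 0 & S <= 1))  # exp(-U) may underflow to 0
  }
})

test_that("death density integrates to one and equals minus the survival slope", {
  expect_equal(death_pdf(const_params(0.5), 0), 0.5, tolerance = 1e-8)
  set.seed(41)
  for (fam in c("gompertz", "weibull", "logistic")) {
    pr <- rand_params(fam)    # c > 0 by construction
    total <- simpson_oracle(function(t) death_pdf(pr, t), 1e-9, 60, n = 12000)
    expect_gt(total, 0.999)
    expect_lt(total, 1.0001)
    # f = -dS/dx by central difference
    ages <- runif(20, 0.2, 6)
    h <- 1e-5
    fd <- -(survivorship(pr, ages + h) - survivorship(pr, ages - h)) / (2 * h)
    expect_equal(death_pdf(pr, ages), fd, tolerance = 1e-6)
  }
})

test_that("ageing rate has the analytic derivative of log hazard", {
  # pure gompertz: the ageing rate is b1 at every age
  pg <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0, b0 = -2, b1 = 0.4)
  expect_equal(ageing_rate(pg, c(2, 4, 6)), rep(0.4, 3), tolerance = 1e-8)
  # constant hazard: flat log-hazard
  expect_equal(ageing_rate(const_params(0.4), c(2, 4, 6)), rep(0, 3),
               tolerance = 1e-8)
  # full models against a central-difference oracle on log(mu)
  set.seed(51)
  h <- 1e-5
  siler <- mortality_params("gompertz", a0 = 0, a1 = 1, c = 0.05,
                            b0 = -3, b1 = 0.6)
  for (pr in list(siler, rand_params("weibull"), rand_params("logistic"))) {
    for (x in c(0.5, 2, 4.5)) {
      fd <- (log(total_hazard(pr, x + h)) - log(total_hazard(pr, x - h))) / (2 * h)
      expect_equal(ageing_rate(pr, x), fd, tolerance = 1e-6)
    }
  }
  expect_error(ageing_rate(siler, 0), class = "mortraj_domain_error")
})

test_that("life expectancy matches constant-hazard and Monte Carlo oracles", {
  expect_equal(life_expectancy(const_params(0.5)), 2, tolerance = 1e-4)
  expect_equal(life_expectancy(const_params(1.25)), 0.8, tolerance = 1e-4)

  # pure gompertz against the empirical mean of simulated lifespans
  pg <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0, b0 = -2, b1 = 1)
  set.seed(61)
  x <- simulate_lifespans(pg, 2e5)
  e0 <- life_expectancy(pg)
  expect_lt(abs(e0 - mean(x)), 3 * sd(x) / sqrt(length(x)))

  # near-zero hazard: the 100-year cap triggers a truncation warning
  slow <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0,
                           b0 = -30, b1 = 0.01)
  expect_warning(e_tr <- life_expectancy(slow), "truncated")
  expect_true(isTRUE(attr(e_tr, "truncated")))
})

test_that("logistic family with b2 = 0 equals gompertz in every derived quantity", {
  set.seed(71)
  for (i in 1:10) {
    a0 <- runif(1, -2, 1); a1 <- runif(1, 0.5, 2); cc <- runif(1, 0.1, 1)
    b0 <- runif(1, -4, 0); b1 <- runif(1, 0.1, 1)
    pg <- mortality_params("gompertz", a0 = a0, a1 = a1, c = cc, b0 = b0, b1 = b1)
    pl <- mortality_params("logistic", a0 = a0, a1 = a1, c = cc, b0 = b0,
                           b1 = b1, b2 = 0)
    xs <- seq(0, 8, 0.5)
    expect_lt(max(abs(total_hazard(pl, xs) - total_hazard(pg, xs))), 1e-10)
    expect_lt(max(abs(cumulative_hazard(pl, xs) - cumulative_hazard(pg, xs))), 1e-10)
    expect_lt(max(abs(survivorship(pl, xs) - survivorship(pg, xs))), 1e-10)
    expect_lt(max(abs(death_pdf(pl, xs) - death_pdf(pg, xs))), 1e-10)
    expect_lt(abs(life_expectancy(pl) - life_expectancy(pg)), 1e-10)
  }
})

test_that("hazard_curves returns a tidy grid of all derived quantities", {
  p <- mortality_params("gompertz", a0 = -0.5, a1 = 1.5, c = 0.7,
                        b0 = -2.5, b1 = 0.35)
  hc <- hazard_curves(p, ages = seq(0, 6, 0.5))
  expect_s3_class(hc, "tbl_df")
  expect_named(hc, c("age", "hazard", "cumulative_hazard", "survival", "density"))
  expect_equal(hc$density, hc$hazard * hc$survival)
})
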