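#' Adult component of the mortality hazard
#'
#' Evaluates the adult hazard \eqn{\mu_a(x)} of a competing-risk mortality
#' model at ages `x` (years). See [mortality_params()] for the three
#' functional forms. For the Weibull family at `x = 0` the hazard is 0 when
#' `b0 > 1`, `b1` when `b0 = 1`, and diverges (`Inf`) when `b0 < 1`.
#'
#' @param params A [mortality_params()] object.
#' @param x Ages in years (numeric vector, all >= 0).
#' @return Hazard rates (per year), same length as `x`.
#' @export
adult_hazard <- function(params, x) {
  validate_mortality_params(params)
  check_age(x)
  with(params, switch(params$family,
    gompertz = exp(b0 + b1 * x),
    weibull = {
      h <- b0 * b1^b0 * x^(b0 - 1)
      if (b0 == 1) h[x == 0] <- b1
      h
    },
    logistic = {
      k <- b2 * exp(b0) / b1
      exp(b0 + b1 * x) / (1 + k * expm1(b1 * x))
    }
  ))
}

#' Total mortality hazard
#'
#' The competing-risk hazard \eqn{\mu(x) = e^{a_0 - a_1 x} + c + \mu_a(x)}:
#' declining juvenile mortality, age-independent mortality, and the adult
#' component from [adult_hazard()].
#'
#' @inheritParams adult_hazard
#' @return Hazard rates (per year), same length as `x`.
#' @examples
#' p <- mortality_params("gompertz", a0 = 0, a1 = 1, c = 0.1, b0 = -2, b1 = 0.5)
#' total_hazard(p, c(0, 1, 2))
#' @export
total_hazard <- function(params, x) {
  validate_mortality_params(params)
  check_age(x)
  exp(params$a0 - params$a1 * x) + params$c + adult_hazard(params, x)
}

#' Cumulative hazard, survivorship and the distribution of ages at death
#'
#' `cumulative_hazard()` evaluates \eqn{U(x) = \int_0^x \mu(t)\,dt} in
#' closed form (every family in this package integrates analytically;
#' see the methods vignette). `survivorship()` is
#' \eqn{S(x) = e^{-U(x)}}, the probability of surviving from birth to age
#' `x`; `death_pdf()` is the density of ages at death
#' \eqn{f(x) = \mu(x) S(x)}, which integrates to 1 whenever the cumulative
#' hazard diverges (e.g. `c > 0`).
#'
#' @inheritParams adult_hazard
#' @return Numeric vector, same length as `x`: dimensionless cumulative
#'   risk, a survival probability in (0, 1], or a density (per year).
#' @examples
#' p <- mortality_params("gompertz", a0 = 0, a1 = 1, c = 0.1, b0 = -2, b1 = 0.5)
#' survivorship(p, 0:4)
#' @export
cumulative_hazard <- function(params, x) {
  validate_mortality_params(params)
  check_age(x)
  juv <- -exp(params$a0) / params$a1 * expm1(-params$a1 * x)
  juv + params$c * x + adult_cumhaz(params, x)
}

# closed-form total hazard without re-validation; sampler hot path
hazard_fast <- function(params, x) {
  exp(params$a0 - params$a1 * x) + params$c + with(params, switch(params$family,
    gompertz = exp(b0 + b1 * x),
    weibull = b0 * b1^b0 * x^(b0 - 1),
    logistic = exp(b0 + b1 * x) / (1 + b2 * exp(b0) / b1 * expm1(b1 * x))
  ))
}

# closed-form total cumulative hazard without re-validation; used by the
# samplers where parameters are already validated at construction
cumhaz_fast <- function(params, x) {
  # expm1 keeps the juvenile/adult integrals accurate when a1 or b1 is
  # tiny (exp(b1*x) - 1 underflows catastrophically there)
  -exp(params$a0) / params$a1 * expm1(-params$a1 * x) + params$c * x +
    adult_cumhaz(params, x)
}

# closed-form adult cumulative hazard for each family
adult_cumhaz <- function(params, x) {
  with(params, switch(params$family,
    gompertz = exp(b0) / b1 * expm1(b1 * x),
    weibull = (b1 * x)^b0,
    logistic = {
      z <- exp(b0) / b1 * expm1(b1 * x)
      if (b2 == 0) z else log1p(b2 * z) / b2
    }
  ))
}

#' @rdname cumulative_hazard
#' @export
survivorship <- function(params, x) {
  exp(-cumulative_hazard(params, x))
}

#' @rdname cumulative_hazard
#' @export
death_pdf <- function(params, x) {
  total_hazard(params, x) * survivorship(params, x)
}

#' Relative ageing rate of the mortality hazard
#'
#' The ageing (senescence) rate at age `x` is the relative slope of the
#' total hazard, \eqn{d \log \mu(x) / dx = \mu'(x)/\mu(x)}, computed with
#' the analytic derivative of each hazard family. For a pure Gompertz
#' hazard this is the constant `b1`; with juvenile mortality still
#' declining it can be negative.
#'
#' @inheritParams adult_hazard
#' @param x Ages in years, all > 0 (the Weibull derivative diverges at 0).
#' @return Per-year relative slope of the hazard, same length as `x`.
#' @export
ageing_rate <- function(params, x) {
  validate_mortality_params(params)
  if (any(x <= 0)) {
    rlang::abort("ageing_rate requires x > 0", class = "mortraj_domain_error")
  }
  mu <- total_hazard(params, x)
  if (any(mu == 0)) {
    rlang::abort("hazard is zero at a requested age", class = "mortraj_domain_error")
  }
  dmu <- -params$a1 * exp(params$a0 - params$a1 * x) + with(params,
    switch(params$family,
      gompertz = b1 * exp(b0 + b1 * x),
      weibull = b0 * (b0 - 1) * b1^b0 * x^(b0 - 2),
      logistic = {
        k <- b2 * exp(b0) / b1
        dn <- 1 + k * expm1(b1 * x)
        b1 * exp(b0 + b1 * x) * (1 - k) / dn^2
      }
    ))
  dmu / mu
}

#' Life expectancy at birth
#'
#' Expected age at death \eqn{e_0 = \int_0^\infty S(x)\,dx}, computed by
#' composite Simpson quadrature on a uniform age grid. The upper limit
#' starts at `max_age` and doubles until `S(upper) < 1e-6`, capped at
#' `cap`; if survivorship is still above `1e-4` at the cap the truncated
#' value is returned with a warning and attribute `truncated = TRUE`.
#'
#' @inheritParams adult_hazard
#' @param max_age Initial upper integration limit in years (default 6, the
#'   species maximum longevity used throughout the package).
#' @param step Quadrature step in years (default 0.01; life expectancies
#'   of about a year need fine resolution near age 0).
#' @param cap Hard upper limit in years (default 100).
#' @return Life expectancy in years (scalar).
#' @examples
#' # pure constant hazard: e0 = 1/c
#' p <- mortality_params("gompertz", a0 = -30, a1 = 1, c = 0.5, b0 = -30, b1 = 0.1)
#' life_expectancy(p)
#' @export
life_expectancy <- function(params, max_age = 6, step = 0.01, cap = 100) {
  validate_mortality_params(params)
  upper <- max_age
  while (survivorship(params, upper) >= 1e-6 && upper < cap) {
    upper <- min(2 * upper, cap)
  }
  truncated <- FALSE
  s_up <- survivorship(params, upper)
  if (s_up >= 1e-4) {
    truncated <- TRUE
    rlang::warn(sprintf(
      "survivorship still %.2g at the %g-year cap; life expectancy truncated",
      s_up, upper
    ))
  }
  grid <- simpson_grid(0, upper, step)
  e0 <- simpson_integral(survivorship(params, grid), grid[2] - grid[1])
  if (truncated) attr(e0, "truncated") <- TRUE
  e0
}

# uniform grid with an even number of intervals for composite Simpson
simpson_grid <- function(lower, upper, step) {
  n <- ceiling((upper - lower) / step)
  if (n %% 2 == 1) n <- n + 1
  seq(lower, upper, length.out = n + 1)
}

# composite Simpson rule on equally spaced ordinates
simpson_integral <- function(y, h) {
  n <- length(y) - 1
  stopifnot(n >= 2, n %% 2 == 0)
  w <- rep(c(4, 2), length.out = n - 1)
  h / 3 * (y[1] + y[n + 1] + sum(w * y[2:n]))
}

check_age <- function(x) {
  if (any(x < 0)) {
    rlang::abort("ages must be >= 0", class = "mortraj_domain_error")
  }
  invisible(x)
}

#' Evaluate all hazard-derived curves on an age grid
#'
#' Convenience wrapper returning a tidy tibble of the total hazard,
#' cumulative hazard, survivorship and age-at-death density at each age,
#' ready for plotting.
#'
#' @inheritParams adult_hazard
#' @param ages Age grid in years (default `seq(0, 6, 0.05)`).
#' @return A tibble with columns `age`, `hazard`, `cumulative_hazard`,
#'   `survival`, `density`.
#' @export
hazard_curves <- function(params, ages = seq(0, 6, by = 0.05)) {
  tibble::tibble(
    age = ages,
    hazard = total_hazard(params, ages),
    cumulative_hazard = cumulative_hazard(params, ages),
    survival = survivorship(params, ages),
    density = death_pdf(params, ages)
  )
}
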