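# shared fixtures and independent oracles

# a pure constant hazard c: juvenile and adult terms pushed to negligible
const_params <- function(c = 0.5) {
  mortality_params("gompertz", a0 = -30, a1 = 1, c = c, b0 = -30, b1 = 0.1)
}

# random valid parameter sets for property checks
rand_params <- function(family = c("gompertz", "weibull", "logistic")) {
  family <- match.arg(family)
  mortality_params(
    family,
    a0 = stats::runif(1, -2, 1),
    a1 = stats::runif(1, 0.3, 3),
    c = stats::runif(1, 0.05, 1),
    b0 = if (family == "weibull") stats::runif(1, 0.5, 3) else stats::runif(1, -4, 0),
    b1 = stats::runif(1, 0.1, 1),
    b2 = if (family == "logistic") stats::runif(1, 0, 0.5)
  )
}

# composite Simpson quadrature oracle, independent of the closed forms
simpson_oracle <- function(f, lower, upper, n = 2000) {
  if (n %% 2 == 1) n <- n + 1
  x <- seq(lower, upper, length.out = n + 1)
  y <- f(x)
  h <- x[2] - x[1]
  w <- rep(c(4, 2), length.out = n - 1)
  h / 3 * (y[1] + y[n + 1] + sum(w * y[2:n]))
}

# Gaussian KLD closed form: KLD(N(m1, s1^2) || N(m2, s2^2))
gauss_kld <- function(m1, s1, m2, s2) {
  log(s2 / s1) + (s1^2 + (m1 - m2)^2) / (2 * s2^2) - 0.5
}

# hand-built three-record table over a short window (2000-2010):
#  A: known birth 2000, death observed 2003
#  B: known birth 2004, death unobserved (last seen 2005)
#  C: birth unknown (first seen 2006 as adult), death unobserved
small_records <- function() {
  yrs <- as.character(2000:2010)
  det <- matrix(0L, 3, length(yrs), dimnames = list(NULL, yrs))
  det[1, c("2000", "2001", "2003")] <- 1L
  det[2, c("2004", "2005")] <- 1L
  det[3, c("2006", "2007")] <- 1L
  dplyr::bind_cols(
    tibble::tibble(
      id = c("A", "B", "C"),
      sex = c("female", "male", "female"),
      birth_min = c(2000L, 2004L, NA),
      birth_max = c(2000L, 2004L, NA),
      death_min = c(2003L, NA, NA),
      death_max = c(2003L, NA, NA)
    ),
    tibble::as_tibble(det)
  )
}

# one-stratum synthetic dataset, defaults matching the study conditions
quick_sim <- function(n = 200, seed = 1, p_detect = 0.6,
                      params = mortality_params("gompertz", a0 = -0.5,
                                                a1 = 1.5, c = 0.75,
                                                b0 = -2.6, b1 = 0.35),
                      start_year = 1999, end_year = 2006, sex = "female") {
  strata <- tibble::tibble(sex = sex, start_year = start_year,
                           end_year = end_year, n = as.integer(n),
                           params = list(params))
  simulate_cmr(sim_config(strata, p_detect = p_detect), seed = seed)
}

# minimal hand-made fit object for summary/DIC edge cases
fake_fit <- function(draws, family = "gompertz", n_chains = 1,
                     dhat = NULL) {
  structure(list(
    draws = draws, family = family, par_names = par_names_for(family),
    config = chain_config(n_chains = n_chains, n_iter = 200, burn_in = 100,
                          thin = 1),
    priors = default_priors(), entry = "none", fix_p = NA, seed = 1,
    acceptance = NULL, latent_mode = NULL, compact = NULL,
    n_records = NA_integer_,
    dhat_fn = function(params, p) if (is.null(dhat)) NA_real_ else dhat
  ), class = "mortraj_fit")
}

par_names_for <- function(family) {
  c("a0", "a1", "c", "b0", "b1", if (family == "logistic") "b2")
}

# constant-draw tibble for a degenerate posterior
degenerate_draws <- function(params, n = 50, deviance = 100) {
  tibble::tibble(
    chain = 1L, draw = seq_len(n),
    a0 = params$a0, a1 = params$a1, c = params$c,
    b0 = params$b0, b1 = params$b1,
    deviance = deviance
  )
}
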