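#' Fit a mortality model to exactly observed lifespans
#'
#' Metropolis-Hastings sampling of the mortality parameters for
#' continuous, exactly observed ages at death (optionally with
#' right-censored ages): the pure mortality likelihood
#' \eqn{\sum \log f(x_i)} plus \eqn{\sum \log S(x_j)} over censored
#' records, with no detection process and no latent times. Used for
#' simulation studies and as a desk-scale check that the sampler targets
#' the intended posterior; parameters can be pinned with `fixed` to fit
#' sub-models (e.g. a pure Gompertz adult hazard).
#'
#' @param ages Numeric vector of ages (years, > 0).
#' @param family Adult hazard family.
#' @param status 1 = death observed at `ages[i]`, 0 = alive at `ages[i]`
#'   (right-censored). Default all observed.
#' @param fixed Named list of parameters held fixed at the given natural
#'   values (e.g. `list(a0 = -30, a1 = 1, c = 0)`).
#' @param config A [chain_config()]; a reduced protocol is usually enough
#'   at these sample sizes.
#' @param priors A [default_priors()] list.
#' @param seed Integer base seed; chain `k` uses `seed + k`.
#' @return A `mortraj_fit` (without detection probability draws).
#' @export
fit_lifespans <- function(ages, family = c("gompertz", "weibull", "logistic"),
                          status = NULL, fixed = list(),
                          config = chain_config(n_chains = 3, n_iter = 6000,
                                                burn_in = 1001, thin = 5),
                          priors = default_priors(), seed = 1) {
  family <- match.arg(family)
  if (is.null(status)) status <- rep(1L, length(ages))
  stopifnot(length(status) == length(ages), all(ages > 0))
  nm <- par_names(family)
  bad_fixed <- setdiff(names(fixed), nm)
  if (length(bad_fixed)) {
    rlang::abort(paste("unknown fixed parameter(s):",
                       paste(bad_fixed, collapse = ", ")),
                 class = "mortraj_config_error")
  }
  free <- setdiff(nm, names(fixed))
  dead <- status == 1L

  build_params <- function(theta_free) {
    full <- stats::setNames(numeric(length(nm)), nm)
    mask <- log_scale_mask(family)
    v <- theta_free
    v[mask[free]] <- exp(v[mask[free]])
    full[free] <- v
    full[names(fixed)] <- unlist(fixed)
    mortality_params(family, a0 = full[["a0"]], a1 = full[["a1"]],
                     c = full[["c"]], b0 = full[["b0"]], b1 = full[["b1"]],
                     b2 = if (family == "logistic") full[["b2"]])
  }
  loglik <- function(params) {
    ll <- sum(log(hazard_fast(params, ages[dead]))) -
      sum(cumhaz_fast(params, ages[dead]))
    if (any(!dead)) ll <- ll - sum(cumhaz_fast(params, ages[!dead]))
    ll
  }

  npar <- length(free)
  n_ret <- n_retained(config)
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    set.seed((seed + k) %% .Machine$integer.max)
    # crude start: constant hazard at 1/mean age, adult terms small
    c0 <- max(1 / mean(ages), 1e-3)
    init_full <- c(a0 = log(c0), a1 = 0, c = log(c0),
                   b0 = if (family == "weibull") 0 else log(c0) - 2,
                   b1 = log(0.3), if (family == "logistic") c(b2 = log(0.1)))
    theta <- init_full[free] + stats::rnorm(npar, 0, 0.3)
    params <- build_params(theta)
    ll <- loglik(params)
    lprior <- sum(stats::dnorm(theta, priors$mean, priors$sd, log = TRUE))
    scales <- rep(config$proposal_scale, npar)
    acc <- num <- acc_win <- num_win <- numeric(npar)
    draws <- matrix(NA_real_, n_ret, length(nm) + 1,
                    dimnames = list(NULL, c(nm, "deviance")))
    ret <- 0L
    for (iter in seq_len(config$n_iter)) {
      for (j in seq_len(npar)) {
        num_win[j] <- num_win[j] + 1
        theta_new <- theta
        theta_new[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
        params_new <- tryCatch(build_params(theta_new), error = function(e) NULL)
        if (is.null(params_new)) next
        ll_new <- loglik(params_new)
        lprior_new <- sum(stats::dnorm(theta_new, priors$mean, priors$sd,
                                       log = TRUE))
        delta <- ll_new + lprior_new - ll - lprior
        if (is.finite(delta) && log(stats::runif(1)) < delta) {
          theta <- theta_new; params <- params_new
          ll <- ll_new; lprior <- lprior_new
          acc_win[j] <- acc_win[j] + 1
          if (iter > config$burn_in) acc[j] <- acc[j] + 1
        }
        if (iter > config$burn_in) num[j] <- num[j] + 1
      }
      if (iter <= config$burn_in && iter %% config$adapt_interval == 0) {
        rate <- ifelse(num_win > 0, acc_win / num_win, 0.25)
        scales <- pmin(pmax(scales * exp(rate - 0.25), 1e-3), 10)
        acc_win[] <- 0; num_win[] <- 0
      }
      if (iter > config$burn_in && (iter - config$burn_in) %% config$thin == 0) {
        ret <- ret + 1L
        nat <- unlist(params[nm])
        draws[ret, ] <- c(nat, -2 * ll)
      }
    }
    accept <- stats::setNames(ifelse(num > 0, acc / num, NA), free)
    chains[[k]] <- list(draws = draws[seq_len(ret), , drop = FALSE],
                        accept = accept)
  }

  draws <- purrr::map2_dfr(chains, seq_along(chains), function(ch, k) {
    out <- tibble::as_tibble(ch$draws)
    out$chain <- k
    out$draw <- seq_len(nrow(out))
    dplyr::relocate(out, "chain", "draw")
  })
  acceptance <- purrr::map2_dfr(chains, seq_along(chains), function(ch, k) {
    tibble::tibble(chain = k, term = names(ch$accept), rate = ch$accept)
  })
  structure(list(
    draws = draws, family = family, par_names = nm, config = config,
    priors = priors, entry = "none", fix_p = NA, seed = seed,
    acceptance = acceptance, latent_mode = NULL, compact = NULL,
    n_records = length(ages),
    dhat_fn = local({
      ages_ <- ages; dead_ <- dead
      function(params, p) {
        ll <- sum(log(hazard_fast(params, ages_[dead_]))) -
          sum(cumhaz_fast(params, ages_[dead_]))
        if (any(!dead_)) ll <- ll - sum(cumhaz_fast(params, ages_[!dead_]))
        -2 * ll
      }
    })
  ), class = "mortraj_fit")
}
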