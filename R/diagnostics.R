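#' Gelman-Rubin potential scale reduction factor
#'
#' \eqn{\hat R = \sqrt{\{(n-1)/n \; W + B/n\}/W}} with \eqn{W} the mean
#' within-chain variance and \eqn{B/n} the variance of the chain means,
#' for \eqn{m \ge 2} chains of \eqn{n \ge 10} draws. When every chain is
#' an identical constant sequence (\eqn{W = 0}) the statistic is reported
#' as 1 with attribute `degenerate = TRUE`.
#'
#' @param x A numeric matrix (draws in rows, chains in columns) or a list
#'   of equal-length numeric vectors.
#' @return Scalar \eqn{\hat R} (>= 1 up to floating point).
#' @export
gelman_rubin <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  m <- ncol(x); n <- nrow(x)
  if (is.null(m) || m < 2) {
    rlang::abort("gelman_rubin needs at least 2 chains", class = "mortraj_config_error")
  }
  if (n < 10) {
    rlang::abort("gelman_rubin needs at least 10 draws per chain",
                 class = "mortraj_config_error")
  }
  w <- mean(apply(x, 2, stats::var))
  b_over_n <- stats::var(colMeans(x))
  if (w == 0) {
    return(structure(1, degenerate = TRUE))
  }
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Convergence diagnostics for a fitted model
#'
#' @param fit A `mortraj_fit` from [run_mcmc()] or [fit_lifespans()].
#' @param threshold Convergence flag cutoff (default 1.05).
#' @return A tibble with `term`, `rhat` and logical `converged`.
#' @export
rhat <- function(fit, threshold = 1.05) {
  terms <- monitored_terms(fit)
  out <- purrr::map_dbl(terms, function(nm) {
    m <- matrix(fit$draws[[nm]], ncol = fit$config$n_chains)
    as.numeric(gelman_rubin(m))
  })
  tibble::tibble(term = terms, rhat = out, converged = out < threshold)
}

monitored_terms <- function(fit) {
  c(fit$par_names, if (is.null(fit$fix_p) && "p" %in% names(fit$draws)) "p")
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{\bar D} the posterior mean deviance
#' (recorded along the chains) and \eqn{p_D = \bar D - D(\bar\theta)} the
#' effective number of parameters, where \eqn{D(\bar\theta)} evaluates the
#' deviance at the componentwise posterior medians of the parameters
#' (medians are parameterization-equivariant and robust on the curved
#' likelihood ridges of weakly identified parameters, where means are
#' not), with latent birth/death years plugged at their posterior modal
#' values. A
#' negative \eqn{p_D} (a known DIC pathology under strong non-normality)
#' triggers a warning but the value is still returned.
#'
#' @param fit A `mortraj_fit`.
#' @return Scalar DIC with attributes `p_d`, `d_bar`, `d_hat`.
#' @export
dic <- function(fit) {
  d_bar <- mean(fit$draws$deviance)
  # plug-in point: componentwise posterior medians. Medians are
  # parameterization-equivariant and stay on the curved likelihood
  # ridges of weakly identified parameters (a1, b1 -> 0 limits), where
  # componentwise means can land at absurd deviance values
  centre <- vapply(fit$par_names, function(nm) stats::median(fit$draws[[nm]]),
                   numeric(1))
  params <- do.call(mortality_params, c(list(family = fit$family), as.list(centre)))
  p_hat <- if (is.null(fit$fix_p)) stats::median(fit$draws$p) else fit$fix_p
  d_hat <- fit$dhat_fn(params, p_hat)
  p_d <- d_bar - d_hat
  if (is.finite(p_d) && p_d < 0) {
    rlang::warn(sprintf("negative effective number of parameters (pD = %.2f)", p_d))
  }
  structure(d_bar + p_d, p_d = p_d, d_bar = d_bar, d_hat = d_hat)
}

#' Select the mortality family with the lowest DIC
#'
#' Ties are broken toward the family with fewer parameters
#' (gompertz < weibull < logistic).
#'
#' @param dic_values A named numeric vector of DIC values (names are
#'   family names), or a data frame with columns `family` and `dic`.
#' @return The selected family name (character scalar).
#' @export
select_model <- function(dic_values) {
  if (is.data.frame(dic_values)) {
    v <- dic_values$dic
    names(v) <- dic_values$family
    dic_values <- v
  }
  rank <- c(gompertz = 1, weibull = 2, logistic = 3)[names(dic_values)]
  ord <- order(dic_values, rank)
  names(dic_values)[ord[1]]
}

#' Tidy posterior parameter summaries
#'
#' Broom-style one-row-per-parameter summary of a fit: posterior mean,
#' `std.error` (the posterior SD), central credible bounds at
#' `conf.level` (sample quantiles of the pooled draws) and the
#' Gelman-Rubin \eqn{\hat R}.
#'
#' @param x A `mortraj_fit`.
#' @param conf.level Credible level (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @method tidy mortraj_fit
#' @export
tidy.mortraj_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  terms <- monitored_terms(x)
  sm <- purrr::map_dfr(terms, function(nm) {
    v <- x$draws[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = unname(stats::quantile(v, a)),
                   conf.high = unname(stats::quantile(v, 1 - a)))
  })
  if (x$config$n_chains >= 2) {
    sm <- dplyr::left_join(sm, rhat(x)[c("term", "rhat")], by = "term")
  } else {
    sm$rhat <- NA_real_
  }
  sm
}

#' One-row model summary
#'
#' @param x A `mortraj_fit`.
#' @param ... Unused.
#' @return A tibble with the family, data and chain sizes, DIC, effective
#'   number of parameters and worst \eqn{\hat R}.
#' @method glance mortraj_fit
#' @export
glance.mortraj_fit <- function(x, ...) {
  d <- suppressWarnings(dic(x))
  max_rhat <- if (x$config$n_chains >= 2) max(rhat(x)$rhat) else NA_real_
  tibble::tibble(
    family = x$family, n_records = x$n_records,
    n_chains = x$config$n_chains, n_draws = nrow(x$draws),
    dic = as.numeric(d), p_d = attr(d, "p_d"), max_rhat = max_rhat
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
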