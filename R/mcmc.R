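# Metropolis-Hastings machinery: transformed parameterisation, chain
# configuration, the joint sampler over mortality parameters, detection
# probability and latent birth/death years.

#' MCMC chain configuration
#'
#' Defaults follow the full sampling protocol used for the dormouse
#' analyses: 10 parallel chains of 60,000 iterations, burn-in 10,001,
#' thinning every 50, giving `floor((60000 - 10001)/50) = 999` retained
#' draws per chain. Proposal scales are tuned toward 0.25 acceptance
#' during burn-in and frozen afterwards.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain.
#' @param burn_in Iterations discarded (must be < `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param proposal_scale Initial random-walk SD on the transformed scale.
#' @param adapt_interval Iterations between proposal-scale updates during
#'   burn-in.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_chains = 10, n_iter = 60000, burn_in = 10001,
                         thin = 50, proposal_scale = 0.1,
                         adapt_interval = 50) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1, proposal_scale >= 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_scale = proposal_scale,
                 adapt_interval = as.integer(adapt_interval)),
            class = "chain_config")
}

#' @rdname chain_config
#' @param config A `chain_config`.
#' @return `n_retained()`: the number of draws kept per chain.
#' @export
n_retained <- function(config) {
  (config$n_iter - config$burn_in) %/% config$thin
}

#' Weakly informative priors for the sampler
#'
#' Independent Normal(`mean`, `sd`) priors on each mortality parameter on
#' its sampling scale (log scale for positivity-constrained parameters,
#' identity otherwise) and a Uniform(0, 1) prior on the detection
#' probability. At the sample sizes this package targets (hundreds of
#' individuals) the default sd of 10 is dominated by the likelihood.
#'
#' @param mean,sd Prior mean and SD on the transformed scale.
#' @return A list with `mean` and `sd`.
#' @export
default_priors <- function(mean = 0, sd = 10) {
  stopifnot(sd > 0)
  list(mean = mean, sd = sd)
}

# ---- transformed parameterisation --------------------------------------

par_names <- function(family) {
  c("a0", "a1", "c", "b0", "b1", if (family == "logistic") "b2")
}

# log transform for positivity-constrained coordinates
log_scale_mask <- function(family) {
  c(a0 = FALSE, a1 = TRUE, c = TRUE, b0 = identical(family, "weibull"),
    b1 = TRUE, if (family == "logistic") c(b2 = TRUE))
}

theta_from_params <- function(params) {
  nm <- par_names(params$family)
  v <- unlist(params[nm])
  mask <- log_scale_mask(params$family)
  v[mask] <- log(v[mask])
  v
}

params_from_theta <- function(theta, family) {
  mask <- log_scale_mask(family)
  v <- theta
  v[mask] <- exp(v[mask])
  mortality_params(family, a0 = v[["a0"]], a1 = v[["a1"]], c = v[["c"]],
                   b0 = v[["b0"]], b1 = v[["b1"]],
                   b2 = if (family == "logistic") v[["b2"]])
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(z) 1 / (1 + exp(-z))

# ---- the joint sampler --------------------------------------------------

#' Fit a mortality model to CMR records by MCMC
#'
#' Joint Metropolis-Hastings sampling of the mortality parameters, the
#' annual detection probability and the latent birth/death years of every
#' record whose bounds leave them uncertain. One-at-a-time Gaussian
#' random-walk proposals on transformed scales (log for
#' positivity-constrained parameters, logit for `p`) keep every retained
#' draw inside the parameter constraints; latent years are proposed
#' uniformly inside their integer bounds and accepted by the same
#' Metropolis ratio, so bounds are never violated. Chains are seeded
#' `seed + chain` and runs are fully reproducible.
#'
#' @param records A prepared records tibble ([prepare_cmr()]).
#' @param family Adult hazard family (`"gompertz"`, `"weibull"`,
#'   `"logistic"`).
#' @param config A [chain_config()].
#' @param priors A [default_priors()] list.
#' @param window Optional [study_window()].
#' @param seed Integer base seed; chain `k` uses `seed + k`.
#' @param entry Entry-into-sample correction (see
#'   [cmr_log_likelihood()]).
#' @param fix_p Optional fixed detection probability; when supplied `p`
#'   is not sampled.
#' @param max_longevity,impute_censored Death-year imputation for records
#'   with an open upper death bound; see [cmr_log_likelihood()].
#' @param verbose Print a line per chain.
#' @return An object of class `mortraj_fit`; see [tidy.mortraj_fit()],
#'   [glance.mortraj_fit()], [dic()], [rhat()], [derived_posteriors()].
#' @export
run_mcmc <- function(records, family = c("gompertz", "weibull", "logistic"),
                     config = chain_config(), priors = default_priors(),
                     window = NULL, seed = 1,
                     entry = c("detected", "truncated", "none"),
                     fix_p = NULL, max_longevity = 6,
                     impute_censored = TRUE, verbose = FALSE) {
  family <- match.arg(family)
  entry <- match.arg(entry)
  cc <- compact_cmr(records, window, max_longevity = max_longevity,
                    impute_censored = impute_censored)
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    if (verbose) message("chain ", k, "/", config$n_chains)
    chains[[k]] <- run_chain(cc, family, config, priors, entry, fix_p,
                             seed = seed + k)
  }
  nm <- par_names(family)
  draws <- purrr::map2_dfr(chains, seq_along(chains), function(ch, k) {
    out <- tibble::as_tibble(ch$draws)
    out$chain <- k
    out$draw <- seq_len(nrow(out))
    dplyr::relocate(out, "chain", "draw")
  })
  acceptance <- purrr::map2_dfr(chains, seq_along(chains), function(ch, k) {
    tibble::tibble(chain = k, term = names(ch$accept), rate = ch$accept)
  })
  latent_mode <- latent_modes(chains, cc)
  fit <- structure(list(
    draws = draws, family = family, par_names = nm, config = config,
    priors = priors, entry = entry, fix_p = fix_p, seed = seed,
    acceptance = acceptance, latent_mode = latent_mode, compact = cc,
    n_records = cc$n,
    dhat_fn = function(params, p) {
      -2 * loglik_state(params, p, latent_mode$birth, latent_mode$death,
                        cc, entry)
    }
  ), class = "mortraj_fit")
  fit
}

# single chain; returns draw matrix, acceptance rates, latent count tables
run_chain <- function(cc, family, config, priors, entry, fix_p, seed) {
  set.seed(seed %% .Machine$integer.max)
  nm <- par_names(family)
  npar <- length(nm)
  mask <- unname(log_scale_mask(family))
  sample_p <- is.null(fix_p)
  use_entry <- entry == "detected"

  # unvalidated constructor for the inner loop: the transform guarantees
  # the positivity constraints, and numeric overflow surfaces as a
  # non-finite Metropolis ratio (rejected), never as an error
  mkparams <- function(theta) {
    v <- unname(theta)
    v[mask] <- exp(v[mask])
    structure(list(family = family, a0 = v[1], a1 = v[2], c = v[3],
                   b0 = v[4], b1 = v[5], b2 = if (npar == 6L) v[6]),
              class = "mortality_params")
  }

  lat <- init_latent(cc)
  b <- lat$b; d <- lat$d
  dead <- !cc$censored
  dead_idx <- cc$dead_idx; cens_idx <- cc$cens_idx
  # integer age caches: age at death for dead records, censoring age for
  # right-censored ones
  x_dead <- integer(cc$n); x_cens <- integer(cc$n)
  x_dead[dead_idx] <- d[dead_idx] - b[dead_idx]
  x_cens[cens_idx] <- cc$dmin[cens_idx] - b[cens_idx]
  mort_from <- function(st) {
    out <- numeric(cc$n)
    out[dead_idx] <- st$logmass[x_dead[dead_idx] + 1L]
    out[cens_idx] <- st$logS[x_cens[cens_idx] + 1L]
    out
  }

  # crude deterministic initialisation: constant hazard at 1/mean span
  span <- ifelse(dead, pmax(d - b, 1L), pmax(cc$dmin - b, 1L))
  c0 <- max(1 / mean(span), 1e-3)
  theta <- c(a0 = log(c0), a1 = 0, c = log(c0),
             b0 = if (family == "weibull") 0 else log(c0) - 2,
             b1 = log(0.3), if (family == "logistic") c(b2 = log(0.1)))
  names(theta) <- nm
  theta <- theta + stats::rnorm(npar, 0, 0.3)
  dc <- detect_counts(b, d, cc)
  p <- if (sample_p) {
    min(max(sum(dc$D) / max(sum(dc$D + dc$M), 1), 0.05), 0.95)
  } else fix_p
  zp <- if (sample_p) logit(p) + stats::rnorm(1, 0, 0.3) else logit(p)
  p <- inv_logit(zp)

  # state caches
  params <- mkparams(theta)
  st <- surv_table(params, cc$amax)
  mort <- mort_from(st)
  epc <- if (use_entry) entry_p_cache(p, cc)
  p0 <- if (use_entry) p0_from(st, epc, cc)
  ent <- entry_cache(st, p0, b, cc, entry)
  lp <- log(p); lq <- log1p(-p)
  det_sum <- sum(mul0(dc$D, lp)) + sum(mul0(dc$M, lq))
  lprior <- sum(stats::dnorm(theta, priors$mean, priors$sd, log = TRUE))
  mort_sum <- sum(mort); ent_sum <- sum(ent)

  scales <- rep(config$proposal_scale, npar + 1)
  acc <- num <- numeric(npar + 2)
  acc_win <- num_win <- numeric(npar + 1)
  acc_lat <- num_lat <- 0

  unc_b <- which(cc$bmin < cc$bmax)
  unc_d <- which(dead & cc$dmin < cc$dmax)
  unc_b_dead <- dead[unc_b]
  ub_base <- cc$dmin[unc_b]            # censored entries never change
  n_ret <- n_retained(config)
  draws <- matrix(NA_real_, n_ret, npar + 2,
                  dimnames = list(NULL, c(nm, "p", "deviance")))
  bcount <- if (length(unc_b)) {
    matrix(0L, length(unc_b), max(cc$bmax[unc_b] - cc$bmin[unc_b]) + 1L)
  }
  dcount <- if (length(unc_d)) {
    matrix(0L, length(unc_d), max(cc$dmax[unc_d] - cc$dmin[unc_d]) + 1L)
  }
  ret <- 0L

  # two-phase joint proposal: a covariance estimated from the first half
  # of burn-in drives a scale-adapted multivariate random walk through the
  # second half; both covariance and scale are re-estimated at the end of
  # burn-in and frozen afterwards
  q1_burn <- max(config$burn_in %/% 4L, 1L)
  half_burn <- max(config$burn_in %/% 2L, 2L)
  cov_stash <- matrix(NA_real_, config$burn_in %/% 5L + 2L, npar)
  stash_i <- 0L
  chol_cov <- NULL
  joint_scale <- 1
  acc_joint_win <- num_joint_win <- 0
  estimate_chol <- function() {
    if (stash_i < 20L) return(NULL)
    sig <- stats::cov(cov_stash[seq_len(stash_i), , drop = FALSE])
    # only useful when burn-in actually explored the posterior
    if (min(diag(sig)) <= 1e-6) return(NULL)
    tryCatch(chol(sig + diag(1e-8, npar)), error = function(e) NULL)
  }

  accept_full <- function(theta_new) {
    params_new <- mkparams(theta_new)
    st_new <- surv_table(params_new, cc$amax)
    mort_new <- mort_from(st_new)
    p0_new <- if (use_entry) p0_from(st_new, epc, cc)
    ent_new <- entry_cache(st_new, p0_new, b, cc, entry)
    lprior_new <- sum(stats::dnorm(theta_new, priors$mean, priors$sd,
                                   log = TRUE))
    ms <- sum(mort_new); es <- sum(ent_new)
    delta <- ms + es + lprior_new - mort_sum - ent_sum - lprior
    if (is.finite(delta) && log(stats::runif(1)) < delta) {
      theta <<- theta_new; params <<- params_new; st <<- st_new
      mort <<- mort_new; p0 <<- p0_new; ent <<- ent_new
      lprior <<- lprior_new; mort_sum <<- ms; ent_sum <<- es
      TRUE
    } else FALSE
  }

  for (iter in seq_len(config$n_iter)) {
    post <- iter > config$burn_in

    # -- mortality parameter updates (one coordinate at a time) --
    for (j in seq_len(npar)) {
      num_win[j] <- num_win[j] + 1
      theta_new <- theta
      theta_new[j] <- theta[j] + stats::rnorm(1, 0, scales[j])
      if (accept_full(theta_new)) {
        acc_win[j] <- acc_win[j] + 1
        if (post) acc[j] <- acc[j] + 1
      }
      if (post) num[j] <- num[j] + 1
    }

    # -- joint update along the estimated burn-in covariance --
    if (!is.null(chol_cov)) {
      step <- drop(stats::rnorm(npar) %*% chol_cov) *
        joint_scale * 2.38 / sqrt(npar)
      ok <- accept_full(theta + step)
      if (post) {
        num[npar + 2] <- num[npar + 2] + 1
        if (ok) acc[npar + 2] <- acc[npar + 2] + 1
      } else {
        num_joint_win <- num_joint_win + 1
        if (ok) acc_joint_win <- acc_joint_win + 1
      }
    }

    # -- detection probability update (logit random walk) --
    if (sample_p) {
      jp <- npar + 1
      num_win[jp] <- num_win[jp] + 1
      zp_new <- zp + stats::rnorm(1, 0, scales[jp])
      p_new <- inv_logit(zp_new)
      lp_new <- log(p_new); lq_new <- log1p(-p_new)
      det_new <- sum(mul0(dc$D, lp_new)) + sum(mul0(dc$M, lq_new))
      epc_new <- if (use_entry) entry_p_cache(p_new, cc)
      p0_new <- if (use_entry) p0_from(st, epc_new, cc)
      ent_new <- entry_cache(st, p0_new, b, cc, entry)
      es <- sum(ent_new)
      # Uniform(0,1) prior on p plus the logit-scale Jacobian
      delta <- det_new + es + lp_new + lq_new - det_sum - ent_sum - lp - lq
      if (is.finite(delta) && log(stats::runif(1)) < delta) {
        zp <- zp_new; p <- p_new; lp <- lp_new; lq <- lq_new
        det_sum <- det_new; epc <- epc_new; p0 <- p0_new
        ent <- ent_new; ent_sum <- es
        acc_win[jp] <- acc_win[jp] + 1
        if (post) acc[jp] <- acc[jp] + 1
      }
      if (post) num[jp] <- num[jp] + 1
    }

    # -- latent birth years (uniform proposals inside bounds) --
    if (length(unc_b)) {
      ub <- ub_base
      ub[unc_b_dead] <- d[unc_b[unc_b_dead]]
      ub <- pmin(cc$bmax[unc_b], ub)
      wid <- ub - cc$bmin[unc_b] + 1L
      bprop <- cc$bmin[unc_b] +
        as.integer(floor(stats::runif(length(unc_b)) * wid))
      mort_prop <- mort_at(st, bprop, d[unc_b], unc_b, cc)
      dc_prop <- detect_counts_at(bprop, d[unc_b], unc_b, cc)
      ent_prop <- entry_at(st, p0, bprop, unc_b, cc, entry)
      delta <- (mort_prop - mort[unc_b]) + ent_prop - ent[unc_b] +
        (dc_prop$M - dc$M[unc_b]) * lq
      take <- is.finite(delta) & log(stats::runif(length(unc_b))) < delta
      if (any(take)) {
        i <- unc_b[take]
        b[i] <- bprop[take]
        mort_sum <- mort_sum + sum(mort_prop[take] - mort[i])
        ent_sum <- ent_sum + sum(ent_prop[take] - ent[i])
        det_sum <- det_sum + sum(dc_prop$M[take] - dc$M[i]) * lq
        mort[i] <- mort_prop[take]
        ent[i] <- ent_prop[take]
        dc$M[i] <- dc_prop$M[take]
        idead <- i[dead[i]]
        x_dead[idead] <- d[idead] - b[idead]
        icens <- i[cc$censored[i]]
        x_cens[icens] <- cc$dmin[icens] - b[icens]
      }
      acc_lat <- acc_lat + sum(take); num_lat <- num_lat + length(take)
    }

    # -- latent death years --
    if (length(unc_d)) {
      lo <- pmax(cc$dmin[unc_d], b[unc_d])
      wid <- cc$dmax[unc_d] - lo + 1L
      dprop <- lo + as.integer(floor(stats::runif(length(unc_d)) * wid))
      mort_prop <- st$logmass[dprop - b[unc_d] + 1L]
      m_new <- pmin(dprop, cc$last) - pmax(b[unc_d], cc$first) + 1L -
        dc$D[unc_d]
      delta <- (mort_prop - mort[unc_d]) + (m_new - dc$M[unc_d]) * lq
      take <- is.finite(delta) & log(stats::runif(length(unc_d))) < delta
      if (any(take)) {
        i <- unc_d[take]
        d[i] <- dprop[take]
        mort_sum <- mort_sum + sum(mort_prop[take] - mort[i])
        det_sum <- det_sum + sum(m_new[take] - dc$M[i]) * lq
        mort[i] <- mort_prop[take]
        dc$M[i] <- m_new[take]
        x_dead[i] <- d[i] - b[i]
      }
      acc_lat <- acc_lat + sum(take); num_lat <- num_lat + length(take)
    }

    # -- proposal-scale adaptation and covariance estimation (burn-in) --
    if (!post) {
      if (iter %% config$adapt_interval == 0) {
        rate <- ifelse(num_win > 0, acc_win / num_win, 0.25)
        scales <- pmin(pmax(scales * exp(rate - 0.25), 1e-3), 10)
        acc_win[] <- 0; num_win[] <- 0
        if (num_joint_win > 0) {
          joint_scale <- min(max(joint_scale *
                                   exp(acc_joint_win / num_joint_win - 0.25),
                                 0.01), 100)
          acc_joint_win <- num_joint_win <- 0
        }
      }
      if (iter >= q1_burn && (iter - q1_burn) %% 5L == 0L &&
          stash_i < nrow(cov_stash)) {
        stash_i <- stash_i + 1L
        cov_stash[stash_i, ] <- theta
      }
      if (iter == half_burn) {
        chol_cov <- estimate_chol()
        stash_i <- 0L
      }
      if (iter == config$burn_in) {
        new_chol <- estimate_chol()
        if (!is.null(new_chol)) chol_cov <- new_chol
      }
    }

    # -- record retained draw --
    if (post && (iter - config$burn_in) %% config$thin == 0) {
      ret <- ret + 1L
      dev <- -2 * (mort_sum + det_sum + ent_sum)
      nat <- theta
      nat[mask] <- exp(nat[mask])
      draws[ret, ] <- c(nat, p, dev)
      if (length(unc_b)) {
        ix <- cbind(seq_along(unc_b), b[unc_b] - cc$bmin[unc_b] + 1L)
        bcount[ix] <- bcount[ix] + 1L
      }
      if (length(unc_d)) {
        ix <- cbind(seq_along(unc_d), d[unc_d] - cc$dmin[unc_d] + 1L)
        dcount[ix] <- dcount[ix] + 1L
      }
    }
  }

  accept <- c(ifelse(num[1:(npar + 1)] > 0, acc[1:(npar + 1)] / num[1:(npar + 1)], NA),
              if (num[npar + 2] > 0) acc[npar + 2] / num[npar + 2] else NA,
              if (num_lat > 0) acc_lat / num_lat else NA)
  names(accept) <- c(nm, "p", "joint", "latent")
  list(draws = draws[seq_len(ret), , drop = FALSE], accept = accept,
       bcount = bcount, dcount = dcount, unc_b = unc_b, unc_d = unc_d)
}

entry_cache <- function(st, p0, b, cc, entry) {
  switch(entry,
    none = numeric(cc$n),
    detected = -log1p(-p0[b - cc$beta_lo + 1L]),
    truncated = {
      open <- cc$bmin < cc$bmax
      out <- numeric(cc$n)
      out[open] <- -st$logS[cc$first_det[open] - b[open] + 1L]
      out
    }
  )
}

# per-individual pieces evaluated at proposed latent values
mort_at <- function(st, b, d, idx, cc) {
  out <- numeric(length(idx))
  cens <- cc$censored[idx]
  out[!cens] <- st$logmass[d[!cens] - b[!cens] + 1L]
  out[cens] <- st$logS[cc$dmin[idx][cens] - b[cens] + 1L]
  out
}

detect_counts_at <- function(b, d, idx, cc) {
  deff <- ifelse(cc$censored[idx], cc$dmin[idx], d)
  n_alive <- pmin(deff, cc$last) - pmax(b, cc$first) + 1L
  list(D = cc$n_det[idx], M = n_alive - cc$n_det[idx])
}

entry_at <- function(st, p0, b, idx, cc, entry) {
  switch(entry,
    none = numeric(length(idx)),
    detected = -log1p(-p0[b - cc$beta_lo + 1L]),
    truncated = {
      open <- cc$bmin[idx] < cc$bmax[idx]
      out <- numeric(length(idx))
      out[open] <- -st$logS[cc$first_det[idx][open] - b[open] + 1L]
      out
    }
  )
}

# posterior modal latent years pooled across chains (ties -> earlier year)
latent_modes <- function(chains, cc) {
  b <- pmin(cc$bmax, ifelse(cc$censored, cc$dmin, cc$dmax))
  b <- pmax(b, cc$bmin)
  d <- ifelse(cc$censored, NA_integer_, pmax(cc$dmin, b))
  unc_b <- chains[[1]]$unc_b
  unc_d <- chains[[1]]$unc_d
  if (length(unc_b)) {
    tot <- Reduce(`+`, lapply(chains, `[[`, "bcount"))
    b[unc_b] <- cc$bmin[unc_b] + max.col(tot, ties.method = "first") - 1L
  }
  if (length(unc_d)) {
    tot <- Reduce(`+`, lapply(chains, `[[`, "dcount"))
    d[unc_d] <- cc$dmin[unc_d] + max.col(tot, ties.method = "first") - 1L
  }
  # modal deaths can collide with modal births; keep death >= birth
  d <- ifelse(!cc$censored, pmax(d, b), d)
  list(id = cc$id, birth = as.integer(b), death = as.integer(d))
}

#' @export
print.mortraj_fit <- function(x, ...) {
  cat("<mortraj_fit> family =", x$family, "|", x$n_records, "records |",
      nrow(x$draws), "draws (", x$config$n_chains, "chains x",
      n_retained(x$config), ")\n")
  print(tidy(x))
  invisible(x)
}
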