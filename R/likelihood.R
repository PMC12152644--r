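# Internal compact representation of CMR records and the data likelihood.
#
# Ages are integer years throughout: a death in calendar year d of an
# individual born in year b means the continuous lifespan fell in the
# interval [d - b, d - b + 1), so the mortality contribution is the
# interval mass S(x) - S(x + 1) with x = d - b (x = 0 allowed: a death in
# the birth year). An individual alive in year t has survived to age
# t - b; a right-censored record contributes S(death_min - b). Detection
# is annual Bernoulli(p) for every year t with
# birth <= t <= min(death, window end): young-of-year are detectable in
# their birth year, which is what identifies infant mortality from
# marked-animals-only data.

compact_cmr <- function(records, window = NULL, max_longevity = 6,
                        impute_censored = TRUE) {
  window <- cmr_window(records, window)
  ds <- det_summary(records)
  if (anyNA(records$birth_min) || anyNA(records$birth_max) ||
      anyNA(records$death_min)) {
    rlang::abort("records have open birth bounds or missing death_min; run prepare_cmr() first",
                 class = "mortraj_config_error")
  }
  censored <- is.na(records$death_max)
  bmin <- as.integer(records$birth_min)
  bmax <- as.integer(pmin(records$birth_max, ds$first_det))
  if (any(bmin > bmax)) {
    rlang::abort("empty birth support (birth_min > min(birth_max, first detection))",
                 class = "mortraj_validation_error")
  }
  dmin <- as.integer(pmax(records$death_min, ds$last_det))
  dmax <- as.integer(records$death_max)
  if (impute_censored && any(censored)) {
    # open-death records become bounded latent deaths: the species dies
    # by birth + max_longevity, so their death year is imputed like any
    # other and the non-detections near the window end stay informative
    dmax[censored] <- pmax(bmax[censored] + as.integer(max_longevity),
                           dmin[censored])
    censored[censored] <- FALSE
  }
  if (any(!censored & dmin > dmax)) {
    rlang::abort("empty death support (death_min > death_max)",
                 class = "mortraj_validation_error")
  }
  first <- window$first_year
  last <- window$last_year
  amax <- max(last - min(bmin),
              if (any(!censored)) max(dmax[!censored] - bmin[!censored]) else 0L,
              max(dmin - bmin)) + 1L
  cc <- list(
    n = nrow(records), id = records$id,
    bmin = bmin, bmax = bmax, dmin = dmin, dmax = dmax,
    censored = censored,
    first_det = ds$first_det, last_det = ds$last_det, n_det = ds$n_det,
    first = first, last = last, amax = amax,
    beta_lo = min(bmin), beta_hi = max(bmax)
  )
  # geometry of the never-detected probability: for each candidate birth
  # year beta, the number of detectable years m(beta, j) for a death at
  # integer age j, and the age beyond which the window is over. Depends
  # only on the window, so precomputed once.
  betas <- cc$beta_lo:cc$beta_hi
  xs <- pmax(last - betas, 0L)
  J <- max(xs)
  jj <- 0:J
  cc$entry_nb <- length(betas)
  cc$entry_J <- J
  cc$entry_m <- outer(betas, jj, function(b, j) {
    pmax(0L, pmin(b + j, last) - pmax(b, first) + 1L)
  })
  cc$entry_diff_mask <- outer(xs, jj, `>`)[, seq_len(J), drop = FALSE]
  cc$entry_tail_col <- xs + 1L
  cc$entry_xs <- xs
  cc$dead_idx <- which(!censored)
  cc$cens_idx <- which(censored)
  cc
}

# detection-dependent part of the never-detected probability, cached
# between mortality-parameter proposals (depends on p only)
entry_p_cache <- function(p, cc) {
  r <- 1 - p
  R <- r^cc$entry_m
  list(M1 = cc$entry_diff_mask * R[, seq_len(cc$entry_J), drop = FALSE],
       tailR = R[cbind(seq_len(cc$entry_nb), cc$entry_tail_col)])
}

# never-detected probability per candidate birth year from the caches
p0_from <- function(st, epc, cc) {
  J <- cc$entry_J
  tail_term <- st$S[cc$entry_xs + 1L] * epc$tailR
  if (J == 0L) return(tail_term)
  mass <- st$S[1:J] - st$S[2:(J + 1L)]
  drop(epc$M1 %*% mass) + tail_term
}

# initial admissible latent state: birth at its upper bound, death at its
# lower bound (pushed up to the birth year where needed)
init_latent <- function(cc) {
  b <- pmin(cc$bmax, ifelse(cc$censored, cc$dmin, cc$dmax))
  b <- pmax(b, cc$bmin)
  d <- ifelse(cc$censored, NA_integer_, pmax(cc$dmin, b))
  list(b = as.integer(b), d = as.integer(d))
}

# survivorship at integer ages 0..amax and log interval masses
surv_table <- function(params, amax) {
  u <- cumhaz_fast(params, 0:amax)
  S <- exp(-u)
  list(S = S, logS = -u, logmass = log(S[1:amax] - S[2:(amax + 1)]))
}

# product that treats 0 * -Inf as 0 (p = 1 or p = 0 edge cases)
mul0 <- function(a, b) ifelse(a == 0, 0, a * b)

# per-individual mortality log-contribution given a survival table;
# logmass[j] = log(S(j-1) - S(j)), so a death at integer age x (lifespan
# in [x, x+1)) contributes logmass[x + 1]
mort_terms <- function(st, b, d, cc) {
  out <- numeric(cc$n)
  dead <- !cc$censored
  x <- d[dead] - b[dead]
  out[dead] <- st$logmass[x + 1L]
  xc <- cc$dmin[cc$censored] - b[cc$censored]
  out[cc$censored] <- st$logS[xc + 1L]
  out
}

# probability that an individual born in year beta is never detected:
# the integer-age death distribution summed against the detection process
# inside the window, plus a tail term for deaths after the window closes;
# returns a vector over beta = beta_lo..beta_hi
never_detected_prob <- function(st, p, cc) {
  r <- 1 - p
  R <- r^cc$entry_m
  J <- cc$entry_J
  tail_term <- st$S[cc$entry_xs + 1L] *
    R[cbind(seq_len(cc$entry_nb), cc$entry_tail_col)]
  if (J == 0L) return(tail_term)
  mass <- st$S[1:J] - st$S[2:(J + 1L)]
  Q <- matrix(mass, cc$entry_nb, J, byrow = TRUE) * cc$entry_diff_mask
  rowSums(Q * R[, seq_len(J), drop = FALSE]) + tail_term
}

# entry-conditioning log-contribution per individual
entry_terms <- function(st, p, b, cc, entry) {
  switch(entry,
    none = numeric(cc$n),
    detected = {
      p0 <- never_detected_prob(st, p, cc)
      -log1p(-p0[b - cc$beta_lo + 1L])
    },
    truncated = {
      open <- cc$bmin < cc$bmax
      out <- numeric(cc$n)
      out[open] <- -st$logS[cc$first_det[open] - b[open] + 1L]
      out
    }
  )
}

# detected-year and missed-year counts per individual
detect_counts <- function(b, d, cc) {
  deff <- ifelse(cc$censored, cc$dmin, d)
  n_alive <- pmin(deff, cc$last) - pmax(b, cc$first) + 1L
  list(D = cc$n_det, M = n_alive - cc$n_det)
}

#' Log-likelihood of CMR records under a mortality and detection model
#'
#' Evaluates the data log-likelihood used by [run_mcmc()]: for each
#' individual, an age-at-death term (the interval mass
#' \eqn{S(x) - S(x+1)} for a death at integer age \eqn{x}, or
#' \eqn{S(x_{cens})} for a right-censored record), a Bernoulli detection
#' term over every alive year inside the study window, and (by default)
#' conditioning on the individual having been detected at least once —
#' marked-animal data contain no all-zero histories. Additive over
#' individuals; inadmissible latent times give `-Inf`, never an error.
#'
#' @param records A prepared records tibble (see [prepare_cmr()]).
#' @param params A [mortality_params()] object.
#' @param p Annual detection probability in (0, 1].
#' @param birth,death Integer vectors of latent birth/death years; default
#'   to the bounds when these determine them (`birth_min == birth_max`
#'   etc.), otherwise they must be supplied. `death` entries for
#'   right-censored records are ignored.
#' @param window Optional [study_window()].
#' @param entry Entry-into-sample correction: `"detected"` (condition on
#'   at least one detection, the default), `"truncated"` (condition
#'   records with uncertain birth on survival to first capture), or
#'   `"none"`.
#' @param max_longevity Maximum lifespan in years used to bound imputed
#'   death years (default 6).
#' @param impute_censored When `TRUE` (default), records with an open
#'   `death_max` are treated as latent interval deaths bounded by
#'   `birth_max + max_longevity`, so non-detections near the window end
#'   stay informative; when `FALSE` they contribute the survivorship
#'   term \eqn{S(x_{cens})} at the last-detection age instead.
#' @return Scalar log-likelihood.
#' @export
cmr_log_likelihood <- function(records, params, p, birth = NULL, death = NULL,
                               window = NULL,
                               entry = c("detected", "truncated", "none"),
                               max_longevity = 6, impute_censored = TRUE) {
  entry <- match.arg(entry)
  cc <- compact_cmr(records, window, max_longevity = max_longevity,
                    impute_censored = impute_censored)
  lat <- init_latent(cc)
  if (is.null(birth)) {
    if (any(cc$bmin != cc$bmax)) {
      rlang::abort("birth years uncertain; supply `birth`",
                   class = "mortraj_config_error")
    }
    birth <- lat$b
  }
  if (is.null(death)) {
    if (any(!cc$censored & cc$dmin != cc$dmax)) {
      rlang::abort("death years uncertain; supply `death`",
                   class = "mortraj_config_error")
    }
    death <- lat$d
  }
  loglik_state(params, p, as.integer(birth), as.integer(death), cc, entry)
}

# full data log-likelihood for one state; -Inf for inadmissible states
loglik_state <- function(params, p, b, d, cc, entry) {
  dead <- !cc$censored
  ok <- all(b >= cc$bmin & b <= cc$bmax) &&
    all(d[dead] >= pmax(cc$dmin[dead], b[dead]) & d[dead] <= cc$dmax[dead]) &&
    all(b <= cc$first_det) && all(d[dead] >= cc$last_det[dead])
  if (!ok) return(-Inf)
  st <- surv_table(params, cc$amax)
  dc <- detect_counts(b, d, cc)
  if (any(dc$M < 0)) return(-Inf)
  sum(mort_terms(st, b, d, cc)) +
    sum(mul0(dc$D, log(p))) + sum(mul0(dc$M, log1p(-p))) +
    sum(entry_terms(st, p, b, cc, entry))
}
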