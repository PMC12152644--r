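#' Plot posterior mortality and survivorship trajectories
#'
#' `autoplot()` on a fitted model draws the posterior mean and 95%
#' credible band of the age-specific hazard and survivorship (or trace
#' plots of the parameter chains).
#'
#' @param object A `mortraj_fit`.
#' @param type `"trajectory"` (default) or `"trace"`.
#' @param max_age Upper age for the trajectory grid (years).
#' @param max_draws Posterior draws used for the band (subsampled).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mortraj_fit
#' @export
autoplot.mortraj_fit <- function(object, type = c("trajectory", "trace"),
                                 max_age = 6, max_draws = 500, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    long <- tidyr::pivot_longer(
      object$draws[c("chain", "draw", monitored_terms(object))],
      -c("chain", "draw"), names_to = "term", values_to = "value"
    )
    return(
      ggplot2::ggplot(long, ggplot2::aes(.data$draw, .data$value,
                                         colour = factor(.data$chain))) +
        ggplot2::geom_line(linewidth = 0.2) +
        ggplot2::facet_wrap(~term, scales = "free_y") +
        ggplot2::labs(colour = "chain", x = "retained draw", y = NULL)
    )
  }
  bands <- trajectory_bands(object, max_age = max_age, max_draws = max_draws)
  ggplot2::ggplot(bands, ggplot2::aes(.data$age, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL)
}

# posterior mean and credible band of hazard and survivorship curves
trajectory_bands <- function(fit, max_age = 6, max_draws = 500,
                             conf.level = 0.95) {
  draws <- fit$draws
  if (nrow(draws) > max_draws) {
    draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), ]
  }
  ages <- seq(0, max_age, by = 0.05)
  a <- (1 - conf.level) / 2
  par_mat <- as.matrix(draws[fit$par_names])
  hz <- sv <- matrix(NA_real_, nrow(draws), length(ages))
  for (i in seq_len(nrow(draws))) {
    params <- do.call(mortality_params,
                      c(list(family = fit$family), as.list(par_mat[i, ])))
    hz[i, ] <- total_hazard(params, ages)
    sv[i, ] <- survivorship(params, ages)
  }
  band <- function(m, what) {
    tibble::tibble(
      quantity = what, age = ages, mean = colMeans(m),
      lower = apply(m, 2, stats::quantile, a),
      upper = apply(m, 2, stats::quantile, 1 - a)
    )
  }
  dplyr::bind_rows(band(hz, "hazard"), band(sv, "survivorship"))
}

#' Plot posterior densities of derived quantities
#'
#' @param object A [derived_posteriors()] result.
#' @param vars Variables to show (default: all).
#' @param ... Unused.
#' @return A ggplot object with one density panel per variable.
#' @method autoplot mortraj_derived
#' @export
autoplot.mortraj_derived <- function(object, vars = NULL, ...) {
  if (is.null(vars)) vars <- object$name
  long <- object |>
    dplyr::filter(.data$name %in% vars) |>
    dplyr::select("name", "samples") |>
    tidyr::unnest("samples")
  ggplot2::ggplot(long, ggplot2::aes(.data$samples)) +
    ggplot2::geom_density(fill = "grey70", alpha = 0.6) +
    ggplot2::facet_wrap(~name, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density")
}

#' Plot survivorship trajectories for every stratum of a full run
#'
#' @param object A `mortraj_run` from [run_full_analysis()].
#' @param max_age Upper age (years).
#' @param ... Unused.
#' @return A ggplot: survivorship bands per period, faceted by sex.
#' @method autoplot mortraj_run
#' @export
autoplot.mortraj_run <- function(object, max_age = 6, ...) {
  bands <- purrr::imap_dfr(object$fits, function(fam_fits, key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    fam <- object$selected$family[object$selected$sex == parts[1] &
                                    object$selected$period == parts[2]]
    b <- trajectory_bands(fam_fits[[fam]], max_age = max_age, max_draws = 200)
    b$sex <- parts[1]
    b$period <- parts[2]
    b
  })
  bands <- dplyr::filter(bands, .data$quantity == "survivorship")
  ggplot2::ggplot(bands, ggplot2::aes(.data$age, .data$mean,
                                      colour = .data$period,
                                      fill = .data$period)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "age (years)", y = "survivorship S(x)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
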