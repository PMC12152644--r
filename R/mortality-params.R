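#' Competing-risk mortality parameters
#'
#' Constructs the parameter set of a competing-risk (Siler-family) hazard
#' \deqn{\mu(x) = e^{a_0 - a_1 x} + c + \mu_a(x),}
#' the sum of an exponentially declining juvenile term, an age-independent
#' term, and an adult component \eqn{\mu_a(x)} that is one of
#'
#' * `"gompertz"`: \eqn{\mu_a(x) = e^{b_0 + b_1 x}} (exponential increase
#'   with age; with the juvenile and constant terms this is the classical
#'   Siler model),
#' * `"weibull"`: \eqn{\mu_a(x) = b_0 b_1^{b_0} x^{b_0 - 1}} (power
#'   function; increasing but decelerating when \eqn{b_0 < 2}),
#' * `"logistic"`: \eqn{\mu_a(x) = e^{b_0 + b_1 x} / \{1 + b_2
#'   (e^{b_0}/b_1)(e^{b_1 x} - 1)\}} (plateauing mortality; reduces to
#'   Gompertz when \eqn{b_2 = 0}).
#'
#' @param family Adult hazard family: `"gompertz"`, `"weibull"` or
#'   `"logistic"`.
#' @param a0 Log-scale juvenile mortality level (dimensionless, any real).
#' @param a1 Juvenile mortality decline rate (per year, must be > 0).
#' @param c Age-independent hazard (per year, must be >= 0).
#' @param b0 Adult level parameter: any real for Gompertz/logistic, > 0
#'   (shape) for Weibull.
#' @param b1 Adult slope (Gompertz/logistic, per year) or scale (Weibull,
#'   per year); must be > 0.
#' @param b2 Logistic shape parameter (>= 0); only used when
#'   `family = "logistic"`, where it defaults to 0.
#'
#' @return An object of class `mortality_params`: a named list with the
#'   family tag and numeric parameters.
#'
#' @examples
#' mortality_params("gompertz", a0 = -0.5, a1 = 1.5, c = 0.7,
#'                  b0 = -2.5, b1 = 0.35)
#' @export
mortality_params <- function(family = c("gompertz", "weibull", "logistic"),
                             a0 = -1, a1 = 1, c = 0.1,
                             b0 = -2, b1 = 0.5, b2 = NULL) {
  if (length(family) != 1 || !family %in% c("gompertz", "weibull", "logistic")) {
    family <- tryCatch(match.arg(family),
      error = function(e) {
        rlang::abort(
          paste0("unknown mortality family ", deparse(substitute(family))),
          class = "mortraj_config_error"
        )
      }
    )
  }
  if (identical(family, "logistic") && is.null(b2)) b2 <- 0
  if (!identical(family, "logistic")) b2 <- NULL
  p <- structure(
    list(family = family, a0 = a0, a1 = a1, c = c, b0 = b0, b1 = b1, b2 = b2),
    class = "mortality_params"
  )
  validate_mortality_params(p)
  p
}

validate_mortality_params <- function(p) {
  bad <- function(msg) rlang::abort(msg, class = "mortraj_domain_error")
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      bad(paste0("parameter ", nm, " must be a finite number"))
    }
  }
  for (nm in c("a0", "a1", "c", "b0", "b1")) num1(p[[nm]], nm)
  if (p$a1 <= 0) bad("a1 must be > 0")
  if (p$c < 0) bad("c must be >= 0")
  if (p$b1 <= 0) bad("b1 must be > 0")
  if (identical(p$family, "weibull") && p$b0 <= 0) {
    bad("b0 must be > 0 for the weibull family")
  }
  if (identical(p$family, "logistic")) {
    num1(p$b2, "b2")
    if (p$b2 < 0) bad("b2 must be >= 0 for the logistic family")
  }
  invisible(p)
}

#' @export
print.mortality_params <- function(x, ...) {
  cat("<mortality_params> family =", x$family, "\n")
  vals <- unlist(x[setdiff(names(x), "family")])
  print(round(vals, 4))
  invisible(x)
}

#' @export
format.mortality_params <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "family")])
  paste0(x$family, " (", paste(names(vals), signif(vals, 3),
                               sep = "=", collapse = ", "), ")")
}

#' @rdname mortality_params
#' @param x Object to test or convert.
#' @export
is_mortality_params <- function(x) inherits(x, "mortality_params")

#' Convert mortality parameters to/from a one-row tibble
#'
#' `params_to_row()` flattens a [mortality_params()] object into a one-row
#' tibble (absent `b2` becomes `NA`); `row_to_params()` rebuilds the object
#' from any list-like with fields `family, a0, a1, c, b0, b1` (and `b2` for
#' the logistic family). Useful for serialising parameter sets in plain
#' tabular configs.
#'
#' @param params A [mortality_params()] object.
#' @param row A one-row data frame or named list.
#' @return A one-row tibble, or a `mortality_params` object.
#' @export
params_to_row <- function(params) {
  stopifnot(is_mortality_params(params))
  tibble::tibble(
    family = params$family, a0 = params$a0, a1 = params$a1, c = params$c,
    b0 = params$b0, b1 = params$b1,
    b2 = if (is.null(params$b2)) NA_real_ else params$b2
  )
}

#' @rdname params_to_row
#' @export
row_to_params <- function(row) {
  b2 <- row[["b2"]]
  if (!is.null(b2) && length(b2) && is.na(b2)) b2 <- NULL
  mortality_params(
    family = as.character(row[["family"]]),
    a0 = as.numeric(row[["a0"]]), a1 = as.numeric(row[["a1"]]),
    c = as.numeric(row[["c"]]),
    b0 = as.numeric(row[["b0"]]), b1 = as.numeric(row[["b1"]]),
    b2 = if (is.null(b2)) NULL else as.numeric(b2)
  )
}
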