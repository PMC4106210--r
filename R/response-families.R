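#' Response-function families
#'
#' The five reaction-norm families used to model genotype response to the
#' environmental index \eqn{x}, plus the reciprocal-quadratic generalization
#' of the Cauchy curve:
#'
#' * `LINEAR`: \eqn{y = a + b x} (classic joint-regression stability model;
#'   the slope \eqn{b} measures sensitivity to environmental change)
#' * `PARABOLA`: \eqn{y = a + b x + c x^2}
#' * `RECIP_QUAD`: \eqn{y = 1 / (a + b x + c x^2)}
#' * `CAUCHY`: \eqn{y = k / (1 + ((x - x_{max})/r)^2)}
#' * `LOGISTIC`: \eqn{y = 1 / (a + b c^x)} with \eqn{0 < c < 1}
#' * `NORMAL`: \eqn{y = k / \sqrt{2\pi r^2} \exp(-(x - x_{max})^2 / (2 r^2))}
#'
#' @format A character vector of family names.
#' @export
RESPONSE_FAMILIES <- c("LINEAR", "PARABOLA", "RECIP_QUAD",
                       "CAUCHY", "LOGISTIC", "NORMAL")

# Free-parameter names, in the order used by gradients and the optimizer.
family_param_names <- function(family) {
  switch(family,
    LINEAR     = c("a", "b"),
    PARABOLA   = c("a", "b", "c"),
    RECIP_QUAD = c("a", "b", "c"),
    LOGISTIC   = c("a", "b", "c"),
    CAUCHY     = c("k", "x_max", "r"),
    NORMAL     = c("k", "x_max", "r"),
    stop("unknown family: ", family)
  )
}

#' Construct a validated response-curve parameter set
#'
#' @param family One of `RESPONSE_FAMILIES`.
#' @param a,b,c Coefficients for the LINEAR / PARABOLA / RECIP_QUAD /
#'   LOGISTIC families. For LOGISTIC, `c` is the base and must satisfy
#'   `0 < c < 1` so the curve rises toward the asymptote `1/a`.
#' @param k Peak-scale parameter (> 0) for CAUCHY and NORMAL.
#' @param x_max Location of the optimum (environmental-index units) for
#'   CAUCHY and NORMAL.
#' @param r Scale of the response range (> 0) for CAUCHY and NORMAL.
#'
#' @return An object of class `response_params`.
#' @examples
#' response_params("CAUCHY", k = 10, x_max = 5, r = 2)
#' response_params("LINEAR", a = 0, b = 1.3)
#' @export
response_params <- function(family, a = NULL, b = NULL, c = NULL,
                            k = NULL, x_max = NULL, r = NULL) {
  family <- match.arg(family, RESPONSE_FAMILIES)
  supplied <- list(a = a, b = b, c = c, k = k, x_max = x_max, r = r)
  need <- family_param_names(family)
  for (nm in need) {
    v <- supplied[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("family %s requires finite numeric parameter '%s'",
                   family, nm))
    }
  }
  extra <- setdiff(names(supplied)[!vapply(supplied, is.null, logical(1))],
                   need)
  if (length(extra)) {
    stop(sprintf("family %s does not use parameter(s): %s",
                 family, paste(extra, collapse = ", ")))
  }
  if (family %in% c("CAUCHY", "NORMAL")) {
    if (k <= 0) stop("k must be > 0")
    if (r <= 0) stop("r must be > 0")
  }
  if (family == "LOGISTIC" && (c <= 0 || c >= 1)) {
    stop("LOGISTIC base c must satisfy 0 < c < 1")
  }
  structure(c(list(family = family), supplied[need]),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  vals <- unlist(x[family_param_names(x$family)])
  cat(sprintf("<response_params %s> %s\n", x$family,
              paste(sprintf("%s = %.6g", names(vals), vals),
                    collapse = ", ")))
  invisible(x)
}

# theta <-> response_params helpers used by the fitters
theta_to_params <- function(family, theta) {
  args <- as.list(theta)
  names(args) <- family_param_names(family)
  do.call(response_params, c(list(family = family), args))
}

params_to_theta <- function(params) {
  unlist(params[family_param_names(params$family)])
}

#' Evaluate a response curve at environmental-index values
#'
#' @param params A [response_params()] object.
#' @param x Numeric vector of environmental-index values.
#' @return Numeric vector of predicted trait values.
#' @examples
#' p <- response_params("CAUCHY", k = 1, x_max = 0, r = 1)
#' evaluate_response(p, c(0, 1)) # 1, 0.5
#' @export
evaluate_response <- function(params, x) {
  stopifnot(inherits(params, "response_params"), is.numeric(x))
  with(params, switch(params$family,
    LINEAR   = a + b * x,
    PARABOLA = a + b * x + c * x^2,
    RECIP_QUAD = {
      den <- a + b * x + c * x^2
      if (any(den <= 0)) {
        stop(sprintf(
          "RECIP_QUAD denominator non-positive at x = %g",
          x[which(den <= 0)[1L]]))
      }
      1 / den
    },
    CAUCHY = k / (1 + ((x - x_max) / r)^2),
    LOGISTIC = {
      den <- a + b * c^x
      if (any(den <= 0)) {
        stop(sprintf(
          "LOGISTIC denominator non-positive at x = %g",
          x[which(den <= 0)[1L]]))
      }
      1 / den
    },
    NORMAL = k / sqrt(2 * pi * r^2) * exp(-(x - x_max)^2 / (2 * r^2))
  ))
}

#' Analytic gradient of a response curve in its free parameters
#'
#' Returns the Jacobian of [evaluate_response()] with respect to the
#' family's free parameters, used by the damped least-squares refinement.
#'
#' @inheritParams evaluate_response
#' @return A `length(x)` by `n_params` matrix with parameter names as
#'   column names.
#' @export
response_gradient <- function(params, x) {
  stopifnot(inherits(params, "response_params"), is.numeric(x))
  J <- with(params, switch(params$family,
    LINEAR   = cbind(a = rep(1, length(x)), b = x),
    PARABOLA = cbind(a = rep(1, length(x)), b = x, c = x^2),
    RECIP_QUAD = {
      den <- a + b * x + c * x^2
      if (any(den <= 0)) stop("RECIP_QUAD denominator non-positive")
      cbind(a = -1 / den^2, b = -x / den^2, c = -x^2 / den^2)
    },
    CAUCHY = {
      u <- (x - x_max) / r
      w <- 1 + u^2
      cbind(k = 1 / w, x_max = 2 * k * u / (r * w^2),
            r = 2 * k * u^2 / (r * w^2))
    },
    LOGISTIC = {
      den <- a + b * c^x
      if (any(den <= 0)) stop("LOGISTIC denominator non-positive")
      cbind(a = -1 / den^2, b = -c^x / den^2,
            c = -b * x * c^(x - 1) / den^2)
    },
    NORMAL = {
      u <- (x - x_max) / r
      f <- k / sqrt(2 * pi * r^2) * exp(-u^2 / 2)
      cbind(k = f / k, x_max = f * u / r, r = f * (u^2 - 1) / r)
    }
  ))
  J
}

#' Standardize a point relative to a Cauchy response curve
#'
#' Maps an (index, trait) pair to the dimensionless scale on which all the
#' non-linear families coincide near the optimum: `x_std = (x - x_max)/r`,
#' `y_std = y / k`. On an exact Cauchy curve `y_std = 1/(1 + x_std^2)`.
#'
#' @param params A CAUCHY [response_params()] object.
#' @param x,y Environmental-index value(s) and trait value(s).
#' @return A list with numeric elements `x_std` and `y_std`.
#' @examples
#' p <- response_params("CAUCHY", k = 2, x_max = 5, r = 2)
#' standardize_cauchy(p, x = 7, y = 1) # x_std = 1, y_std = 0.5
#' @export
standardize_cauchy <- function(params, x, y) {
  stopifnot(inherits(params, "response_params"))
  if (params$family != "CAUCHY") {
    stop("standardize_cauchy supports only the CAUCHY family, got ",
         params$family)
  }
  list(x_std = (x - params$x_max) / params$r, y_std = y / params$k)
}

#' Error of the quadratic approximation to the standardized Cauchy curve
#'
#' Near the optimum the standardized Cauchy response `1/(1 + x^2)` is well
#' approximated by `1 - x^2`; this returns the absolute discrepancy
#' `|1/(1 + x^2) - (1 - x^2)| = x^4/(1 + x^2)`, which vanishes at the
#' optimum and is bounded above by `x^4`.
#'
#' @param x_std Dimensionless standardized index value(s).
#' @return Non-negative numeric vector.
#' @examples
#' quadratic_approx_error(c(0, 1)) # 0, 0.5
#' @export
quadratic_approx_error <- function(x_std) {
  stopifnot(is.numeric(x_std), all(is.finite(x_std)))
  abs(1 / (1 + x_std^2) - (1 - x_std^2))
}
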