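#' Build the cell-means table and environmental index
#'
#' Aggregates replicated trial records to genotype-by-environment cell means
#' and computes the environmental index \eqn{x_j}: the mean of all genotypes
#' tested in environment \eqn{j}. The index is the regressor of
#' joint-regression stability analysis and of all the non-linear fits.
#'
#' @param raw Either a long-format `data.frame` of trial records with
#'   columns `environment`, `genotype`, `value` (optionally `year`, `block`),
#'   or a numeric genotype-by-environment matrix of cell means (rows named
#'   by genotype, columns by environment).
#' @param year Optional year label to subset `raw` to; required when the
#'   records span more than one year (the analysis is stratified by year).
#'
#' @return An object of class `cell_means`: a list with `genotypes`,
#'   `environments`, `means` (genotype x environment matrix, `NA` for
#'   cells a genotype was not tested in), `env_index`, `n_reps`, `year`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE,
#'             dimnames = list(c("G1", "G2"), c("E1", "E2", "E3")[1:2]))
#' \dontrun{compute_environment_index(m)} # errors: < 3 environments
#' @export
compute_environment_index <- function(raw, year = NULL) {
  if (is.matrix(raw)) {
    means <- raw
    if (is.null(rownames(means)))
      rownames(means) <- paste0("G", seq_len(nrow(means)))
    if (is.null(colnames(means)))
      colnames(means) <- paste0("E", seq_len(ncol(means)))
    n_reps <- 1L
    yr <- if (is.null(year)) NA_character_ else as.character(year)
  } else {
    raw <- as.data.frame(raw)
    need <- c("environment", "genotype", "value")
    if (!all(need %in% names(raw))) {
      stop("records need columns: ", paste(need, collapse = ", "))
    }
    if (!is.null(year)) raw <- raw[raw$year == year, , drop = FALSE]
    if ("year" %in% names(raw) && length(unique(raw$year)) > 1L) {
      stop("records span multiple years; pass `year=` or stratify upstream")
    }
    yr <- if ("year" %in% names(raw) && nrow(raw)) {
      as.character(raw$year[1L])
    } else NA_character_
    if (!nrow(raw)) stop("no records after year subset")
    gl <- sort(unique(as.character(raw$genotype)))
    el <- sort(unique(as.character(raw$environment)))
    means <- matrix(NA_real_, length(gl), length(el),
                    dimnames = list(gl, el))
    agg <- tapply(raw$value,
                  list(as.character(raw$genotype),
                       as.character(raw$environment)),
                  mean)
    means[rownames(agg), colnames(agg)] <- agg
    counts <- table(as.character(raw$genotype),
                    as.character(raw$environment))
    nr <- unique(as.integer(counts[counts > 0]))
    n_reps <- if (length(nr) == 1L) nr else NA_integer_
  }
  empty <- rowSums(!is.na(means)) == 0
  if (any(empty)) {
    warning("dropping genotype(s) absent from all environments: ",
            paste(rownames(means)[empty], collapse = ", "))
    means <- means[!empty, , drop = FALSE]
  }
  if (ncol(means) < 3L) {
    stop("need at least 3 environments, got ", ncol(means))
  }
  if (nrow(means) < 1L) stop("no genotypes left after aggregation")
  structure(
    list(genotypes = rownames(means), environments = colnames(means),
         means = means, env_index = colMeans(means, na.rm = TRUE),
         n_reps = n_reps, year = yr),
    class = "cell_means"
  )
}

#' @export
print.cell_means <- function(x, ...) {
  cat(sprintf("<cell_means> %d genotypes x %d environments (n_reps = %s%s)\n",
              length(x$genotypes), length(x$environments),
              x$n_reps, if (is.na(x$year)) "" else paste0(", year ", x$year)))
  cat("env_index:", paste(sprintf("%.4g", x$env_index), collapse = " "), "\n")
  invisible(x)
}

n_free <- function(family) length(family_param_names(family))
min_obs_for <- function(family) n_free(family) + 1L

# ---- damped (Levenberg-Marquardt style) least squares -----------------

# Validation-free evaluators used inside the optimizer hot loop; the public
# evaluate_response()/response_gradient() wrap the same formulas with
# domain checks.
eval_theta <- function(family, theta, x) {
  switch(family,
    LINEAR   = theta[1] + theta[2] * x,
    PARABOLA = theta[1] + theta[2] * x + theta[3] * x^2,
    RECIP_QUAD = 1 / (theta[1] + theta[2] * x + theta[3] * x^2),
    CAUCHY   = theta[1] / (1 + ((x - theta[2]) / theta[3])^2),
    LOGISTIC = 1 / (theta[1] + theta[2] * theta[3]^x),
    NORMAL   = theta[1] / sqrt(2 * pi * theta[3]^2) *
      exp(-(x - theta[2])^2 / (2 * theta[3]^2))
  )
}

grad_theta <- function(family, theta, x) {
  switch(family,
    LINEAR   = cbind(rep(1, length(x)), x),
    PARABOLA = cbind(rep(1, length(x)), x, x^2),
    RECIP_QUAD = {
      den <- theta[1] + theta[2] * x + theta[3] * x^2
      cbind(-1 / den^2, -x / den^2, -x^2 / den^2)
    },
    CAUCHY = {
      u <- (x - theta[2]) / theta[3]
      w <- 1 + u^2
      cbind(1 / w, 2 * theta[1] * u / (theta[3] * w^2),
            2 * theta[1] * u^2 / (theta[3] * w^2))
    },
    LOGISTIC = {
      den <- theta[1] + theta[2] * theta[3]^x
      cbind(-1 / den^2, -theta[3]^x / den^2,
            -theta[2] * x * theta[3]^(x - 1) / den^2)
    },
    NORMAL = {
      u <- (x - theta[2]) / theta[3]
      f <- theta[1] / sqrt(2 * pi * theta[3]^2) * exp(-u^2 / 2)
      cbind(f / theta[1], f * u / theta[3], f * (u^2 - 1) / theta[3])
    }
  )
}

valid_theta <- function(family, theta, x) {
  ok <- all(is.finite(theta))
  if (!ok) return(FALSE)
  switch(family,
    CAUCHY = ,
    NORMAL = theta[1] > 0 && theta[3] > 0,
    LOGISTIC = theta[1] > 0 && theta[2] >= 0 &&
      theta[3] > 0 && theta[3] < 1,
    RECIP_QUAD = all(theta[1] + theta[2] * x + theta[3] * x^2 > 0),
    TRUE
  )
}

# Minimize sum((y - f(x; theta))^2) by damped Gauss-Newton with the
# analytic Jacobian. Steps are accepted only if they reduce the RSS and
# keep theta in the family's valid region, so the refinement can never do
# worse than its starting point. Stops on a small gradient (scaled by the
# problem size), a tiny step, or a run of negligible relative improvements.
lm_refine <- function(family, theta, x, y,
                      grad_tol = 1e-8, step_tol = 1e-10, max_iter = 500L) {
  stopifnot(valid_theta(family, theta, x))
  res <- y - eval_theta(family, theta, x)
  rss <- sum(res^2)
  damp <- 1e-3
  converged <- FALSE
  stalled <- 0L
  for (it in seq_len(max_iter)) {
    J <- grad_theta(family, theta, x)
    g <- drop(crossprod(J, res))
    if (max(abs(g)) <= grad_tol * max(1, rss)) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (try in 1:30) {
      A <- JtJ + damp * diag(diag(JtJ) + 1e-12, nrow(JtJ))
      delta <- tryCatch(drop(solve(A, g)), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- theta + delta
        if (valid_theta(family, cand, x)) {
          rss_new <- sum((y - eval_theta(family, cand, x))^2)
          if (is.finite(rss_new) && rss_new <= rss) {
            step <- sqrt(sum(delta^2))
            gain <- rss - rss_new
            theta <- cand; res <- y - eval_theta(family, cand, x)
            rss <- rss_new
            damp <- max(damp / 10, 1e-12)
            accepted <- TRUE
            if (step <= step_tol * (1 + sqrt(sum(theta^2)))) {
              converged <- TRUE
            }
            stalled <- if (gain <= 1e-13 * (1 + rss)) stalled + 1L else 0L
            if (stalled >= 3L) converged <- TRUE
            break
          }
        }
      }
      damp <- damp * 10
      if (damp > 1e14) break
    }
    if (!accepted) {
      # Cannot make progress: at a (possibly constrained) stationary point.
      converged <- max(abs(g)) <= 1e-6 * (1 + rss)
      break
    }
    if (converged) break
  }
  list(theta = theta, rss = rss, converged = converged)
}

make_fit <- function(genotype, family, theta, rss, n_obs, converged,
                     transform_rss = NA_real_) {
  structure(
    list(genotype = genotype, family = family,
         params = theta_to_params(family, theta),
         rss = rss, n_obs = n_obs, converged = converged,
         n_params = n_free(family), transform_rss = transform_rss),
    class = "genotype_fit"
  )
}

#' @export
print.genotype_fit <- function(x, ...) {
  cat(sprintf("<genotype_fit %s %s> rss = %.6g, n_obs = %d, converged = %s\n",
              if (is.na(x$genotype)) "?" else x$genotype,
              x$family, x$rss, x$n_obs, x$converged))
  print(x$params)
  invisible(x)
}

ols_poly <- function(x, y, degree) {
  X <- vapply(0:degree, function(p) x^p, numeric(length(x)))
  fit <- lm.fit(X, y)
  if (fit$rank < degree + 1L) stop("rank-deficient polynomial design")
  list(coef = unname(fit$coefficients), rss = sum(fit$residuals^2))
}

# Seeded multi-start draws for the peaked families (CAUCHY/NORMAL).
multistart_grid <- function(family, x, y, n_starts) {
  xr <- range(x); span <- max(diff(xr), .Machine$double.eps)
  peak_targets <- runif(n_starts, 0.5, 2) * max(y)
  x_maxs <- runif(n_starts, xr[1], xr[2])
  rs <- runif(n_starts, 0.1, 2) * span
  lapply(seq_len(n_starts), function(i) {
    k <- if (family == "CAUCHY") peak_targets[i]
         else peak_targets[i] * sqrt(2 * pi * rs[i]^2)
    c(max(k, 1e-8), x_maxs[i], rs[i])
  })
}

# Run a short refinement from every start, then polish the winner at the
# full iteration budget; ties in rss break toward the smaller range scale r.
refine_best <- function(family, starts, x, y, control) {
  best <- NULL
  for (th in starts) {
    if (!valid_theta(family, th, x)) next
    fit <- tryCatch(
      lm_refine(family, th, x, y, control$grad_tol, control$step_tol,
                min(control$max_iter, 100L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$rss < best$rss - 1e-12 ||
        (abs(fit$rss - best$rss) <= 1e-12 && fit$theta[3] < best$theta[3])) {
      best <- fit
    }
  }
  if (!is.null(best)) {
    best <- lm_refine(family, best$theta, x, y, control$grad_tol,
                      control$step_tol, control$max_iter)
  }
  best
}

fit_control <- function(grad_tol = 1e-8, step_tol = 1e-10, max_iter = 500L,
                        n_starts = 20L, c_grid = 50L) {
  list(grad_tol = grad_tol, step_tol = step_tol, max_iter = max_iter,
       n_starts = n_starts, c_grid = c_grid)
}

#' Fit one response family to (index, trait) observations
#'
#' The workhorse behind [fit_genotype()]. LINEAR and PARABOLA are ordinary
#' least squares; RECIP_QUAD is least squares of `1/y` on `x` (coefficients
#' on the transform scale, RSS reported on the original scale); CAUCHY and
#' NORMAL use their linearizing-transform initializers (reciprocal and
#' log quadratics) refined by damped least squares on the original scale;
#' LOGISTIC profiles the base `c` over a log-spaced grid with
#' golden-section refinement, then polishes on the original scale.
#'
#' @param x Environmental-index values.
#' @param y Trait values (cell means), same length as `x`. Must be positive
#'   for RECIP_QUAD, CAUCHY, LOGISTIC and NORMAL; no automatic shifting is
#'   applied.
#' @param family One of `RESPONSE_FAMILIES`.
#' @param genotype Optional genotype label carried into the result.
#' @param seed Seed for the multi-start fallback draws (used only when the
#'   transform initializer is infeasible).
#' @param control List from `fit_control()` with optimizer tolerances.
#'
#' @return An object of class `genotype_fit` with elements `params`
#'   ([response_params()]), `rss` (original scale), `n_obs`, `converged`,
#'   `n_params`, and `transform_rss` where a transform-scale fit exists.
#' @examples
#' x <- seq(10, 90, length.out = 15)
#' y <- evaluate_response(response_params("CAUCHY", k = 10, x_max = 50, r = 20), x)
#' fit_response(x, y, "CAUCHY")
#' @export
fit_response <- function(x, y, family, genotype = NA_character_,
                         seed = 1L, control = fit_control()) {
  family <- match.arg(family, RESPONSE_FAMILIES)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_obs_for(family)) {
    stop(sprintf("genotype %s: %d observations, need >= %d for %s",
                 genotype, n, min_obs_for(family), family))
  }
  if (family %in% c("RECIP_QUAD", "CAUCHY", "LOGISTIC", "NORMAL") &&
      any(y <= 0)) {
    stop(sprintf(
      "genotype %s: non-positive response at x = %g; %s requires y > 0 (pre-shift explicitly if needed)",
      genotype, x[which(y <= 0)[1L]], family))
  }
  if (family %in% c("PARABOLA", "RECIP_QUAD", "CAUCHY", "NORMAL") &&
      length(unique(x)) < 3L) {
    stop(sprintf("genotype %s: need >= 3 distinct index values for %s",
                 genotype, family))
  }
  if (var(x) == 0) stop("degenerate environmental index (zero variance)")

  switch(family,
    LINEAR = {
      f <- ols_poly(x, y, 1L)
      make_fit(genotype, family, f$coef, f$rss, n, TRUE)
    },
    PARABOLA = {
      f <- ols_poly(x, y, 2L)
      make_fit(genotype, family, f$coef, f$rss, n, TRUE)
    },
    RECIP_QUAD = {
      f <- ols_poly(x, 1 / y, 2L)
      den <- f$coef[1] + f$coef[2] * x + f$coef[3] * x^2
      if (any(den <= 0)) {
        stop(sprintf(
          "genotype %s: fitted RECIP_QUAD denominator non-positive at x = %g",
          genotype, x[which(den <= 0)[1L]]))
      }
      rss <- sum((y - 1 / den)^2)
      make_fit(genotype, family, f$coef, rss, n, TRUE, transform_rss = f$rss)
    },
    CAUCHY = fit_cauchy_xy(x, y, genotype, seed, control),
    LOGISTIC = fit_logistic_xy(x, y, genotype, control),
    NORMAL = fit_normal_xy(x, y, genotype, seed, control)
  )
}

fit_cauchy_xy <- function(x, y, genotype, seed, control) {
  n <- length(x)
  if (sd(y) == 0) {
    # r is unidentifiable on a flat response
    th <- c(mean(y), mean(x), diff(range(x)))
    rss <- sum((y - evaluate_response(theta_to_params("CAUCHY", th), x))^2)
    return(make_fit(genotype, "CAUCHY", th, rss, n, FALSE))
  }
  # 1/y = (1/k) (1 + ((x - x_max)/r)^2) is quadratic in x
  q <- ols_poly(x, 1 / y, 2L)$coef
  start <- NULL
  if (q[3] > 0) {
    x_max <- -q[2] / (2 * q[3])
    inv_k <- q[1] - q[3] * x_max^2
    if (inv_k > 0) {
      k <- 1 / inv_k
      r <- sqrt(1 / (k * q[3]))
      start <- c(k, x_max, r)
    }
  }
  if (!is.null(start) && valid_theta("CAUCHY", start, x)) {
    fit <- lm_refine("CAUCHY", start, x, y, control$grad_tol,
                     control$step_tol, control$max_iter)
  } else {
    fit <- with_seed(seed, {
      starts <- multistart_grid("CAUCHY", x, y, control$n_starts)
      refine_best("CAUCHY", starts, x, y, control)
    })
    if (is.null(fit)) {
      th <- c(max(y), mean(x), diff(range(x)))
      return(make_fit(genotype, "CAUCHY", th,
                      sum((y - evaluate_response(
                        theta_to_params("CAUCHY", th), x))^2),
                      n, FALSE))
    }
  }
  make_fit(genotype, "CAUCHY", fit$theta, fit$rss, n, fit$converged)
}

fit_normal_xy <- function(x, y, genotype, seed, control) {
  n <- length(x)
  if (sd(y) == 0) {
    th <- c(mean(y) * sqrt(2 * pi) * diff(range(x)), mean(x), diff(range(x)))
    rss <- sum((y - evaluate_response(theta_to_params("NORMAL", th), x))^2)
    return(make_fit(genotype, "NORMAL", th, rss, n, FALSE))
  }
  # log y is quadratic in x with negative leading coefficient
  q <- ols_poly(x, log(y), 2L)$coef
  start <- NULL
  if (q[3] < 0) {
    r <- sqrt(-1 / (2 * q[3]))
    x_max <- -q[2] / (2 * q[3])
    k <- exp(q[1] + x_max^2 / (2 * r^2)) * sqrt(2 * pi * r^2)
    start <- c(k, x_max, r)
  }
  if (!is.null(start) && valid_theta("NORMAL", start, x)) {
    fit <- lm_refine("NORMAL", start, x, y, control$grad_tol,
                     control$step_tol, control$max_iter)
  } else {
    fit <- with_seed(seed, {
      starts <- multistart_grid("NORMAL", x, y, control$n_starts)
      refine_best("NORMAL", starts, x, y, control)
    })
    if (is.null(fit)) {
      th <- c(max(y) * sqrt(2 * pi) * diff(range(x)), mean(x),
              diff(range(x)))
      return(make_fit(genotype, "NORMAL", th,
                      sum((y - evaluate_response(
                        theta_to_params("NORMAL", th), x))^2),
                      n, FALSE))
    }
  }
  make_fit(genotype, "NORMAL", fit$theta, fit$rss, n, fit$converged)
}

fit_logistic_xy <- function(x, y, genotype, control) {
  n <- length(x)
  # profile fit: given the base c, (a, b) is OLS of 1/y on c^x
  profile_ab <- function(cc) {
    X <- cbind(1, cc^x)
    f <- lm.fit(X, 1 / y)
    list(a = unname(f$coefficients[1]), b = unname(f$coefficients[2]),
         rss = sum(f$residuals^2))
  }
  grid <- exp(seq(log(0.01), log(0.99), length.out = control$c_grid))
  prof <- vapply(grid, function(cc) profile_ab(cc)$rss, numeric(1))
  i <- which.min(prof)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  copt <- if (lo < hi) {
    optimize(function(cc) profile_ab(cc)$rss, c(lo, hi), tol = 1e-10)$minimum
  } else grid[i]
  ab <- profile_ab(copt)
  theta <- c(ab$a, ab$b, copt)
  if (!is.finite(ab$b) || ab$b < 0 || ab$a <= 0) {
    # decreasing (b < 0) or non-positive-asymptote fits are outside the
    # family's constraint region; report the transform-scale solution
    theta_rep <- c(max(ab$a, 1e-8), max(ab$b, 0), copt)
    rss <- tryCatch(
      sum((y - evaluate_response(theta_to_params("LOGISTIC", theta_rep),
                                 x))^2),
      error = function(e) Inf)
    return(make_fit(genotype, "LOGISTIC", theta_rep, rss, n, FALSE,
                    transform_rss = ab$rss))
  }
  fit <- lm_refine("LOGISTIC", theta, x, y, control$grad_tol,
                   control$step_tol, control$max_iter)
  make_fit(genotype, "LOGISTIC", fit$theta, fit$rss, n, fit$converged,
           transform_rss = ab$rss)
}

#' Fit a response family to one genotype of a cell-means table
#'
#' @param table A `cell_means` object from [compute_environment_index()].
#' @param genotype Genotype label present in `table`.
#' @param family One of `RESPONSE_FAMILIES`.
#' @param seed,control Passed to [fit_response()].
#' @return A `genotype_fit`.
#' @export
fit_genotype <- function(table, genotype, family, seed = 1L,
                         control = fit_control()) {
  stopifnot(inherits(table, "cell_means"))
  if (!genotype %in% table$genotypes) {
    stop("unknown genotype: ", genotype)
  }
  y <- table$means[genotype, ]
  fit_response(table$env_index, y, family, genotype = genotype,
               seed = seed, control = control)
}

#' Fit a response family to every genotype in a table
#'
#' Genotypes failing the family's preconditions (too few environments,
#' non-positive responses for the reciprocal/log families) are skipped and
#' listed with the reason. Multi-start draws are seeded per genotype from
#' `seed`, so repeated runs are identical.
#'
#' @inheritParams fit_genotype
#' @return An object of class `genotype_fits`: list with `fits` (named list
#'   of `genotype_fit`), `skipped` (`data.frame` of genotype, reason),
#'   `family`.
#' @export
fit_all_genotypes <- function(table, family, seed = 1L,
                              control = fit_control()) {
  stopifnot(inherits(table, "cell_means"))
  family <- match.arg(family, RESPONSE_FAMILIES)
  fits <- list()
  skipped <- data.frame(genotype = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (idx in seq_along(table$genotypes)) {
    g <- table$genotypes[idx]
    res <- tryCatch(
      fit_genotype(table, g, family, seed = seed + idx, control = control),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- rbind(skipped,
                       data.frame(genotype = g, reason = res,
                                  stringsAsFactors = FALSE))
    } else {
      fits[[g]] <- res
    }
  }
  structure(list(fits = fits, skipped = skipped, family = family),
            class = "genotype_fits")
}

#' @export
print.genotype_fits <- function(x, ...) {
  cat(sprintf("<genotype_fits %s> %d fitted, %d skipped\n",
              x$family, length(x$fits), nrow(x$skipped)))
  invisible(x)
}
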