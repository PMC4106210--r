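#' Construct a doubled-haploid marker panel
#'
#' @param genotypes Numeric line x marker matrix coded -1/+1 (the two
#'   homozygous classes of a DH biparental cross), with line and marker
#'   names as dimnames.
#' @param map `data.frame` with columns `marker`, `chromosome`, `position`
#'   (cM), one row per column of `genotypes`, positions non-decreasing
#'   within chromosome.
#' @return Object of class `marker_panel`.
#' @export
marker_panel <- function(genotypes, map) {
  stopifnot(is.matrix(genotypes), is.data.frame(map))
  if (!all(c("marker", "chromosome", "position") %in% names(map))) {
    stop("map needs columns marker, chromosome, position")
  }
  if (is.null(colnames(genotypes))) colnames(genotypes) <- map$marker
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("DH", seq_len(nrow(genotypes)))
  }
  if (!identical(as.character(map$marker), colnames(genotypes))) {
    stop("map markers must match genotype columns in order")
  }
  if (!all(genotypes %in% c(-1, 1))) {
    stop("genotypes must be coded -1/+1")
  }
  for (ch in unique(map$chromosome)) {
    pos <- map$position[map$chromosome == ch]
    if (is.unsorted(pos)) {
      stop("positions must be non-decreasing within chromosome ", ch)
    }
  }
  structure(list(lines = rownames(genotypes),
                 markers = as.character(map$marker),
                 map = map, genotypes = genotypes),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d lines x %d markers on %d chromosome(s)\n",
              length(x$lines), length(x$markers),
              length(unique(x$map$chromosome))))
  invisible(x)
}

#' Line phenotypes at the poor, average and good environments
#'
#' Evaluates each line's fitted linear response at three representative
#' points of the environmental index: its minimum (poor environment), mean
#' (average) and maximum (good), giving the per-line trait values at which
#' marker effects are estimated.
#'
#' @param table `cell_means` table for the DH lines.
#' @param fits LINEAR `genotype_fits` covering every line in `table`.
#' @return Numeric matrix, lines x `c("POOR", "AVERAGE", "GOOD")`, with an
#'   attribute `x_class` holding the three index values used.
#' @export
representative_phenotypes <- function(table, fits) {
  stopifnot(inherits(table, "cell_means"))
  flist <- if (inherits(fits, "genotype_fits")) fits$fits else fits
  missing_fit <- setdiff(table$genotypes, names(flist))
  if (length(missing_fit)) {
    stop("no linear fit for line(s): ", paste(missing_fit, collapse = ", "))
  }
  if (any(vapply(flist, function(f) f$family, "") != "LINEAR")) {
    stop("representative phenotypes require LINEAR fits")
  }
  xc <- c(POOR = min(table$env_index), AVERAGE = mean(table$env_index),
          GOOD = max(table$env_index))
  out <- t(vapply(table$genotypes, function(g) {
    evaluate_response(flist[[g]]$params, xc)
  }, numeric(3)))
  colnames(out) <- names(xc)
  attr(out, "x_class") <- xc
  out
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))           # population sd so x'x/n = 1 exactly
  s[s == 0] <- 1                      # constant markers stay zero columns
  list(X = sweep(Xc, 2, s, "/"), center = mu, scale = s)
}

#' Elastic-net fit at a single penalty by cyclic coordinate descent
#'
#' Minimizes `(1/2n) ||y - X b||^2 + lambda (alpha ||b||_1 +
#' (1 - alpha) ||b||^2 / 2)` by cyclic coordinate descent with the
#' univariate soft-threshold update and active-set iteration. Iterates
#' until the largest coefficient change in a sweep is below `tol` and the
#' KKT stationarity conditions hold within `kkt_tol`.
#'
#' @param X Standardized predictor matrix (columns mean 0, variance 1);
#'   unstandardized input is an error.
#' @param y Centered response vector.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (`1` = LASSO,
#'   `0` = ridge).
#' @param lambda Non-negative penalty strength (may be a decreasing vector,
#'   fitted with warm starts).
#' @param tol Coefficient max-change convergence tolerance.
#' @param kkt_tol KKT residual tolerance.
#' @param max_sweeps Sweep budget per penalty value.
#' @return If `lambda` is scalar, the coefficient vector; otherwise a
#'   `p x length(lambda)` coefficient matrix.
#' @examples
#' x <- matrix(c(-1, 1), dimnames = list(NULL, "m1"))
#' elastic_net_fit(x, c(-1, 1), alpha = 1, lambda = 0.5) # 0.5
#' @export
elastic_net_fit <- function(X, y, alpha, lambda, tol = 1e-7,
                            kkt_tol = 1e-8, max_sweeps = 10000L) {
  stopifnot(is.matrix(X), is.numeric(y), nrow(X) == length(y))
  if (nrow(X) < 2L) stop("need n >= 2 observations")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  n <- nrow(X)
  mu <- colMeans(X)
  v_pop <- colMeans(sweep(X, 2, mu)^2)
  v_smp <- v_pop * n / max(n - 1, 1)
  nonconst <- v_pop > 0
  ok <- max(abs(mu[nonconst]), 0) <= 1e-6 &&
    all(pmin(abs(v_pop[nonconst] - 1), abs(v_smp[nonconst] - 1)) <= 1e-4)
  if (!ok) {
    stop("X must be standardized (column means 0, variance 1)")
  }
  if (abs(mean(y)) > 1e-6 * (sd(y) + 1e-12)) {
    stop("y must be centered")
  }
  ord <- order(lambda, decreasing = TRUE)
  B <- .enet_cd_path(X, as.numeric(y), alpha, as.numeric(lambda[ord]),
                     tol, as.integer(max_sweeps), kkt_tol)
  B <- B[, order(ord), drop = FALSE]
  rownames(B) <- colnames(X)
  if (length(lambda) == 1L) drop(B) else B
}

#' Penalty path for the elastic net
#'
#' Log-spaced decreasing grid starting at the smallest penalty with an
#' all-zero solution, `lambda_max = max_k |x_k' y| / (n alpha)`, down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @inheritParams elastic_net_fit
#' @param n_lambda Grid length (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @param alpha0_ceiling Stand-in for the (infinite) `lambda_max` when
#'   `alpha = 0`; the ridge path then starts at this multiple of the
#'   `alpha = 0.001` value.
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X, y, alpha, n_lambda = 100L,
                        lambda_min_ratio = 1e-3, alpha0_ceiling = 1000) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X)
  lmax_l1 <- max(abs(crossprod(X, y))) / n
  lmax <- if (alpha > 0) lmax_l1 / alpha else alpha0_ceiling * lmax_l1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Elastic-net configuration for a genome scan
#'
#' @param alpha Mixing parameter; the two presets used in the analyses are
#'   0.5 (elastic net) and 1 (LASSO).
#' @param lambda_grid Optional penalty grid; computed by [lambda_path()]
#'   when `NULL`.
#' @param n_lambda,lambda_min_ratio Path shape when `lambda_grid` is `NULL`.
#'   The scan default floors the path at `lambda_max / 100`: with more
#'   markers than lines the unpenalized end of the path is degenerate,
#'   cross-validation selects penalties far above it, and path solvers
#'   conventionally stop there in the p > n regime.
#' @param n_folds Cross-validation folds for penalty selection.
#' @param seed RNG seed for fold assignment.
#' @return List of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, lambda_grid = NULL, n_lambda = 100L,
                        lambda_min_ratio = 1e-2, n_folds = 10L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid),
                                             strictly = TRUE)) {
      stop("lambda_grid must be positive and strictly decreasing")
    }
  }
  structure(list(alpha = alpha, lambda_grid = lambda_grid,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 n_folds = n_folds, seed = seed),
            class = "enet_config")
}

#' Cross-validated penalty selection for the elastic net
#'
#' K-fold cross-validation of the mean squared prediction error over a
#' penalty path, with seeded fold assignment; the minimum-MSE penalty is
#' selected (ties broken toward the larger, sparser penalty).
#'
#' @param X Standardized predictors; `y` centered response.
#' @inheritParams elastic_net_fit
#' @param lambda_grid Decreasing penalty grid.
#' @param n_folds Number of folds (must not exceed `nrow(X)`).
#' @param seed Seed for the fold assignment.
#' @return List with `lambda_min`, `cvm` (mean CV MSE per penalty),
#'   `lambda_grid`, and `beta` (full-data coefficients at `lambda_min`).
#' @export
cv_elastic_net <- function(X, y, alpha, lambda_grid, n_folds = 10L,
                           seed = 1L) {
  n <- nrow(X)
  if (n_folds > n) stop("fewer observations than folds")
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  mse <- matrix(NA_real_, n_folds, length(lambda_grid))
  # fold fits only rank penalties, so they use a tolerance scaled to the
  # response; the final full-data fit below is KKT-certified at 1e-7
  tol_cv <- max(1e-7, 1e-4 * sd(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    mu_tr <- mean(y[tr])
    Btr <- .enet_cd_path(X[tr, , drop = FALSE], y[tr] - mu_tr, alpha,
                         as.numeric(lambda_grid), tol_cv, 3000L, tol_cv)
    pred <- mu_tr + X[!tr, , drop = FALSE] %*% Btr
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(mse)
  i <- which(cvm <= min(cvm) + 1e-12)[1L]  # first = largest penalty
  bm <- elastic_net_fit(X, y, alpha, lambda_grid[seq_len(i)])
  beta <- if (i == 1L) bm else bm[, i]
  list(lambda_min = lambda_grid[i], cvm = cvm, lambda_grid = lambda_grid,
       beta = beta)
}

#' Genome-wide marker-effect scan at poor, average and good environments
#'
#' Fits a penalized regression of the line phenotypes at each environment
#' class on all markers simultaneously; the penalty is chosen by k-fold
#' cross-validated MSE. Markers are standardized internally and the
#' returned effects are on the original -1/+1 coding scale (half the
#' fitted difference between the two homozygous classes).
#'
#' @param panel `marker_panel`.
#' @param phenotypes Matrix from [representative_phenotypes()] (lines x
#'   POOR/AVERAGE/GOOD), or any lines x classes numeric matrix with rows
#'   matching `panel$lines`.
#' @param config `enet_config`.
#' @return Named list of `effect_scan` objects (one per environment class),
#'   each a list with `environment_class`, `alpha`, `effects` (named by
#'   marker, original coding scale), `n_nonzero`, `lambda_selected`,
#'   `intercept`.
#' @export
genome_scan <- function(panel, phenotypes, config = enet_config()) {
  stopifnot(inherits(panel, "marker_panel"), is.matrix(phenotypes))
  if (!identical(rownames(phenotypes), panel$lines)) {
    if (nrow(phenotypes) != length(panel$lines)) {
      stop("phenotype lines do not match panel lines")
    }
    if (!is.null(rownames(phenotypes)) &&
        !setequal(rownames(phenotypes), panel$lines)) {
      stop("phenotype lines do not match panel lines")
    }
    if (!is.null(rownames(phenotypes))) {
      phenotypes <- phenotypes[panel$lines, , drop = FALSE]
    }
  }
  n <- nrow(phenotypes)
  if (config$n_folds > n) stop("fewer lines than folds")
  std <- standardize_columns(panel$genotypes)
  scans <- list()
  for (cls in colnames(phenotypes)) {
    y <- phenotypes[, cls]
    yc <- y - mean(y)
    grid <- config$lambda_grid
    if (is.null(grid)) {
      if (max(abs(yc)) == 0) {
        grid <- 1  # arbitrary positive penalty; solution is all-zero anyway
      } else {
        grid <- lambda_path(std$X, yc, config$alpha, config$n_lambda,
                            config$lambda_min_ratio)
      }
    }
    cv <- cv_elastic_net(std$X, yc, config$alpha, grid,
                         n_folds = config$n_folds, seed = config$seed)
    effects <- cv$beta / std$scale
    names(effects) <- panel$markers
    scans[[cls]] <- structure(
      list(environment_class = cls, alpha = config$alpha,
           effects = effects, n_nonzero = sum(effects != 0),
           lambda_selected = cv$lambda_min, intercept = mean(y)),
      class = "effect_scan")
  }
  scans
}

#' @export
print.effect_scan <- function(x, ...) {
  cat(sprintf(
    "<effect_scan %s alpha=%.2g> %d nonzero of %d markers, lambda = %.4g\n",
    x$environment_class, x$alpha, x$n_nonzero, length(x$effects),
    x$lambda_selected))
  invisible(x)
}

#' Tidy a set of effect scans into a genome-scan table
#'
#' @param panel The `marker_panel` the scans were run on.
#' @param scans Output of [genome_scan()].
#' @return `data.frame` with marker, chromosome, position and one effect
#'   column per environment class.
#' @export
scan_table <- function(panel, scans) {
  out <- panel$map
  for (cls in names(scans)) {
    out[[paste0("effect_", tolower(cls))]] <- unname(scans[[cls]]$effects)
  }
  out
}
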