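#' Two-way ANOVA partition of a replicated multi-environment trial
#'
#' Partitions the total sum of squares of a balanced genotype x environment
#' x block layout into genotype (G), environment (E), interaction (G x E)
#' and within-cell error components by the direct mean decomposition.
#' Degrees of freedom are `G-1`, `E-1`, `(G-1)(E-1)` and `GE(r-1)`.
#'
#' Genotypes not present in every environment are excluded first (largest
#' complete-genotype subset, with a warning); remaining imbalance in the
#' replicate counts is an error listing the offending cells.
#'
#' @param raw Long-format records with columns `environment`, `block`,
#'   `genotype`, `value` (optionally `year`).
#' @param year Optional year label to subset to.
#' @return Object of class `gxe_anova`: list with `ss_total`, `ss_G`,
#'   `ss_E`, `ss_GxE`, `ss_error`, matching `df_*`, plus `n_genotypes`,
#'   `n_environments`, `n_reps`.
#' @export
anova_partition <- function(raw, year = NULL) {
  raw <- as.data.frame(raw)
  need <- c("environment", "genotype", "value")
  if (!all(need %in% names(raw))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(year)) raw <- raw[raw$year == year, , drop = FALSE]
  if ("year" %in% names(raw) && length(unique(raw$year)) > 1L) {
    stop("records span multiple years; pass `year=` or stratify upstream")
  }
  if (!"block" %in% names(raw)) raw$block <- "B1"
  g <- as.character(raw$genotype)
  e <- as.character(raw$environment)

  # complete-case genotype rule: keep genotypes observed in all environments
  envs <- sort(unique(e))
  seen <- table(unique(data.frame(g, e))$g)
  complete <- names(seen)[seen == length(envs)]
  if (length(complete) < length(seen)) {
    warning("excluding genotype(s) not present in every environment: ",
            paste(setdiff(names(seen), complete), collapse = ", "))
    keep <- g %in% complete
    raw <- raw[keep, , drop = FALSE]
    g <- g[keep]; e <- e[keep]
  }
  if (length(complete) < 2L) stop("need >= 2 complete genotypes")

  counts <- table(g, e)
  r <- unique(as.integer(counts))
  if (length(r) != 1L) {
    bad <- which(counts != max(counts), arr.ind = TRUE)
    stop("unbalanced replicate counts in cells: ",
         paste(sprintf("(%s, %s)", rownames(counts)[bad[, 1]],
                       colnames(counts)[bad[, 2]]),
               collapse = ", "))
  }
  y <- raw$value
  G <- nrow(counts); E <- ncol(counts)
  cell <- tapply(y, list(g, e), mean)
  gm <- mean(y)
  rm_ <- rowMeans(cell); cm <- colMeans(cell)
  ss_G <- r * E * sum((rm_ - gm)^2)
  ss_E <- r * G * sum((cm - gm)^2)
  ss_GxE <- r * sum((sweep(sweep(cell, 1, rm_), 2, cm) + gm)^2)
  ss_total <- sum((y - gm)^2)
  fitted_cell <- cell[cbind(g, e)]
  ss_error <- sum((y - fitted_cell)^2)
  structure(
    list(ss_total = ss_total, ss_G = ss_G, ss_E = ss_E, ss_GxE = ss_GxE,
         ss_error = ss_error,
         df_G = G - 1L, df_E = E - 1L, df_GxE = (G - 1L) * (E - 1L),
         df_error = G * E * (r - 1L),
         n_genotypes = G, n_environments = E, n_reps = r,
         year = if (is.null(year)) {
           if ("year" %in% names(raw) && nrow(raw)) as.character(raw$year[1L])
           else NA_character_
         } else as.character(year)),
    class = "gxe_anova"
  )
}

#' @export
print.gxe_anova <- function(x, ...) {
  df <- data.frame(
    source = c("G", "E", "GxE", "Error", "Total"),
    df = c(x$df_G, x$df_E, x$df_GxE, x$df_error,
           x$df_G + x$df_E + x$df_GxE + x$df_error),
    ss = c(x$ss_G, x$ss_E, x$ss_GxE, x$ss_error, x$ss_total))
  cat(sprintf("<gxe_anova> %d genotypes x %d environments x %d reps\n",
              x$n_genotypes, x$n_environments, x$n_reps))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Partition the G x E sum of squares by a fitted response family
#'
#' Measures how much of the interaction a family's per-genotype response
#' curves capture. Per-cell deviations from the fitted curves,
#' \eqn{\delta_{ij} = \bar y_{ij} - \hat f_i(x_j)}, are double-centered
#' (removing genotype and environment margins); the residual interaction is
#' `n_reps * sum(centered delta^2)` and the explained component is
#' `ss_GxE - ss_residual` (floored at 0 and flagged if the curves do worse
#' than the additive model). For the LINEAR family this reduces exactly to
#' the classical heterogeneity-of-regressions sum of squares
#' \eqn{r \sum_i (b_i - 1)^2 S_{xx}}.
#'
#' @param table Complete `cell_means` table.
#' @param fits `genotype_fits` covering every genotype in `table` (a named
#'   list of `genotype_fit` objects is also accepted).
#' @param anova `gxe_anova` for the same data (supplies `ss_GxE`, `n_reps`).
#' @return Object of class `gxe_partition`: list with `family`,
#'   `ss_explained`, `ss_residual`, `pct_explained` (% of `ss_GxE`, `NA`
#'   when `ss_GxE` is zero), `floored`.
#' @export
partition_gxe <- function(table, fits, anova) {
  stopifnot(inherits(table, "cell_means"), inherits(anova, "gxe_anova"))
  flist <- if (inherits(fits, "genotype_fits")) fits$fits else fits
  family <- if (inherits(fits, "genotype_fits")) fits$family
            else flist[[1L]]$family
  missing_fit <- setdiff(table$genotypes, names(flist))
  if (length(missing_fit)) {
    stop("no fit for genotype(s): ", paste(missing_fit, collapse = ", "))
  }
  if (anyNA(table$means)) stop("cell-means table must be complete")
  pred <- t(vapply(table$genotypes, function(g) {
    evaluate_response(flist[[g]]$params, table$env_index)
  }, numeric(length(table$env_index))))
  delta <- table$means - pred
  centered <- sweep(sweep(delta, 1, rowMeans(delta)), 2, colMeans(delta)) +
    mean(delta)
  ss_residual <- anova$n_reps * sum(centered^2)
  ss_explained <- anova$ss_GxE - ss_residual
  floored <- ss_explained < 0
  if (floored) ss_explained <- 0
  pct <- if (anova$ss_GxE <= 1e-10 * max(1, anova$ss_total)) NA_real_
         else 100 * ss_explained / anova$ss_GxE
  structure(
    list(family = family, ss_explained = ss_explained,
         ss_residual = ss_residual, ss_GxE = anova$ss_GxE,
         pct_explained = pct, floored = floored),
    class = "gxe_partition"
  )
}

#' @export
print.gxe_partition <- function(x, ...) {
  cat(sprintf(
    "<gxe_partition %s> explained %.6g / %.6g (%.2f%%)%s\n",
    x$family, x$ss_explained, x$ss_GxE,
    if (is.na(x$pct_explained)) NA else x$pct_explained,
    if (x$floored) " [floored at 0]" else ""))
  invisible(x)
}

#' Per-year, per-family percentage of G x E explained
#'
#' Runs the full partition pipeline — environmental index, per-genotype
#' fits for each family, interaction partition — on each year stratum of a
#' replicated trial data set, and appends the across-year average.
#'
#' @param raw Long-format records (columns `year`, `environment`, `block`,
#'   `genotype`, `value`; `year` optional for single-year data).
#' @param families Character vector of families to compare.
#' @param seed Seed forwarded to the fitters.
#' @param control Optimizer control from `fit_control()`.
#' @return A `data.frame` with columns `year`, `family`, `pct_explained`,
#'   `ss_explained`, `ss_residual`, `ss_GxE`, `floored`; rows with
#'   `year == "Average"` hold the across-year mean percentage per family.
#' @export
percent_table <- function(raw, families = RESPONSE_FAMILIES[-3L],
                          seed = 1L, control = fit_control()) {
  raw <- as.data.frame(raw)
  years <- if ("year" %in% names(raw)) {
    sort(unique(as.character(raw$year)))
  } else NA_character_
  out <- list()
  for (yr in years) {
    sub <- if (is.na(yr)) raw else raw[raw$year == yr, , drop = FALSE]
    an <- anova_partition(sub)
    tab <- suppressWarnings(compute_environment_index(sub))
    # align with the ANOVA's complete-genotype subset
    if (anyNA(tab$means)) {
      keep <- rowSums(is.na(tab$means)) == 0
      tab$means <- tab$means[keep, , drop = FALSE]
      tab$genotypes <- rownames(tab$means)
      tab$env_index <- colMeans(tab$means)
    }
    for (fam in families) {
      fits <- fit_all_genotypes(tab, fam, seed = seed, control = control)
      if (nrow(fits$skipped)) {
        stop(sprintf("year %s, family %s: unfittable genotype(s): %s",
                     yr, fam, paste(fits$skipped$genotype, collapse = ", ")))
      }
      p <- partition_gxe(tab, fits, an)
      out[[length(out) + 1L]] <- data.frame(
        year = as.character(yr), family = fam,
        pct_explained = p$pct_explained, ss_explained = p$ss_explained,
        ss_residual = p$ss_residual, ss_GxE = p$ss_GxE,
        floored = p$floored, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (length(years) > 1L) {
    avg <- do.call(rbind, lapply(split(res, res$family), function(d) {
      data.frame(year = "Average", family = d$family[1L],
                 pct_explained = mean(d$pct_explained),
                 ss_explained = NA_real_, ss_residual = NA_real_,
                 ss_GxE = NA_real_, floored = any(d$floored),
                 stringsAsFactors = FALSE)
    }))
    res <- rbind(res, avg)
  }
  rownames(res) <- NULL
  res
}

#' Finlay-Wilkinson / Eberhart-Russell stability classification
#'
#' From the per-genotype linear joint regressions, classifies each genotype
#' by the slope against the environmental index: `AVERAGE` stability when
#' `b` is not significantly different from 1 (two-sided t-test on `n - 2`
#' df), `LOW_STABILITY` when significantly above 1 (sensitive to
#' environment), `HIGH_STABILITY` when significantly below 1. The
#' Eberhart-Russell refinement flags as `er_stable` the genotypes that
#' additionally have a low deviation-from-regression mean square and an
#' above-median mean yield.
#'
#' @param fits LINEAR `genotype_fits` (or named list of LINEAR
#'   `genotype_fit`) for the genotypes of `table`.
#' @param table The `cell_means` table the fits came from.
#' @param alpha_level Significance level of the slope test (default 0.05).
#' @param error_ms,error_df Optional pooled error mean square and its df
#'   (from [anova_partition()]); when supplied, "low deviation variance"
#'   means `dev_ms` not significantly greater than `error_ms` by an F-test
#'   at `alpha_level`. Otherwise `dev_ms` at or below the across-genotype
#'   median counts as low.
#' @return A `data.frame` (class `stability_report`) with columns
#'   `genotype`, `slope`, `se_b`, `t_value`, `p_value`, `dev_ms`,
#'   `mean_yield`, `fw_class`, `er_stable`. Genotypes with fewer than 4
#'   environments get `NA` `dev_ms` and class, with a warning.
#' @export
classify_stability <- function(fits, table, alpha_level = 0.05,
                               error_ms = NULL, error_df = NULL) {
  stopifnot(inherits(table, "cell_means"))
  flist <- if (inherits(fits, "genotype_fits")) fits$fits else fits
  if (any(vapply(flist, function(f) f$family, "") != "LINEAR")) {
    stop("stability classification requires LINEAR fits")
  }
  x <- table$env_index
  rows <- lapply(names(flist), function(g) {
    f <- flist[[g]]
    y <- table$means[g, ]
    ok <- is.finite(y)
    n <- sum(ok)
    sxx <- sum((x[ok] - mean(x[ok]))^2)
    mean_yield <- mean(y[ok])
    b <- f$params$b
    if (n < 4L) {
      warning(sprintf(
        "genotype %s has %d environments (< 4): dev_ms and class not estimable",
        g, n))
      return(data.frame(genotype = g, slope = b, se_b = NA_real_,
                        t_value = NA_real_, p_value = NA_real_,
                        dev_ms = NA_real_, mean_yield = mean_yield,
                        fw_class = NA_character_, er_stable = NA,
                        stringsAsFactors = FALSE))
    }
    dev_ms <- f$rss / (n - 2)
    se_b <- sqrt(dev_ms / sxx)
    t_val <- (b - 1) / se_b
    p_val <- 2 * pt(-abs(t_val), df = n - 2)
    cls <- if (p_val > alpha_level) "AVERAGE"
           else if (b > 1) "LOW_STABILITY" else "HIGH_STABILITY"
    data.frame(genotype = g, slope = b, se_b = se_b, t_value = t_val,
               p_value = p_val, dev_ms = dev_ms, mean_yield = mean_yield,
               fw_class = cls, er_stable = NA, stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  est <- !is.na(rep_$dev_ms)
  low_dev <- rep(NA, nrow(rep_))
  if (!is.null(error_ms) && !is.null(error_df) && error_df > 0 &&
      error_ms > 0) {
    dfs <- vapply(rep_$genotype[est],
                  function(g) flist[[g]]$n_obs - 2L, integer(1))
    fcrit <- qf(1 - alpha_level, dfs, error_df)
    low_dev[est] <- rep_$dev_ms[est] / error_ms <= fcrit
  } else {
    low_dev[est] <- rep_$dev_ms[est] <= median(rep_$dev_ms[est])
  }
  high_yield <- rep_$mean_yield > median(rep_$mean_yield)
  rep_$er_stable <- rep_$fw_class == "AVERAGE" & low_dev & high_yield
  class(rep_) <- c("stability_report", "data.frame")
  rep_
}
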