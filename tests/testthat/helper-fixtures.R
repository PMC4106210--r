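# Shared fixture builders (all data generated in code).

withr_tempfile <- function() tempfile(fileext = ".csv")

# cell_means object directly from a matrix of means
table_from_matrix <- function(m) {
  suppressWarnings(compute_environment_index(m))
}

# long-format records from a genotype x environment matrix of cell
# expectations, with `blocks` replicates and iid noise
records_from_matrix <- function(m, blocks = 1L, noise_sd = 0, seed = 1L) {
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("E", seq_len(ncol(m)))
  rec <- expand.grid(genotype = rownames(m), block = paste0("B", 1:blocks),
                     environment = colnames(m),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr_seed <- function(expr) { set.seed(seed); expr }
  rec$value <- m[cbind(rec$genotype, rec$environment)] +
    withr_seed(rnorm(nrow(rec), 0, noise_sd))
  rec$year <- "Y1"
  rec[, c("year", "environment", "block", "genotype", "value")]
}

# minimal genotype_fit stand-in for partition tests (e.g. 2-point linear
# "fits" below the fitter's n >= 3 precondition)
manual_fit <- function(genotype, family, ...) {
  structure(list(genotype = genotype, family = family,
                 params = response_params(family, ...),
                 rss = NA_real_, n_obs = NA_integer_, converged = TRUE,
                 n_params = length(list(...))),
            class = "genotype_fit")
}

# brute-force two-way-with-replication sums of squares, written as the
# explicit mean decomposition (independent of anova_partition internals)
brute_force_anova <- function(rec) {
  g <- as.character(rec$genotype); e <- as.character(rec$environment)
  y <- rec$value
  gm <- mean(y)
  cell <- tapply(y, list(g, e), mean)
  r <- length(unique(rec$block))
  gi <- rowMeans(cell); ej <- colMeans(cell)
  ss_G <- r * ncol(cell) * sum((gi - gm)^2)
  ss_E <- r * nrow(cell) * sum((ej - gm)^2)
  ss_GxE <- r * sum((cell - outer(gi, rep(1, ncol(cell))) -
                       outer(rep(1, nrow(cell)), ej) + gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_error <- ss_total - ss_G - ss_E - ss_GxE
  list(ss_total = ss_total, ss_G = ss_G, ss_E = ss_E, ss_GxE = ss_GxE,
       ss_error = ss_error)
}

# random valid parameter set per family, for property tests
random_params <- function(family) {
  switch(family,
    LINEAR   = response_params("LINEAR", a = rnorm(1, 2), b = rnorm(1, 1, 0.4)),
    PARABOLA = response_params("PARABOLA", a = rnorm(1, 4), b = rnorm(1, 1, 0.3),
                               c = -abs(rnorm(1, 0.1, 0.05)) - 0.01),
    RECIP_QUAD = response_params("RECIP_QUAD", a = runif(1, 0.3, 0.7),
                                 b = runif(1, -0.05, 0.02),
                                 c = runif(1, 0.002, 0.02)),
    CAUCHY   = response_params("CAUCHY", k = runif(1, 4, 12),
                               x_max = runif(1, 3, 8), r = runif(1, 1, 4)),
    LOGISTIC = response_params("LOGISTIC", a = runif(1, 0.08, 0.2),
                               b = runif(1, 0.2, 0.8), c = runif(1, 0.2, 0.8)),
    NORMAL   = response_params("NORMAL", k = runif(1, 20, 80),
                               x_max = runif(1, 3, 8), r = runif(1, 1.5, 4))
  )
}
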