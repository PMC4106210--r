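test_that("environmental index is the column mean of the cell means", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("E1", "E2", "E3")))
  tab <- compute_environment_index(m)
  expect_equal(tab$env_index, c(E1 = 1.5, E2 = 3.5, E3 = 5.5))
  # single genotype: index equals its own responses
  tab1 <- compute_environment_index(m[1, , drop = FALSE])
  expect_equal(unname(tab1$env_index), c(1, 3, 5))
  # three genotypes, direct column averaging
  m3 <- rbind(G1 = c(0, 2, 4), G2 = c(1, 3, 5), G3 = c(2, 4, 6))
  colnames(m3) <- paste0("E", 1:3)
  expect_equal(unname(compute_environment_index(m3)$env_index), c(1, 3, 5))
  expect_error(compute_environment_index(m[, 1:2]), "3 environments")
})

test_that("records are aggregated over blocks and validated", {
  m <- rbind(G1 = c(2, 4, 6), G2 = c(3, 5, 7))
  colnames(m) <- paste0("E", 1:3)
  rec <- records_from_matrix(m, blocks = 3, noise_sd = 0)
  tab <- compute_environment_index(rec)
  expect_equal(tab$means, m)
  expect_equal(tab$n_reps, 3L)
  # genotype absent everywhere is dropped with a warning
  m_na <- rbind(m, G3 = c(NA, NA, NA))
  expect_warning(tab2 <- compute_environment_index(m_na), "G3")
  expect_equal(tab2$genotypes, c("G1", "G2"))
  # multi-year records need stratification
  rec2 <- rec; rec2$year[1] <- "Y2"
  expect_error(compute_environment_index(rec2), "year")
  expect_silent(compute_environment_index(rec2, year = "Y1"))
})

test_that("linear fits equal ordinary least squares", {
  f <- fit_response(c(1, 2, 3), c(2, 4, 6), "LINEAR")
  expect_equal(f$params$a, 0, tolerance = 1e-12)
  expect_equal(f$params$b, 2, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-20)
  expect_error(fit_response(c(0, 3), c(0, 2), "LINEAR"), ">= 3")
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(10, 5, 2); y <- 1 + 0.8 * x + rnorm(10, 0, 0.5)
    f <- fit_response(x, y, "LINEAR")
    o <- lm(y ~ x)
    expect_equal(unname(c(f$params$a, f$params$b)), unname(coef(o)),
                 tolerance = 1e-10)
    expect_equal(f$rss, sum(resid(o)^2), tolerance = 1e-10)
  }
  expect_error(fit_response(rep(2, 5), 1:5, "LINEAR"), "degenerate")
})

test_that("parabola fits equal the degree-2 normal equations", {
  f <- fit_response(0:3, (0:3)^2, "PARABOLA")
  expect_equal(unname(unlist(f$params[c("a", "b", "c")])), c(0, 0, 1),
               tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-18)
  fc <- fit_response(0:4, rep(5, 5), "PARABOLA")
  expect_equal(unname(unlist(fc$params[c("a", "b", "c")])), c(5, 0, 0),
               tolerance = 1e-10)
  set.seed(12)
  for (i in 1:5) {
    x <- runif(12, 0, 10); y <- 2 + x - 0.1 * x^2 + rnorm(12, 0, 0.3)
    f <- fit_response(x, y, "PARABOLA")
    o <- lm(y ~ x + I(x^2))
    expect_equal(unname(unlist(f$params[c("a", "b", "c")])),
                 unname(coef(o)), tolerance = 1e-9)
  }
})

test_that("reciprocal-quadratic fits on the transform scale, rss on the original", {
  x <- 0:3; y <- 1 / (1 + x)
  f <- fit_response(x, y, "RECIP_QUAD")
  expect_equal(unname(unlist(f$params[c("a", "b", "c")])), c(1, 1, 0),
               tolerance = 1e-9)
  expect_equal(f$rss, 0, tolerance = 1e-18)
  expect_error(fit_response(0:3, c(0.5, 0, 0.2, 0.1), "RECIP_QUAD"),
               "non-positive")
  set.seed(13)
  for (i in 1:5) {
    x <- runif(10, 0, 5)
    y <- 1 / (0.5 + 0.1 * x + 0.02 * x^2) + runif(10, 0, 0.05)
    f <- fit_response(x, y, "RECIP_QUAD")
    o <- lm(I(1 / y) ~ x + I(x^2))
    expect_equal(unname(unlist(f$params[c("a", "b", "c")])),
                 unname(coef(o)), tolerance = 1e-9)
    expect_equal(f$rss,
                 sum((y - 1 / (coef(o)[1] + coef(o)[2] * x +
                                 coef(o)[3] * x^2))^2),
                 tolerance = 1e-9)
  }
})

test_that("Cauchy fits recover generating parameters and flag degeneracy", {
  x <- seq(10, 90, length.out = 15)
  y <- evaluate_response(response_params("CAUCHY", k = 10, x_max = 50,
                                         r = 20), x)
  f <- fit_response(x, y, "CAUCHY")
  expect_true(f$converged)
  expect_equal(unname(unlist(f$params[c("k", "x_max", "r")])),
               c(10, 50, 20), tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  # flat response: r unidentifiable
  fd <- fit_response(1:6, rep(4, 6), "CAUCHY")
  expect_false(fd$converged)
  # noisy consistency: estimates centred on the truth
  set.seed(14)
  x <- seq(10, 90, length.out = 40)
  est <- t(replicate(60, {
    y <- evaluate_response(response_params("CAUCHY", k = 10, x_max = 50,
                                           r = 20), x) + rnorm(40, 0, 0.01)
    unlist(fit_response(x, y, "CAUCHY")$params[c("k", "x_max", "r")])
  }))
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - c(10, 50, 20)) < 4 * mc_se + 1e-4))
})

test_that("logistic fits profile the base and respect constraints", {
  x <- 0:6; y <- 1 / (2 + 3 * 0.5^x)
  f <- fit_response(x, y, "LOGISTIC")
  expect_true(f$converged)
  expect_equal(unname(unlist(f$params[c("a", "b", "c")])), c(2, 3, 0.5),
               tolerance = 1e-6)
  # decreasing response needs b < 0, which is outside the family
  fdec <- fit_response(0:5, 1 / (2 + 3 * 0.5^(5:0)), "LOGISTIC")
  expect_false(fdec$converged)
  expect_gte(fdec$params$b, 0)
  # constant response: flat curve with b ~ 0, a ~ 1/y
  fcst <- fit_response(0:5, rep(0.25, 6), "LOGISTIC")
  expect_equal(fcst$params$a, 4, tolerance = 1e-6)
  expect_equal(fcst$params$b, 0, tolerance = 1e-6)
  expect_equal(sd(evaluate_response(fcst$params, 0:5)), 0, tolerance = 1e-8)
})

test_that("Gaussian fits recover parameters; symmetric data centre the optimum", {
  x <- seq(0, 6, length.out = 11)
  y <- evaluate_response(response_params("NORMAL", k = sqrt(2 * pi),
                                         x_max = 3, r = 1), x)
  f <- fit_response(x, y, "NORMAL")
  expect_true(f$converged)
  expect_equal(unname(unlist(f$params[c("k", "x_max", "r")])),
               c(sqrt(2 * pi), 3, 1), tolerance = 1e-6)
  expect_error(fit_response(x, c(y[-11], 0), "NORMAL"), "non-positive")
  # exactly symmetric responses about x = 3 put the optimum at 3
  ys <- exp(-(x - 3)^2 / 5)
  expect_equal(fit_response(x, ys, "NORMAL")$params$x_max, 3,
               tolerance = 1e-8)
})

test_that("refinement never does worse than the transform initializer", {
  set.seed(15)
  x <- seq(2, 8, length.out = 12)
  for (i in 1:10) {
    k <- runif(1, 5, 10); xm <- runif(1, 4, 7); r <- runif(1, 1.5, 3)
    y <- k / (1 + ((x - xm) / r)^2) + rnorm(12, 0, 0.3)
    if (any(y <= 0)) next
    # the initializer the Cauchy fit starts from, reproduced independently
    q <- coef(lm(I(1 / y) ~ x + I(x^2)))
    f <- fit_response(x, y, "CAUCHY")
    if (q[3] > 0 && (q[1] - q[3] * (q[2] / (2 * q[3]))^2) > 0) {
      xm0 <- -q[2] / (2 * q[3]); k0 <- 1 / (q[1] - q[3] * xm0^2)
      r0 <- sqrt(1 / (k0 * q[3]))
      rss0 <- sum((y - k0 / (1 + ((x - xm0) / r0)^2))^2)
      expect_lte(f$rss, rss0 + 1e-10)
    }
  }
})

test_that("independent nonlinear optimizer agrees on noisy Cauchy fits", {
  skip_if_not_installed("minpack.lm")
  set.seed(16)
  x <- seq(2, 8, length.out = 16)
  y <- 8 / (1 + ((x - 6) / 2)^2) + rnorm(16, 0, 0.2)
  f <- fit_response(x, y, "CAUCHY")
  o <- minpack.lm::nlsLM(
    y ~ k / (1 + ((x - xm) / r)^2),
    start = list(k = max(y), xm = 6, r = 2),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14))
  expect_equal(f$rss, sum(resid(o)^2), tolerance = 1e-7)
  expect_equal(unname(unlist(f$params[c("k", "x_max", "r")])),
               unname(coef(o)), tolerance = 1e-4)
})

test_that("fitting a whole table skips unfittable genotypes and is deterministic", {
  m <- rbind(G1 = c(2, 4, 6, 8), G2 = c(3, 5, 7, 9), G3 = c(1, 2, 4, 8),
             G4 = c(4, 4.5, 5, 5.5), G5 = c(2, 3, 5, 6))
  colnames(m) <- paste0("E", 1:4)
  tab <- table_from_matrix(m)
  fits <- fit_all_genotypes(tab, "LINEAR")
  expect_length(fits$fits, 5)
  expect_equal(nrow(fits$skipped), 0)
  # genotype seen in only 2 environments lands in the skip list
  m2 <- m; m2 <- rbind(m2, G6 = c(1, 2, NA, NA))
  tab2 <- table_from_matrix(m2)
  fits2 <- fit_all_genotypes(tab2, "LINEAR")
  expect_equal(fits2$skipped$genotype, "G6")
  expect_length(fits2$fits, 5)
  # determinism: identical object on repeat runs
  sim <- simulate_met(met_sim_config(n_genotypes = 8, n_environments = 10,
                                     family = "CAUCHY", seed = 5))
  tab3 <- compute_environment_index(sim$records)
  expect_identical(fit_all_genotypes(tab3, "CAUCHY", seed = 2),
                   fit_all_genotypes(tab3, "CAUCHY", seed = 2))
})

test_that("adding a constant to one genotype shifts its intercept, not its slope", {
  m <- rbind(G1 = c(2, 4, 5, 7), G2 = c(3, 4, 6, 7), G3 = c(1, 3, 5, 6))
  colnames(m) <- paste0("E", 1:4)
  tab <- table_from_matrix(m)
  f1 <- fit_genotype(tab, "G2", "LINEAR")
  y2 <- tab$means["G2", ] + 10
  f2 <- fit_response(tab$env_index, y2, "LINEAR")
  expect_equal(f2$params$b, f1$params$b, tolerance = 1e-12)
  expect_equal(f2$params$a, f1$params$a + 10, tolerance = 1e-10)
})

test_that("parameter estimates sharpen as noise shrinks", {
  # median recovery error decreases with the noise sd for each family
  set.seed(17)
  x <- seq(2, 8, length.out = 20)
  sds <- c(0.5, 0.1, 0.01)
  for (family in c("LINEAR", "PARABOLA", "CAUCHY", "NORMAL")) {
    med <- sapply(sds, function(s) {
      errs <- replicate(30, {
        p <- random_params(family)
        y <- evaluate_response(p, x) + rnorm(length(x), 0, s)
        if (family %in% c("CAUCHY", "NORMAL") && any(y <= 0)) return(NA)
        f <- tryCatch(fit_response(x, y, family), error = function(e) NULL)
        if (is.null(f)) return(NA)
        th <- unlist(p[names(p) != "family"])
        max(abs(unlist(f$params[names(th)]) - th) / pmax(abs(th), 1))
      })
      median(errs, na.rm = TRUE)
    })
    expect_true(all(diff(med) < 0), label = paste(family, "error monotone"))
  }
})
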