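test_that("two-way sums of squares match hand decomposition", {
  # 2x2 cell means [[0,2],[0,4]], one rep: interaction residuals +-0.5
  m <- rbind(G1 = c(0, 2), G2 = c(0, 4))
  colnames(m) <- c("E1", "E2")
  rec <- records_from_matrix(m)
  an <- anova_partition(rec)
  expect_equal(an$ss_GxE, 1.0)
  expect_equal(an$df_GxE, 1L)
  expect_equal(an$ss_error, 0)
  # additive table has zero interaction
  g <- c(1, 2, 4); e <- c(0, 3, 5, 6)
  madd <- outer(g, e, `+`)
  dimnames(madd) <- list(paste0("G", 1:3), paste0("E", 1:4))
  expect_equal(anova_partition(records_from_matrix(madd))$ss_GxE, 0,
               tolerance = 1e-12)
})

test_that("ANOVA equals the brute-force oracle on random layouts", {
  set.seed(21)
  for (i in 1:10) {
    G <- sample(3:6, 1); E <- sample(4:8, 1); B <- sample(2:3, 1)
    m <- matrix(rnorm(G * E, 5, 2), G, E,
                dimnames = list(paste0("G", 1:G), paste0("E", 1:E)))
    rec <- records_from_matrix(m, blocks = B, noise_sd = 1, seed = i)
    an <- anova_partition(rec)
    bf <- brute_force_anova(rec)
    for (comp in names(bf)) {
      expect_equal(an[[comp]], bf[[comp]], tolerance = 1e-9,
                   label = comp)
    }
    expect_equal(an$ss_total, an$ss_G + an$ss_E + an$ss_GxE + an$ss_error,
                 tolerance = 1e-8 * an$ss_total)
  }
})

test_that("imbalance is handled by the complete-genotype rule, then errors", {
  m <- rbind(G1 = c(2, 4, 6), G2 = c(3, 5, 7), G3 = c(1, 2, 3))
  colnames(m) <- paste0("E", 1:3)
  rec <- records_from_matrix(m, blocks = 2)
  # genotype missing one environment is excluded with a warning
  rec_inc <- rec[!(rec$genotype == "G3" & rec$environment == "E2"), ]
  expect_warning(an <- anova_partition(rec_inc), "G3")
  expect_equal(an$n_genotypes, 2L)
  # unequal replicate counts within a kept cell is an error naming it
  rec_bad <- rec[-which(rec$genotype == "G1" & rec$environment == "E1" &
                          rec$block == "B2"), ]
  expect_error(anova_partition(rec_bad), "G1.*E1")
})

test_that("linear partition reduces to heterogeneity of regressions", {
  # worked 2x2 example: ss_GxE = 1, linear fits are exact, pct = 100,
  # and the closed form n_reps * sum((b_i - 1)^2) * S_xx equals ss_GxE
  m <- rbind(G1 = c(0, 2), G2 = c(0, 4))
  colnames(m) <- c("E1", "E2")
  rec <- records_from_matrix(m)
  an <- anova_partition(rec)
  tab <- structure(list(genotypes = rownames(m), environments = colnames(m),
                        means = m, env_index = colMeans(m), n_reps = 1L,
                        year = "Y1"), class = "cell_means")
  # two-point "fits" are exact lines through the cells
  fits <- list(G1 = manual_fit("G1", "LINEAR", a = 0, b = 2 / 3),
               G2 = manual_fit("G2", "LINEAR", a = 0, b = 4 / 3))
  p <- partition_gxe(tab, fits, an)
  expect_equal(p$ss_residual, 0, tolerance = 1e-12)
  expect_equal(p$pct_explained, 100)
  x <- colMeans(m)
  sxx <- sum((x - mean(x))^2)
  het <- 1 * sum((c(2 / 3, 4 / 3) - 1)^2) * sxx
  expect_equal(het, an$ss_GxE)

  # random balanced tables: partition equals the closed form
  set.seed(22)
  for (i in 1:5) {
    G <- 6; E <- 8
    mm <- matrix(rnorm(G * E, 5, 1.5), G, E,
                 dimnames = list(paste0("G", 1:G), paste0("E", 1:E)))
    rec <- records_from_matrix(mm, blocks = 3, noise_sd = 0.5, seed = 30 + i)
    an <- anova_partition(rec)
    tab <- compute_environment_index(rec)
    fits <- fit_all_genotypes(tab, "LINEAR")
    p <- partition_gxe(tab, fits, an)
    x <- tab$env_index
    sxx <- sum((x - mean(x))^2)
    b <- vapply(fits$fits, function(f) f$params$b, 0)
    het <- an$n_reps * sum((b - 1)^2) * sxx
    expect_equal(p$ss_explained, het, tolerance = 1e-8 * max(het, 1))
    expect_equal(p$ss_explained + p$ss_residual, an$ss_GxE,
                 tolerance = 1e-8 * an$ss_GxE)
    # mean fitted slope is 1 when regressing on the column-mean index
    expect_equal(mean(b), 1, tolerance = 1e-10)
  }
})

test_that("exact fits explain all interaction; additive fits none", {
  # mirrored parabolas around the identity: the column means equal x, so
  # the responses are exact curves of their own environmental index
  x <- c(2, 3, 5, 6, 8, 9)
  m <- rbind(G1 = x + 0.08 * (x - 5)^2, G2 = x - 0.08 * (x - 5)^2)
  colnames(m) <- paste0("E", 1:6)
  rec <- records_from_matrix(m, blocks = 2)
  an <- anova_partition(rec)
  tab <- compute_environment_index(rec)
  expect_equal(unname(tab$env_index), x)
  expect_gt(an$ss_GxE, 0)
  fits <- fit_all_genotypes(tab, "PARABOLA")
  p <- partition_gxe(tab, fits, an)
  expect_equal(p$pct_explained, 100, tolerance = 1e-8)
  expect_equal(p$ss_residual, 0, tolerance = 1e-10)
  # additive predictions f_i(x_j) = rowmean_i + (x_j - mean(x)) explain none
  add_fits <- lapply(tab$genotypes, function(g) {
    manual_fit(g, "LINEAR", a = mean(m[g, ]) - mean(tab$env_index), b = 1)
  })
  names(add_fits) <- tab$genotypes
  p0 <- partition_gxe(tab, add_fits, an)
  expect_equal(p0$ss_explained, 0, tolerance = 1e-8 * an$ss_GxE)
  expect_lt(p0$pct_explained, 1e-6)
})

test_that("explained percentage is invariant to shift and positive rescaling", {
  set.seed(23)
  m <- matrix(rnorm(5 * 6, 6, 1), 5, 6,
              dimnames = list(paste0("G", 1:5), paste0("E", 1:6)))
  rec <- records_from_matrix(m, blocks = 2, noise_sd = 0.4, seed = 23)
  base <- percent_table(rec, families = "LINEAR")$pct_explained
  rec_shift <- rec; rec_shift$value <- rec$value + 100
  rec_scale <- rec; rec_scale$value <- rec$value * 7
  expect_equal(percent_table(rec_shift, families = "LINEAR")$pct_explained,
               base, tolerance = 1e-10)
  expect_equal(percent_table(rec_scale, families = "LINEAR")$pct_explained,
               base, tolerance = 1e-10)
  # scale invariance holds for the nonlinear families up to optimizer noise
  rec2 <- records_from_matrix(m + 2, blocks = 2, noise_sd = 0.3, seed = 24)
  rec2_scale <- rec2; rec2_scale$value <- rec2$value * 3
  expect_equal(
    percent_table(rec2_scale, families = "CAUCHY")$pct_explained,
    percent_table(rec2, families = "CAUCHY")$pct_explained,
    tolerance = 1e-4)
})

test_that("the percentage table stratifies by year and averages across years", {
  set.seed(25)
  recs <- do.call(rbind, lapply(1:2, function(yr) {
    sim <- simulate_met(met_sim_config(n_genotypes = 6, n_environments = 6,
                                       n_blocks = 2, family = "LINEAR",
                                       seed = yr))
    r <- sim$records; r$year <- paste0("Y", yr); r
  }))
  pt <- percent_table(recs, families = c("LINEAR", "PARABOLA"))
  expect_setequal(unique(pt$year), c("Y1", "Y2", "Average"))
  avg_lin <- pt$pct_explained[pt$year == "Average" & pt$family == "LINEAR"]
  expect_equal(avg_lin,
               mean(pt$pct_explained[pt$year != "Average" &
                                       pt$family == "LINEAR"]))
})

test_that("stability classes follow the slope t-test and the ER refinement", {
  # true slopes (1.9, 1, 0.1) average to 1, so against the index G2 tracks
  # the mean (b = 1), G1 is hypersensitive and G3 insensitive
  x <- c(1, 3, 5, 7, 9, 11)
  m <- rbind(G1 = 1.9 * x - 3, G2 = x + 0.3, G3 = 0.1 * x + 5.1)
  colnames(m) <- paste0("E", 1:6)
  rec <- records_from_matrix(m, blocks = 2, noise_sd = 0.15, seed = 26)
  tab <- compute_environment_index(rec)
  an <- anova_partition(rec)
  lin <- fit_all_genotypes(tab, "LINEAR")
  st <- classify_stability(lin, tab, alpha_level = 0.05,
                           error_ms = an$ss_error / an$df_error,
                           error_df = an$df_error)
  st <- st[order(st$genotype), ]
  expect_equal(st$fw_class, c("LOW_STABILITY", "AVERAGE", "HIGH_STABILITY"))
  # the t statistic matches its textbook construction
  g <- "G1"; f <- lin$fits[[g]]
  xc <- tab$env_index
  dev_ms <- f$rss / (f$n_obs - 2)
  se_b <- sqrt(dev_ms / sum((xc - mean(xc))^2))
  expect_equal(st$se_b[st$genotype == g], se_b, tolerance = 1e-12)
  expect_equal(st$p_value[st$genotype == g],
               2 * pt(-abs((f$params$b - 1) / se_b), f$n_obs - 2),
               tolerance = 1e-12)
  # borderline slopes with large standard errors stay AVERAGE
  mb <- rbind(G1 = 1.2 * x + rnorm(6, 0, 2.5), G2 = x, G3 = 0.9 * x)
  colnames(mb) <- paste0("E", 1:6)
  set.seed(27)
  tb <- table_from_matrix(mb)
  lb <- fit_all_genotypes(tb, "LINEAR")
  sb <- classify_stability(lb, tb)
  expect_true(sb$fw_class[sb$genotype == "G1"] == "AVERAGE")
  # er_stable demands average slope, low deviation MS and high mean yield
  expect_true(all(st$er_stable[st$fw_class != "AVERAGE"] == FALSE))
  # too few environments: NA report with a warning
  m4 <- rbind(G1 = c(1, 2, 3), G2 = c(2, 3, 4), G3 = c(1, 3, 5))
  colnames(m4) <- paste0("E", 1:3)
  t4 <- table_from_matrix(m4)
  l4 <- fit_all_genotypes(t4, "LINEAR")
  w <- capture_warnings(s4 <- classify_stability(l4, t4))
  expect_match(w, "estimable", all = FALSE)
  expect_true(all(is.na(s4$dev_ms)))
})
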