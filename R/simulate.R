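default_param_distributions <- function(family) {
  switch(family,
    LINEAR     = list(a = c(2, 0.5),     b = c(1, 0.3)),
    PARABOLA   = list(a = c(4, 0.5),     b = c(1.2, 0.3),  c = c(-0.12, 0.04)),
    RECIP_QUAD = list(a = c(0.5, 0.05),  b = c(-0.12, 0.02), c = c(0.01, 0.002)),
    CAUCHY     = list(k = c(8, 1),       x_max = c(7.5, 1), r = c(2.5, 0.6)),
    LOGISTIC   = list(a = c(0.125, 0.01), b = c(0.5, 0.1),  c = c(0.5, 0.1)),
    NORMAL     = list(k = c(50, 6),      x_max = c(7.5, 1), r = c(2.5, 0.6)),
    stop("unknown family: ", family)
  )
}

#' Configuration for a simulated multi-environment trial
#'
#' Defaults emulate a provincial barley variety-trial system: ~40 cultivars
#' grown at 16 sites in randomized complete blocks with 3 replications,
#' site quality (latent environmental value, trait units, e.g. t/ha yield)
#' spanning 2-8, and a residual sd of 0.4 (about 5% of the response range).
#'
#' @param n_genotypes,n_environments,n_blocks Layout counts (all >= 2,
#'   except `n_blocks >= 1`).
#' @param family Generating response family.
#' @param parameter_distributions Named list of `c(mean, sd)` pairs, one
#'   per family parameter, describing the across-genotype distribution;
#'   defaults depend on `family`.
#' @param env_quality Latent per-environment quality values `x*_j` (trait
#'   units); length `n_environments`.
#' @param noise_sd Residual standard deviation.
#' @param min_response Realism floor: parameter draws whose expected
#'   response dips below this value at any sampled environment are redrawn
#'   (viable cultivars do not yield near zero at trial sites; this also
#'   keeps simulated positive traits positive under noise).
#' @param seed RNG seed.
#' @return List of class `met_sim_config`.
#' @export
met_sim_config <- function(n_genotypes = 40L, n_environments = 16L,
                           n_blocks = 3L, family = "CAUCHY",
                           parameter_distributions = NULL,
                           env_quality = NULL, noise_sd = 0.4,
                           min_response = 1.5, seed = 1L) {
  family <- match.arg(family, RESPONSE_FAMILIES)
  if (n_genotypes < 2L || n_environments < 2L || n_blocks < 1L) {
    stop("counts too small: need >= 2 genotypes, >= 2 environments, >= 1 block")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(env_quality)) {
    env_quality <- seq(2, 8, length.out = n_environments)
  }
  if (length(env_quality) != n_environments) {
    stop("env_quality must have length n_environments")
  }
  if (is.null(parameter_distributions)) {
    parameter_distributions <- default_param_distributions(family)
  }
  if (!identical(sort(names(parameter_distributions)),
                 sort(family_param_names(family)))) {
    stop("parameter_distributions must name exactly: ",
         paste(family_param_names(family), collapse = ", "))
  }
  structure(list(n_genotypes = n_genotypes,
                 n_environments = n_environments, n_blocks = n_blocks,
                 family = family,
                 parameter_distributions = parameter_distributions,
                 env_quality = env_quality, noise_sd = noise_sd,
                 min_response = min_response, seed = seed),
            class = "met_sim_config")
}

draw_genotype_params <- function(config) {
  fam <- config$family
  pd <- config$parameter_distributions
  nm <- family_param_names(fam)
  for (attempt in 1:1000) {
    th <- vapply(nm, function(p) rnorm(1, pd[[p]][1], pd[[p]][2]),
                 numeric(1))
    p <- tryCatch(theta_to_params(fam, th), error = function(e) NULL)
    if (is.null(p)) next
    ok <- tryCatch({
      y <- evaluate_response(p, config$env_quality)
      all(is.finite(y)) && min(y) >= config$min_response
    }, error = function(e) FALSE)
    if (ok) return(p)
  }
  stop("could not draw valid ", fam,
       " parameters in 1000 attempts; check parameter_distributions")
}

#' Simulate a replicated multi-environment trial
#'
#' Generates `y_ijk = f_i(x*_j) + block_jk + e_ijk` where each genotype's
#' response curve `f_i` is drawn from the configured family with
#' genotype-specific parameters, `x*_j` is the latent environment quality,
#' block effects are `N(0, (noise_sd/2)^2)` nuisance shifts shared by all
#' genotypes of a block, and `e ~ N(0, noise_sd^2)`. The analysis pipeline
#' re-estimates the environmental index from the simulated data, so
#' index-estimation error is part of any end-to-end evaluation.
#'
#' @param config A [met_sim_config()].
#' @return List with `records` (long-format `data.frame`: year,
#'   environment, block, genotype, value) and `truth` (list with `params`,
#'   the per-genotype [response_params()], and `env_quality`).
#' @export
simulate_met <- function(config) {
  stopifnot(inherits(config, "met_sim_config"))
  with_seed(config$seed, {
    G <- config$n_genotypes; E <- config$n_environments
    B <- config$n_blocks
    gl <- sprintf("G%02d", seq_len(G))
    el <- sprintf("E%02d", seq_len(E))
    bl <- sprintf("B%d", seq_len(B))
    params <- setNames(lapply(seq_len(G), function(i) {
      draw_genotype_params(config)
    }), gl)
    fvals <- vapply(gl, function(g) {
      evaluate_response(params[[g]], config$env_quality)
    }, numeric(E))  # E x G
    block_eff <- matrix(rnorm(E * B, 0, config$noise_sd / 2), E, B)
    rec <- expand.grid(genotype = gl, block = bl, environment = el,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ei <- match(rec$environment, el)
    bi <- match(rec$block, bl)
    gi <- match(rec$genotype, gl)
    rec$value <- fvals[cbind(ei, gi)] + block_eff[cbind(ei, bi)] +
      rnorm(nrow(rec), 0, config$noise_sd)
    records <- data.frame(year = "Y1", environment = rec$environment,
                          block = rec$block, genotype = rec$genotype,
                          value = rec$value, stringsAsFactors = FALSE)
    list(records = records,
         truth = list(params = params, env_quality = config$env_quality))
  })
}

#' Haldane map function
#'
#' Recombination fraction between loci `d` centimorgans apart assuming no
#' interference: \eqn{r = (1 - e^{-2d/100}) / 2}.
#'
#' @param d Genetic distance(s) in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane(10) # ~0.0906
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d / 100))
}

#' Configuration for a doubled-haploid population simulation
#'
#' Defaults mirror a barley biparental mapping population: 150 DH lines and
#' 223 markers over seven chromosomes (37/37/31/33/29/22/34 markers), each
#' chromosome 150 cM with equally spaced markers. QTL effects have a base
#' component plus a component that scales with environment quality, so
#' that effects are larger in good than in poor environments.
#'
#' @param chrom_marker_counts Integer vector of markers per chromosome.
#' @param chrom_lengths_cM Map length per chromosome (recycled).
#' @param n_lines Number of DH lines.
#' @param qtl `data.frame` with columns `marker` (index into the full
#'   marker vector), `base` (effect at `x* = 0`, trait units per allele),
#'   `scale` (effect change per unit of environment quality).
#' @param h2 Broad-sense heritability targeted at the median environment.
#' @param mu Overall trait mean.
#' @param env_quality Latent environment quality values (centered scale).
#' @param seed RNG seed.
#' @return List of class `dh_sim_config`.
#' @export
dh_sim_config <- function(chrom_marker_counts = c(37L, 37L, 31L, 33L, 29L,
                                                  22L, 34L),
                          chrom_lengths_cM = 150,
                          n_lines = 150L,
                          qtl = data.frame(marker = c(19L, 90L, 155L),
                                           base = c(0.5, 0.4, 0.3),
                                           scale = c(0.15, 0.12, 0.10)),
                          h2 = 0.7, mu = 8,
                          env_quality = seq(-2, 2, length.out = 16L),
                          seed = 1L) {
  p <- sum(chrom_marker_counts)
  if (!all(qtl$marker >= 1 & qtl$marker <= p)) {
    stop("qtl marker indices must be in 1..", p)
  }
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  chrom_lengths_cM <- rep_len(chrom_lengths_cM,
                              length(chrom_marker_counts))
  structure(list(chrom_marker_counts = as.integer(chrom_marker_counts),
                 chrom_lengths_cM = chrom_lengths_cM,
                 n_lines = as.integer(n_lines), qtl = qtl, h2 = h2,
                 mu = mu, env_quality = env_quality, seed = seed),
            class = "dh_sim_config")
}

#' Simulate a doubled-haploid biparental marker panel
#'
#' One gamete per chromosome per line is generated by a Markov walk along
#' the marker map: the first allele is -1/+1 with probability 1/2 and each
#' subsequent marker switches parental origin with the Haldane
#' recombination fraction of its spacing. Chromosome doubling makes lines
#' fully homozygous, so the gamete is the line genotype.
#'
#' @param config A [dh_sim_config()].
#' @return A [marker_panel()].
#' @export
simulate_dh_population <- function(config) {
  stopifnot(inherits(config, "dh_sim_config"))
  with_seed(config$seed, {
    n <- config$n_lines
    geno_chr <- list()
    map_chr <- list()
    for (ch in seq_along(config$chrom_marker_counts)) {
      m <- config$chrom_marker_counts[ch]
      pos <- if (m == 1L) 0 else seq(0, config$chrom_lengths_cM[ch],
                                     length.out = m)
      G <- matrix(0, n, m)
      G[, 1] <- sample(c(-1, 1), n, replace = TRUE)
      if (m > 1L) {
        rfrac <- haldane(diff(pos))
        switch_mat <- matrix(runif(n * (m - 1L)), n, m - 1L) <
          matrix(rfrac, n, m - 1L, byrow = TRUE)
        flip <- 1 - 2 * switch_mat           # -1 where a crossover occurs
        for (j in 2:m) G[, j] <- G[, j - 1L] * flip[, j - 1L]
      }
      geno_chr[[ch]] <- G
      map_chr[[ch]] <- data.frame(
        marker = sprintf("C%dM%02d", ch, seq_len(m)),
        chromosome = ch, position = pos, stringsAsFactors = FALSE)
    }
    genotypes <- do.call(cbind, geno_chr)
    map <- do.call(rbind, map_chr)
    rownames(genotypes) <- sprintf("DH%03d", seq_len(n))
    colnames(genotypes) <- map$marker
    marker_panel(genotypes, map)
  })
}

#' Simulate line-by-environment phenotypes with environment-scaled QTL
#'
#' Generates `y_ij = mu + x*_j + sum_q g_iq (base_q + scale_q x*_j) + e_ij`.
#' Positive `scale_q` makes QTL effects larger in good (high `x*`)
#' environments than in poor ones — the generating model behind the
#' expectation that marker effects are more pronounced in good
#' environments. The residual sd is set so the broad-sense heritability at
#' the median environment equals `config$h2`.
#'
#' @param panel Panel from [simulate_dh_population()].
#' @param config The same [dh_sim_config()].
#' @param env_quality Optional override of `config$env_quality`.
#' @return List with `phenotypes` (lines x environments matrix), `records`
#'   (long format, single block), and `truth` (list with `qtl`,
#'   `env_quality`, `residual_sd`).
#' @export
simulate_dh_phenotypes <- function(panel, config, env_quality = NULL) {
  stopifnot(inherits(panel, "marker_panel"),
            inherits(config, "dh_sim_config"))
  if (is.null(env_quality)) env_quality <- config$env_quality
  with_seed(config$seed + 1L, {
    n <- length(panel$lines); E <- length(env_quality)
    Gq <- panel$genotypes[, config$qtl$marker, drop = FALSE]
    xq <- median(env_quality)
    gmed <- drop(Gq %*% (config$qtl$base + config$qtl$scale * xq))
    vg <- var(gmed)
    if (config$h2 >= 1 && vg == 0) {
      stop("h2 = 1 with zero genetic variance is not satisfiable")
    }
    res_sd <- if (config$h2 <= 0) {
      if (vg == 0) 1 else sqrt(vg) * 10
    } else sqrt(vg * (1 - config$h2) / config$h2)
    pheno <- matrix(NA_real_, n, E,
                    dimnames = list(panel$lines,
                                    sprintf("E%02d", seq_len(E))))
    for (j in seq_len(E)) {
      eff <- config$qtl$base + config$qtl$scale * env_quality[j]
      pheno[, j] <- config$mu + env_quality[j] + drop(Gq %*% eff) +
        rnorm(n, 0, res_sd)
    }
    records <- data.frame(
      year = "Y1",
      environment = rep(colnames(pheno), each = n),
      block = "B1",
      genotype = rep(rownames(pheno), times = E),
      value = as.vector(pheno), stringsAsFactors = FALSE)
    list(phenotypes = pheno, records = records,
         truth = list(qtl = config$qtl, env_quality = env_quality,
                      residual_sd = res_sd))
  })
}
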