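# nlgxe — linear and non-linear genotype-by-environment interaction

`nlgxe` is an R toolkit for breeders and quantitative geneticists analysing
multi-environment trials (MET). It extends classic joint-regression
stability analysis — the regression of each genotype's performance on the
*environmental index* `x_j` (the mean of all genotypes in environment `j`)
— to non-linear reaction norms, and asks two questions:

1. **How much of the G×E interaction does each response family explain?**
   Per genotype, five curves are fitted against the index —

   | family | curve |
   |---|---|
   | linear | `y = a + b x` |
   | parabola | `y = a + b x + c x²` |
   | reciprocal quadratic | `y = 1/(a + b x + c x²)` |
   | Cauchy | `y = k / (1 + ((x − x_max)/r)²)` |
   | logistic | `y = 1/(a + b cˣ)`, `0 < c < 1` |
   | Gaussian | `y = k/√(2πr²) · exp(−(x − x_max)²/(2r²))` |

   — and the two-way ANOVA interaction sum of squares is split into a
   component explained by the fitted curves and a residual (the linear
   case reduces exactly to the classical heterogeneity-of-regressions sum
   of squares `r Σᵢ (bᵢ − 1)² S_xx`). Genotypes are classified by
   Finlay–Wilkinson stability (t-test of `b = 1`) with the
   Eberhart–Russell refinement (low deviation mean square, high mean
   yield).

2. **Do marker effects change with environment quality?** For a
   doubled-haploid biparental panel, line phenotypes at the *poor*
   (minimum index), *average* (mean) and *good* (maximum) environments are
   derived from the per-line linear responses, and all marker effects are
   estimated jointly by elastic-net regression (`α = 0.5` and `α = 1`,
   i.e. LASSO), fitted by cyclic coordinate descent with KKT-certified
   solutions and cross-validated penalty choice.

Seeded simulators for replicated RCBD trials under any response family and
for DH marker panels (Haldane meiosis, QTL effects that scale with
environment quality) make every claim testable end-to-end. See the
methods vignette (`vignettes/nonlinear-gxe.Rmd`) for the model details and
design choices.

## Worked example

Simulate a 30-genotype × 20-environment × 3-block trial whose genotypes
follow heterogeneous Cauchy reaction norms, then partition the G×E:

```r
library(nlgxe)
sim <- simulate_met(met_sim_config(n_genotypes = 30, n_environments = 20,
                                   n_blocks = 3, family = "CAUCHY", seed = 42))
percent_table(sim$records,
              families = c("LINEAR", "LOGISTIC", "PARABOLA", "NORMAL", "CAUCHY"),
              seed = 42)[, c("year", "family", "pct_explained")]
#>   year   family pct_explained
#> 1   Y1   LINEAR         40.75
#> 2   Y1 LOGISTIC         30.07
#> 3   Y1 PARABOLA         58.74
#> 4   Y1   NORMAL         59.31
#> 5   Y1   CAUCHY         59.71
```

The Cauchy family (the generating truth) explains the largest share of the
interaction sum of squares; the linear model lumps suboptimal and
super-optimal sites together and captures much less. Stability
classification from the same data:

```r
tab <- compute_environment_index(sim$records)
lin <- fit_all_genotypes(tab, "LINEAR", seed = 42)
an  <- anova_partition(sim$records)
st  <- classify_stability(lin, tab, error_ms = an$ss_error / an$df_error,
                          error_df = an$df_error)
table(st$fw_class)
#>        AVERAGE HIGH_STABILITY  LOW_STABILITY
#>              9              8             13
```

A genome scan on a simulated DH population (150 lines, 223 markers over 7
chromosomes, 16 environments) with three QTL planted at markers 19, 90 and
155 whose effects grow with environment quality:

```r
cfg   <- dh_sim_config(seed = 42)
panel <- simulate_dh_population(cfg)
ph    <- simulate_dh_phenotypes(panel, cfg)
tab   <- compute_environment_index(ph$phenotypes)
rp    <- representative_phenotypes(tab, fit_all_genotypes(tab, "LINEAR", seed = 42))
sc    <- genome_scan(panel, rp, enet_config(alpha = 1, seed = 42))
head(scan_table(panel, sc)[order(-abs(scan_table(panel, sc)$effect_good)), ], 3)
#>     marker chromosome position effect_poor effect_average effect_good
#> 19   C1M19          1     75.0      0.1070         0.4179      0.6520
#> 90   C3M16          3     75.0      0.0465         0.3442      0.6038
#> 155  C5M17          5     85.7      0.0656         0.2623      0.4176
```

The three strongest effects sit exactly at the planted QTL, and every
effect is larger in the good environment than in the poor one — effect
sizes, not just curve shapes, carry the interaction.

A command-line wrapper with subcommands (`simulate-met`, `simulate-dh`,
`index`, `fit`, `partition`, `stability`, `scan`, `run`) is installed at
`system.file("cli", "nlgxe.R", package = "nlgxe")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","nlgxe.R",package="nlgxe"))')" \
    simulate-met --out trial --seed 42
```

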