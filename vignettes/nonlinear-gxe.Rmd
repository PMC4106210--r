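---
title: "Modelling linear and non-linear genotype-by-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling linear and non-linear genotype-by-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlgxe)
```

## The problem

Genotypes rarely rank the same way in every environment. In
multi-environment trials (MET) this genotype-by-environment interaction
(G×E) is classically analysed by joint regression: each genotype's mean
performance $\bar y_{ij}$ is regressed on the *environmental index* $x_j$,
the mean of all genotypes in environment $j$,

$$y_{ij} = a_i + b_i x_j + \delta_{ij},$$

and the slope $b_i$ measures sensitivity: $b_i = 1$ is average stability,
$b_i > 1$ hypersensitive (low stability), $b_i < 1$ insensitive (high
stability). The refinement of Eberhart and Russell adds two more
requirements for a genotype to be called stable: a small
deviation-from-regression mean square and a high mean yield.

A straight line, however, lumps together suboptimal and super-optimal
conditions. When trials span a wide environmental range, genotype
responses rise from poor performance at suboptimal sites to an optimum and
decline again at super-optimal ones, and the linear model can absorb only
a small share of the interaction. `nlgxe` therefore fits, per genotype,
five response families against the same index:

| family | curve | free parameters |
|---|---|---|
| LINEAR | $a + b x$ | $a, b$ |
| PARABOLA | $a + b x + c x^2$ | $a, b, c$ |
| RECIP_QUAD | $1/(a + b x + c x^2)$ | $a, b, c$ |
| CAUCHY | $k / \{1 + ((x - x_{max})/r)^2\}$ | $k, x_{max}, r$ |
| LOGISTIC | $1/(a + b\,c^{x})$, $0 < c < 1$ | $a, b, c$ |
| NORMAL | $k/\sqrt{2\pi r^2}\, e^{-(x - x_{max})^2/(2r^2)}$ | $k, x_{max}, r$ |

For the peaked families, $x_{max}$ is the optimum environment, $r$ the
width of the response range and $k$ the peak scale; the Cauchy curve is
allowed any $k > 0$ (the fitted peak in trait units) and the conventional
0–1 scale is recovered by `standardize_cauchy()`, which maps points to
$x' = (x - x_{max})/r$, $y' = y/k$ so that an exact Cauchy response obeys
$y' = 1/(1 + x'^2)$. Near the optimum all the standardized curves are
indistinguishable — `quadratic_approx_error()` quantifies how fast the
quadratic approximation $1 - x'^2$ degrades, namely as $x'^4/(1 + x'^2)$.

## Fitting

Each family is estimated per genotype by least squares on the original
trait scale, started from the natural linearization:

* RECIP_QUAD is plain OLS of $1/\bar y$ on $(x, x^2)$ (the fit itself is a
  transform-scale fit; the reported RSS is on the original scale so
  families are comparable).
* CAUCHY: $1/y$ is quadratic in $x$; the quadratic's vertex and curvature
  give $(k, x_{max}, r)$, refined by damped Gauss–Newton
  (Levenberg–Marquardt style) with analytic Jacobians.
* NORMAL: $\log y$ is quadratic in $x$ with negative curvature; same
  refinement.
* LOGISTIC: for fixed base $c$, $(a, b)$ is OLS of $1/y$ on $c^x$; the
  base is profiled over 50 log-spaced values in $[0.01, 0.99]$ and
  polished by golden-section search, then all three parameters are
  refined on the original scale.

The refinement accepts a step only if it reduces the RSS and keeps the
parameters in the family's valid region ($k, r > 0$; $0 < c < 1$ and
$a > 0$, $b \ge 0$ for LOGISTIC; positive denominators at every design
point), so a fit can never end worse than its initializer. Convergence is
declared at a gradient norm below $10^{-8}$ (scaled by the RSS), a step
norm below $10^{-10}$, or three consecutive relative RSS improvements
below $10^{-13}$, with at most 500 iterations. When the linearizing
transform is infeasible (e.g. the reciprocal quadratic opens downward),
20 seeded multi-starts draw $x_{max}$ uniformly over the observed index
range, $r$ over 0.1–2 times that range and the peak over 0.5–2 times the
maximum response; the best RSS wins, ties broken toward smaller $r$.
Degenerate inputs are flagged rather than forced: a flat response leaves
$r$ unidentifiable (`converged = FALSE`), a decreasing response demands
$b < 0$ in the logistic family and is reported unconverged at the
constraint boundary, and the positive-response families refuse
non-positive trait values instead of silently shifting them.

A genotype needs at least one more environment than free parameters
(3 for LINEAR, 4 for the rest). `fit_all_genotypes()` skips genotypes
failing these preconditions and lists the reason; all stochastic pieces
are seeded, so rerunning with the same seed is bit-identical.

## Partitioning G×E by response family

`anova_partition()` computes the balanced two-way decomposition
($SS_G$, $SS_E$, $SS_{G\times E}$, within-cell error) by direct mean
summation; genotypes absent from some environment are excluded first
(largest complete-genotype subset, with a warning; no imputation).

The share of interaction a family captures is computed from the per-cell
deviations $\delta_{ij} = \bar y_{ij} - \hat f_i(x_j)$: the deviations are
double-centered (genotype and environment margins removed), the residual
interaction is $r\sum \tilde\delta_{ij}^2$, and the explained component is
$SS_{G\times E}$ minus that residual (floored at zero and flagged if a
family does worse than the additive model). This construction was chosen
because it reduces *exactly* to the classical heterogeneity-of-regressions
sum of squares $r\sum_i (b_i - 1)^2 S_{xx}$ for the linear family and
guarantees the decomposition identity
`ss_explained + ss_residual = ss_GxE` for every family. The percentage is
reported as `NA` when $SS_{G\times E}$ is zero.

One statistical property of this (or any comparable) construction deserves
emphasis: when the true responses are parallel, $SS_{G\times E}$ is pure
replication noise, and the share absorbed by per-genotype curves
concentrates at its degrees-of-freedom ratio rather than at zero —
approximately $(G-1)/\{(G-1)(E-1)\} = 1/(E-1)$ for the linear family and
about $2/(E-1)$ for the three-parameter families, *independent of the
noise level*. With 20 environments that noise floor is roughly 5% and
10%; it falls below 5% for every family only once $E$ approaches 80.
Percentages near these floors should be read as "nothing beyond noise".

`classify_stability()` tests $H_0\!: b_i = 1$ with a two-sided t-test on
$n_i - 2$ degrees of freedom (default level 0.05) rather than comparing
$\hat b_i$ to 1 directly, because under noise a raw comparison classifies
every genotype as non-average. "Low deviation variance" for the
Eberhart–Russell flag means the deviation mean square is not significantly
above the pooled error mean square by an F-test when replicates are
available, and at or below the across-genotype median otherwise; "high
mean yield" means above the median genotype mean.

The paper-style analysis sequence is `percent_table()` (one analysis per
year stratum plus the across-year average) and is orchestrated end-to-end,
with CSV/JSON outputs, by `run_pipeline()` and the `inst/cli/nlgxe.R`
subcommand script (`simulate-met`, `simulate-dh`, `index`, `fit`,
`partition`, `stability`, `scan`, `run`).

## Marker effects at poor, average and good environments

For a doubled-haploid (DH) biparental panel the interest shifts from
curves to effect sizes: does a QTL act more strongly in good environments?
Because DH line responses to the index are predominantly linear, each
line's fitted line is evaluated at three representative points of the
environmental index — its minimum (poor), mean (average) and maximum
(good) — giving three phenotype vectors (`representative_phenotypes()`;
observed values at the extreme environments can be used instead by passing
those columns directly to `genome_scan()`).

Marker effects are then estimated jointly for all markers by elastic-net
regression,
$$\tfrac{1}{2n}\lVert y - X\beta\rVert^2 +
  \lambda\{\alpha\lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert^2\},$$
minimized by cyclic coordinate descent with the univariate soft-threshold
update, warm starts along a log-spaced penalty path from $\lambda_{max} =
\max_k |x_k^\top y|/(n\alpha)$ (the all-zero point), sequential
strong-rule screening, and a full Karush–Kuhn–Tucker check at every
penalty (tolerance $10^{-8}$; screening can therefore never change a
solution). The two shipped presets are $\alpha = 0.5$ (elastic net) and
$\alpha = 1$ (LASSO). The penalty is selected by 10-fold cross-validated
mean squared error with seeded fold assignment (minimum-MSE rule, ties
toward the sparser penalty); fold fits use a response-scaled tolerance
since they only rank penalties, while the final full-data fit is
KKT-certified at $10^{-7}$. The default scan path stops at
$\lambda_{max}/100$: with more markers than lines the unpenalized end of
the path is degenerate and cross-validation selects penalties far above
it. Markers are coded $-1/+1$ (the two homozygous DH classes), centred
and scaled to unit variance for fitting, and effects are reported back on
the $\pm 1$ coding scale, i.e. half the fitted difference between the
classes.

## What the simulators emulate

`simulate_met()` emulates a provincial variety-trial system: `y_ijk =
f_i(x*_j) + block_{jk} + e_ijk` with genotype-specific curves drawn from
the configured family, a randomized-complete-block layout, and latent
environment quality `x*_j`. Defaults: 40 genotypes, 16 sites, 3 blocks,
quality spanning 2–8 trait units (yield-like), residual sd 0.4 (≈ 5% of
the response range), block effects `N(0, (noise_sd/2)^2)` as a fixed
nuisance scale. For the Cauchy family the optima are drawn `N(7.5, 1)`
with range scale `N(2.5, 0.6)`: most sites are suboptimal and the best
sites sit near or beyond some genotypes' optima, the regime in which
curve choice matters. (With optima in the middle of the sampled range the
environmental index — the mean response — becomes non-monotone in latent
quality, and no function of the index can express much of the
interaction; that regime is reproducible by setting `x_max` centrally.)
Parameter draws violating a family constraint or predicting a response
below `min_response` (default 1.5, keeping simulated yields of viable
cultivars well away from zero) are redrawn, at most 1000 times. The
analysis pipeline re-estimates the index from the simulated records, so
index-estimation error is part of every end-to-end check.

`simulate_dh_population()` generates a DH biparental panel by one meiosis
per chromosome per line: a Markov walk along the marker map with Haldane
recombination fractions $r = \tfrac12(1 - e^{-2d/100})$ (no
interference — interference is irrelevant to the patterns studied here),
then chromosome doubling. Defaults mirror a barley mapping population:
150 lines, 223 markers over 7 chromosomes (37/37/31/33/29/22/34), and —
since real map lengths are not part of the emulated summary — 150 cM per
chromosome with equally spaced markers, a stated assumption.
`simulate_dh_phenotypes()` plants QTL whose allelic effect is
`base + scale * x*`, so a positive `scale` makes effects larger in good
environments; the residual sd is set to hit the target broad-sense
heritability (default 0.7, a mid-range value for yield in balanced DH
trials) at the median environment.

Not emulated: missing plots and unbalanced designs, spatial field trend,
epistasis, multi-parental crosses, genotyping error. Passing tests on
these generators therefore demonstrate correctness of the estimation and
partitioning machinery under the stated generating models, not robustness
to those additional features of real data.

## Numerical conventions and test scale

All percentages print with two decimals; all stochastic steps (parameter
draws, multi-starts, CV folds) derive from a single user seed and repeat
runs are byte-identical. The test suite exercises ANOVA and partition
identities on random layouts up to 6×8×3 against brute-force summation,
parameter recovery on 200 simulated genotypes per family and noise level,
the Table-style family ranking on one hundred 30×20×3 Cauchy-generated
trials, elastic-net optimality (KKT residuals below $10^{-7}$) on random
instances up to n = 60, p = 300 with `glmnet` as an independent
cross-check, Haldane calibration on 10,000 simulated lines, and genome
scans on twenty full-size DH populations; these sizes were chosen as the
smallest at which the qualitative claims are statistically stable.

## Known limitations

* The G×E partition assumes a complete genotype × environment table after
  the complete-case rule; there is no imputation or mixed-model shrinkage.
* Variance components are fixed-effects sums of squares, not REML
  estimates; no F-tests are attached to the non-linear explained
  components (their degrees of freedom are reported for reference only).
* The explained-share noise floor discussed above means family comparisons
  are informative about *relative* explanatory power; absolute percentages
  near the floor carry no signal.
* Multi-trait scans, interval mapping and permutation thresholds are out
  of scope; the scan output table is designed to feed external plotting or
  QTL software.
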