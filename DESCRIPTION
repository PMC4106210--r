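Package: nlgxe
Title: Linear and Non-Linear Genotype-by-Environment Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint-regression stability analysis and its non-linear
    extensions for multi-environment trials. Fits per-genotype response
    curves against the environmental index under five function families
    (linear, parabola, reciprocal-quadratic/Cauchy, logistic, Gaussian),
    partitions genotype-by-environment interaction variation into a
    curve-explained component and a residual, classifies genotypes by
    Finlay-Wilkinson stability with the Eberhart-Russell refinement, and
    estimates genome-wide marker effects at poor, average and good
    environments by elastic-net penalized regression fitted with cyclic
    coordinate descent. Includes seeded simulators for replicated
    randomized-complete-block trials under any response family and for
    doubled-haploid biparental marker panels with environment-scaled
    QTL effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
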