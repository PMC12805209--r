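# lcmshrink

MSE-optimal regularized estimation of between-group effects in two-level
latent covariate models.

## The problem

Contextual studies in psychology, education and epidemiology often ask how a
group-level aggregate of an individual predictor relates to an outcome: does
the *average* economic need of a district predict school achievement, over
and above each school's own need? The two-level latent covariate model
decomposes the predictor of individual *i* in group *j* as

    X_ij = U_j + R_ij,      U_j ~ N(mu_x, sigma2_bx),  R_ij ~ N(0, sigma2_wx)

and regresses the outcome on the *latent* group mean and the individual
deviation:

    Y_ij = beta_0 + beta_b U_j + beta_w R_ij + e_bj + e_wij.

The target is the between-group slope `beta_b`. For balanced data its ML
estimator is the ratio of ANOVA-type latent (co)variance estimates,

    beta_b_ML = s_bxy / s_bx,      s_bx = MS_b(x) - s_wx / n,

which is consistent but wildly unstable when the number of groups J and the
predictor's intraclass correlation ICC_X are small: `s_bx` is then often
estimated near (or below) zero and the ratio explodes.

## The estimator

`lcmshrink` implements a regularized Bayesian (Stein-type) alternative

    beta_b_B = lambda * s_bxy / (lambda * s_bx + (1 - lambda) * omega),

where `omega` is a gamma-prior location for the between-group variance and
`lambda = (J-1) / (J-1 + 2*eps)` weights the data against the prior
(`eps = 0` recovers ML exactly; `lambda -> 1` as J grows). The two prior
parameters are chosen *automatically* by minimizing an analytic estimate of
the estimator's mean squared error, derived from gamma/F approximations to
the sampling distributions of `s_bx` and `s_bxy`, with the ML estimate of
`beta_b` plugged in (empirical Bayes). The search is a grid over
`(lambda, omega)` with the `omega` region bounded by five standard
deviations of `s_bx`. Deliberate shrinkage bias is traded for a large
variance reduction; in small, low-ICC samples the RMSE drops by an order of
magnitude or more relative to ML.

Also included: analytic and delete-d jackknife standard errors, a
group-size balancing step for unbalanced data (seeded random deletion with
a 20% abort threshold), an ICC-indexed balanced data simulator, and a
Monte-Carlo engine comparing ML, the regularized estimator and its
known-slope benchmark variant by RMSE and relative bias.

## Worked example

```r
library(lcmshrink)
# a small, low-ICC two-level dataset: 20 groups of 15, ICC_X = 0.1,
# true beta_b = 0.5
d <- generate_dataset(scenario_spec(icc_x = 0.1, J = 20, n = 15, seed = 42), 1)
fit <- regularized_bayes(d)
summary(fit)
#> Call: regularized Bayesian between-group slope estimation
#>
#> Coefficients:
#>                            Estimate Std.Error
#> beta_b (regularized Bayes)  0.37644   0.28009
#> beta_b (ML)                 0.79470   0.73756
#>
#> Selected prior: eps = 4.268, omega = 0.1873, lambda = 0.69
#> Estimated MSE at optimum: 0.47185 (ML point: 0.80679)
```

The ML estimate (0.795) overshoots the generating slope 0.5 with a large
standard error; the regularized estimate (0.376, lambda = 0.69) is pulled
toward the prior and carries less than half the standard error. The
selected prior says the data's between-group information is worth about
`J - 1` observations against `2 * eps ~ 8.5` pseudo-observations of prior.

For data on disk, the command-line interface mirrors the same pipeline:

```sh
Rscript scripts/lcmshrink-cli.R --file data.csv --y score --x need \
    --group district --seed 1 --machine
```

It balances unequal groups (aborting if more than 20% of rows would be
deleted), prints the side-by-side summary above and, with `--machine`, a
tab-separated key-value block.

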