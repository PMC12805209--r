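---
title: "Methods: MSE-optimal shrinkage for the between-group slope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSE-optimal shrinkage for the between-group slope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmshrink)
```

## Model and assumptions

The two-level latent covariate model assumes J groups of equal size n, with
the predictor decomposed into independent normal components
$X_{ij} = U_j + R_{ij}$, $U_j \sim N(\mu_x, \sigma^2_{bx})$,
$R_{ij} \sim N(0, \sigma^2_{wx})$, and the outcome generated as
$Y_{ij} = \beta_0 + \beta_b U_j + \beta_w R_{ij} + e_{bj} + e_{wij}$ with
normal residuals at both levels. The estimand is the between-group slope
$\beta_b$, the regression of the outcome's group-level component on the
*latent* group mean $U_j$ rather than on the observed group mean — the
latent formulation avoids the attenuation bias of manifest aggregation.
Everything below assumes balance; unbalanced data are first trimmed to the
minimum group size by `balance_data()` (seeded random deletion, aborting
with a warning when more than the `threshold` fraction of rows — default
20% — would be lost).

## Sufficient statistics and the ML estimator

`sufficient_stats()` computes the pooled within (co)variance estimators
(sums of squares over $J(n-1)$), the between mean squares of the group
means (over $J-1$), and the latent between estimators
$\hat\sigma_{bx} = MS_b(x) - \hat\sigma_{wx}/n$ (and analogously for the
covariance and the outcome). The divisor convention is the unbiased one:
$E[\hat\sigma_{bx}] = \sigma^2_{bx}$ exactly, which the test suite pins by
Monte Carlo. The ML estimator is the plain ratio
$\hat\beta_b^{ML} = \hat\sigma_{bxy}/\hat\sigma_{bx}$, deliberately left
untruncated: its near-zero-denominator instability at small $J \cdot ICC_X$
is a real property the simulation engine must reproduce, so the package
never censors it outside the regularized path.

## Sampling distributions

Both between estimators are quadratic forms in the standardized vector of
the independent normal components. `build_quadform_reps()` constructs the
symmetric coefficient matrices explicitly and eigendecomposes them;
`gamma_rep_from_quadform()` maps each eigenvalue $c$ with multiplicity $m$
to a Gamma$(m/2,\, 2c)$ term. Two exact identities anchor the algebra and
are asserted in tests: the trace equals the estimator's mean, and twice the
sum of squared eigenvalues equals its variance. In closed form, with
$v_x = \sigma^2_{bx} + \sigma^2_{wx}/n$ (and $v_y$, $c_b$ the analogous
moments of the group means),

$$\mathrm{var}(\hat\sigma_{bx}) = \frac{2v_x^2}{J-1} +
  \frac{2\sigma^4_{wx}}{n^2 J(n-1)}, \qquad
  \mathrm{var}(\hat\sigma_{bxy}) = \frac{c_b^2 + v_x v_y}{J-1} +
  \frac{c_w^2 + \sigma^2_{wx}\sigma^2_{wy}}{J(n-1)\,n^2}.$$

The variance form splits into a positive-semidefinite between-group block
($J-1$ equal weights $v_x/(J-1)$) and a negative-weighted within
correction; the covariance form is indefinite and is represented as a
difference of gamma sums rather than forced positive.

## The shrinkage estimator and its F-form

The regularized estimator is
$\hat\beta_b^{B} = \lambda\hat\sigma_{bxy} / (\lambda\hat\sigma_{bx} +
(1-\lambda)\omega)$ with $\lambda(\epsilon, J) = (J-1)/(J-1+2\epsilon)$:
the gamma-prior shape $\epsilon$ acts as $2\epsilon$ pseudo-degrees of
freedom added to the $J-1$ between-group degrees of freedom, and $\omega$
is the prior location of the between-group variance. $\epsilon = 0$
recovers ML exactly for any $\omega$; $\lambda \to 0$ with $\omega > 0$ is
full shrinkage toward the prior-implied slope 0.

For the estimator's moments the ratio is treated as a ratio of independent
gamma variables (an F-type form). The numerator keeps its exact first two
moments. The denominator $\lambda\hat\sigma_{bx} + (1-\lambda)\omega$ is
matched by a gamma that stays in the chi-square$(J-1)$ shape family:
shape $k_D = \frac{J-1}{2}\,\bigl(m_D/(\lambda\sigma^2_{bx})\bigr)^2$ with
the exact mean $m_D$. Rationale: the dominant between term *is*
chi-square$(J-1)$-shaped, the prior shift adds mean without variance (so
the matched shape grows as shrinkage increases), and on the $\omega = 0$
ray — where the estimator algebraically equals ML for every $\lambda$ —
the matched distribution correctly does not change. A free two-moment
match was considered and rejected: it is dominated by the heavy tail of
$\hat\sigma_{bx}$ and leaves the inverse moments undefined over most of
the region of interest. Inverse moments require $k_D > 1$ (mean) and
$k_D > 2$ (variance); outside that region `estimator_distribution()`
signals a condition of class `lcmshrink_undefined_moment` naming the
offending degrees of freedom — for ML this happens whenever $J \le 5$,
which is the analytic counterpart of the fact that the exact ML estimator
has no finite moments when the denominator's density is positive at zero.
Mean, variance, MSE ($= \mathrm{var} + \mathrm{bias}^2$, an exact internal
identity) and SE follow.

These moments are approximations: they ignore the numerator–denominator
dependence, so at moderate-to-large samples the analytic MSE overstates the
empirical one (the analytic mean carries an $O(1/J)$ upward factor
$k_D/(k_D-1)$). The approximation is used for *ranking* priors, where its
bias is shared across the grid; the package's tests check it against
simulation only where the comparison is statistically meaningful.

## Estimated MSE and the plug-in rule

`estimated_mse()` evaluates the analytic MSE with every model parameter
replaced by a sample estimate: $\sigma^2_{bx} \to \max(\hat\sigma_{bx},0)$,
within slope by the pooled ratio, residual variances truncated at zero, and
$\beta_b$ by a plug-in value — the ML estimate in the practical estimator,
or the known true slope in the simulation-only benchmark variant (same
formula, different value). One further choice matters: the squared signal
$(\beta_b\sigma^2_{bx})^2 = E[\hat\sigma_{bxy}]^2$ is estimated by the
noise-corrected $\max(\hat\sigma_{bxy}^2 - \widehat{\mathrm{var}}
(\hat\sigma_{bxy}),\,0)$ rather than by the raw square. Without this
correction, sampling noise in $\hat\sigma_{bxy}$ masquerades as signal and
the optimizer chases extreme ML plug-ins; with it, the criterion collapses
to full shrinkage exactly when the observed covariance is within noise of
zero, which is what makes the empirical-Bayes estimator stable in the
cells where ML explodes. The nonnegativity of the resulting criterion is
guaranteed (Cauchy–Schwarz on the corrected terms) and tested.

## Grid search

`grid_search_prior()` evaluates the criterion on a grid of 100 uniformly
spaced $\lambda$ values on $[0.01, 1]$ crossed with 100 $\omega$ values on
$[0, d]$, where $d$ is five times the standard deviation of
$\hat\sigma_{bx}$ taken from its derived gamma distribution (with the
moment-based plug-in SD as a floor, so $d$ is always at least five SDs).
The resolution is exposed (`grid_n`). Grid points with undefined moments
are excluded, not imputed; if every point is excluded the search falls back
to ML with a warning. The ML special case lies in the grid, so the
minimized criterion never exceeds its ML value. Ties break toward the
least-shrinkage point (largest $\lambda$, then smallest $\omega$) —
among equal-criterion solutions the one with least deliberate bias is
preferred — implemented by grid ordering, so the search is exactly an
argmin and is reproduced by the exhaustive double loop in the tests. This
is a bounded local search by construction; no global-optimality claim is
made.

## Standard errors

The analytic SE is the square root of the derived distribution's variance
at the selected prior. Because the derived variance reflects the *believed*
precision under the prior (it can be very small under heavy shrinkage), the
delete-d jackknife over groups is offered as the resampling alternative and
is the more defensible choice in very small samples: all $\binom{J}{d}$
deletion patterns are enumerated up to 10,000, beyond which a seeded random
subset of 10,000 is used; the default is $d = \max(1, \lfloor\sqrt{J}
\rfloor)$. The delete-1 jackknife on a linear statistic reproduces the
closed-form SE of a mean, and delete-2 is tested against brute-force
enumeration.

## Synthetic data

`generate_dataset()` draws from the model with unit total variance on both
variables: $\sigma^2_{bx} = ICC_X$, $\sigma^2_{wx} = 1 - ICC_X$, and
residual variances solved from $\sigma^2_{eb} = ICC_Y - \beta_b^2 ICC_X$,
$\sigma^2_{ew} = (1-ICC_Y) - \beta_w^2(1-ICC_X)$. A combination is feasible
exactly when both are nonnegative; `check_icc_feasibility()` names the
binding constraint otherwise (for instance $\beta_b = 0.7$ at
$ICC_X = 0.5$, $ICC_Y = 0.2$ is infeasible, which is why the design's
between-slope list tops out at 0.6). Intercepts and $\mu_x$ are zero —
they cancel in every slope estimator. The default factorial design crosses
$ICC_X \in \{0.05, 0.1, 0.3, 0.5\}$, $J \in \{5, 10, 20, 30, 40\}$,
$n \in \{5, 15, 30\}$, $\beta_b \in \{0.2, 0.5, 0.6\}$,
$\beta_w \in \{0.2, 0.5, 0.7\}$ with $ICC_Y$ fixed at 0.2 — 540 feasible
cells, each defaulting to 5000 replications. Reproducibility is
counter-based: each (scenario seed, replication) pair derives an
independent RNG stream, so results are independent of execution order and
bit-identical under a repeated root seed.

What the generator does *not* emulate: unbalanced designs (test fixtures
are made by deleting rows from balanced draws), non-normal components,
measurement error in the outcome, and more than two levels. Passing tests
therefore show calibration and comparative performance under the model's
own assumptions, not robustness to their violation.

## Monte-Carlo study engine

`run_scenario()` applies ML, the regularized estimator and/or its
known-slope benchmark to each replication and reports RMSE and relative
bias with delta-method Monte-Carlo standard errors. ML failures and extreme
values are included as computed — censoring them would hide exactly the
instability the comparison is about (a `winsor` cap exists for diagnostics
and defaults to off). Relative bias at $\beta_b = 0$ is reported as
undefined, not infinite. `summarize_by_design()` averages over the
non-$(n, J)$ factors and flags per-cell winners by RMSE and by absolute
relative bias.

The test suite runs scaled-down versions of these studies: 1000
replications per cell for the headline small-sample comparison (six cells
at $n = 5$, $ICC_X \in \{0.05, 0.1\}$, $J \in \{5, 10, 20\}$), 5000 for the
analytic-versus-empirical MSE check at $(J = 10, n = 5, ICC_X = 0.1)$, 2000
for the large-sample bias check at $(J = 200, n = 30, ICC_X = 0.5)$, and
120 replications per cell for a 16-cell design-average table. These sizes
were chosen so Monte-Carlo error is small relative to the effects under
test while the whole suite stays fast on one CPU.

## Known limitations

* The analytic moments assume numerator–denominator independence; they are
  reliable for prior selection and qualitative SE statements, not as
  calibrated frequentist variances at large samples.
* The practical (ML plug-in) estimator remains measurably — though
  modestly — worse than the known-slope benchmark in the hardest
  small-sample cells: plugging an occasionally extreme ML estimate into the
  bias term of the criterion costs on the order of 0.01–0.07 RMSE at
  $n = 5$, $ICC_X \le 0.1$. The benchmark variant is simulation-only by
  construction.
* At large $n \times ICC_X$ the deliberate shrinkage bias can exceed ML's
  variance advantage at the level of individual scenarios; the estimator's
  advantage is concentrated where ML is unstable.
* Balancing by deletion discards data; with strongly unbalanced designs the
  20% threshold stops the analysis rather than risk unrepresentative
  trimming.
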