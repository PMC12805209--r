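test_that("the weighting parameter behaves as specified", {
  expect_equal(lambda_weight(0, 10), 1)           # ML special case
  expect_lt(1 - lambda_weight(1, 1e6), 1e-4)      # large-J limit
  eps <- seq(0, 20, by = 0.5)
  lam <- lambda_weight(eps, 10)
  expect_true(all(diff(lam) < 0))                 # monotone decreasing
  expect_true(all(lam > 0 & lam <= 1))
  expect_error(lambda_weight(-1, 10), "nonnegative")
  # formula transcription oracle at mid-range eps
  expect_equal(lambda_weight(3, 10), 9 / (9 + 6))
  # round trip through the inverse
  expect_equal(lambda_weight(lcmshrink:::eps_from_lambda(0.37, 10), 10), 0.37)
})

test_that("the shrinkage estimate matches its closed form and limits", {
  set.seed(21)
  for (k in 1:10) {
    d <- oracle_draw(5, 5, 0.3, 0.2, 0.5, 0.5)
    s <- sufficient_stats(d)
    # ML special case: identical to the ML estimate
    expect_identical(bayes_estimate(s, prior_params(0, 0.7, 5)),
                     ml_estimate(s))
    # transcription oracle at a mid prior
    pr <- prior_params(2, 0.3, 5)
    expect_equal(bayes_estimate(s, pr),
                 pr$lam * s$s_bxy / (pr$lam * s$s_bx + (1 - pr$lam) * 0.3),
                 tolerance = 1e-14)
  }
  # full shrinkage: the estimate goes to the prior-implied slope 0
  d <- oracle_draw(10, 5, 0.5, 0.2, 0.5, 0.5)
  s <- sufficient_stats(d)
  pr_full <- prior_params(1e8, 0.3, 10)
  expect_lt(abs(bayes_estimate(s, pr_full)), 1e-5)
  # invalid prior/variance combination is rejected
  s_neg <- s; s_neg$s_bx <- -1
  expect_error(bayes_estimate(s_neg, prior_params(0.5, 0.001, 10)),
               "invalid prior")
})

test_that("estimated MSE agrees with an independent evaluation and is nonnegative", {
  set.seed(31)
  d <- oracle_draw(12, 6, 0.3, 0.2, 0.5, 0.5)
  st <- sufficient_stats(d)
  bp <- ml_estimate(st)
  # independent route: integration-based inverse moments on an
  # independently assembled plug-in surface
  oracle_mse <- function(lam, om, bp) {
    J <- st$J; n <- st$n
    bw <- st$swxy / st$swx
    s2bx <- max(st$s_bx, 0)
    s2eb <- max(st$s_by - bp^2 * s2bx, 0)
    s2ew <- max(st$swy - bw^2 * st$swx, 0)
    s2wy <- bw^2 * st$swx + s2ew
    vN <- ((bp * s2bx + bw * st$swx / n)^2 +
           (s2bx + st$swx / n) * (bp^2 * s2bx + s2eb + s2wy / n)) / (J - 1) +
          ((bw * st$swx)^2 + st$swx * s2wy) / (J * (n - 1) * n^2)
    sig2 <- max(st$s_bxy^2 - vN, 0)
    M2 <- sig2 + vN
    C1 <- bp * sig2 / st$s_bxy
    mD <- lam * st$s_bx + (1 - lam) * om
    kD <- (J - 1) / 2 * (mD / (lam * st$s_bx))^2
    if (!(mD > 0 && kD > 2)) return(Inf)
    im <- oracle_inverse_moments(kD, mD)
    lam^2 * M2 * im$i2 - 2 * lam * C1 * im$i1 + bp^2
  }
  for (lam in c(1, 0.7, 0.3)) for (om in c(0, 0.1, 0.4)) {
    pr <- prior_params(lcmshrink:::eps_from_lambda(lam, st$J), om, st$J)
    for (bval in c(bp, 0.5)) {   # empirical-Bayes and known-slope plug-ins
      got <- estimated_mse(pr, st, bval)
      want <- oracle_mse(lam, om, bval)
      if (is.finite(want)) expect_equal(got, want, tolerance = 1e-7)
      else expect_identical(got, Inf)
      if (is.finite(got)) expect_gte(got, 0)
    }
  }
  # ML special case equals the ML estimated MSE under the same plug-ins
  pr0 <- prior_params(0, 0.2, st$J)
  expect_equal(estimated_mse(pr0, st, bp),
               estimated_mse(prior_params(0, 0.9, st$J), st, bp))
})

test_that("grid search returns the exhaustive argmin with the stated tie-break", {
  set.seed(41)
  for (k in 1:8) {
    d <- oracle_draw(sample(6:15, 1), 5, 0.2, 0.2, 0.5, 0.5)
    st <- sufficient_stats(d)
    bp <- ml_estimate(st)
    res <- grid_search_prior(st, bp, grid_n = 30)
    # independent exhaustive double loop over the identical grid
    lam_grid <- seq(1, 0.01, length.out = 30)
    om_grid <- seq(0, res$d, length.out = 30)
    best <- Inf; best_lam <- NA; best_om <- NA
    for (lam in lam_grid) for (om in om_grid) {
      v <- estimated_mse(prior_params(lcmshrink:::eps_from_lambda(lam, st$J),
                                      om, st$J), st, bp)
      if (is.finite(v) && v < best) { best <- v; best_lam <- lam; best_om <- om }
    }
    expect_equal(res$mse_opt, best, tolerance = 1e-12)
    expect_equal(res$prior$lam, best_lam, tolerance = 1e-12)
    expect_equal(res$prior$omega, best_om, tolerance = 1e-12)
    # dominance: never worse than the ML point
    expect_lte(res$mse_opt, res$mse_ml)
  }
})

test_that("degenerate grids and determinism behave", {
  set.seed(51)
  d <- oracle_draw(10, 5, 0.3, 0.2, 0.5, 0.5)
  st <- sufficient_stats(d)
  bp <- ml_estimate(st)
  # single-point grid contains only the ML special case
  res1 <- grid_search_prior(st, bp, grid_n = 1)
  expect_equal(res1$prior$lam, 1)
  expect_equal(res1$prior$eps, 0)
  # rerun reproduces the full result bit-identically
  a <- grid_search_prior(st, bp, grid_n = 40)
  b <- grid_search_prior(st, bp, grid_n = 40)
  expect_identical(a, b)
})

test_that("the full pipeline converges to ML at large J and flags degeneracies", {
  d <- generate_dataset(scenario_spec(icc_x = 0.5, J = 500, n = 30, seed = 61), 1)
  fit <- regularized_bayes(d)
  expect_lt(abs(fit$beta_hat - fit$beta_ml), 0.01)
  # zero between-group covariance triggers simpler-model advice
  dz <- grouped_data(rep(c(-1, 0, 1), each = 2), rep(0, 6), rep(1:3, each = 2))
  fz <- regularized_bayes(dz)
  expect_true(any(grepl("covariance is zero", fz$advice)))
  # deterministic given data and options
  d2 <- generate_dataset(scenario_spec(icc_x = 0.1, J = 10, n = 5, seed = 62), 1)
  expect_identical(regularized_bayes(d2)[-which(names(regularized_bayes(d2)) == "stats")],
                   regularized_bayes(d2)[-which(names(regularized_bayes(d2)) == "stats")])
})

test_that("delete-d jackknife matches closed forms and enumeration", {
  set.seed(71)
  # linear statistic, d = 1: the jackknife SE of a mean of group means
  d <- oracle_draw(12, 4, 0.3, 0.2, 0.5, 0.5)
  gm_mean <- function(dat) mean(tapply(dat$x, dat$group, mean))
  se <- jackknife_se(d, 1, gm_mean)
  gm <- tapply(d$x, d$group, mean)
  expect_equal(se, sd(gm) / sqrt(length(gm)), tolerance = 1e-12)
  # zero-variance data give SE 0
  dz <- grouped_data(rep(1, 12), rep(2, 12), rep(1:4, each = 3))
  expect_equal(jackknife_se(dz, 1, gm_mean), 0)
  # delete-2 on J = 8: equals brute-force enumeration over all 28 subsets
  d8 <- oracle_draw(8, 5, 0.3, 0.2, 0.5, 0.5)
  est_fun <- function(dat) ml_estimate(sufficient_stats(dat))
  se2 <- jackknife_se(d8, 2, est_fun)
  vals <- apply(combn(8, 2), 2, function(drop) {
    keep <- !(d8$group %in% drop)
    est_fun(grouped_data(d8$x[keep], d8$y[keep], d8$group[keep]))
  })
  expect_equal(se2, sqrt((8 - 2) / (2 * 28) * sum((vals - mean(vals))^2)),
               tolerance = 1e-12)
  expect_error(jackknife_se(d8, 7, est_fun), "retained")
})
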