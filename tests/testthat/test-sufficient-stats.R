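test_that("zero within-group variation reduces to the variance of group means", {
  # both members of each group identical: within variance is exactly zero
  xm <- c(-1, 0, 1)
  ym <- 0.5 * xm
  d <- grouped_data(rep(xm, each = 2), rep(ym, each = 2), rep(1:3, each = 2))
  s <- sufficient_stats(d)
  expect_equal(s$swx, 0)
  expect_equal(s$s_bx, var(xm))
  expect_equal(ml_estimate(s), 0.5)
})

test_that("degenerate inputs are signalled", {
  d <- grouped_data(rnorm(7), rnorm(7), rep(1:2, c(3, 4)))
  expect_error(sufficient_stats(d), "balance required")
  d1 <- grouped_data(rnorm(3), rnorm(3), 1:3)
  expect_error(sufficient_stats(d1), "degenerate group")
  # constant predictor: no between-group signal
  dc <- grouped_data(rep(1, 8), rnorm(8), rep(1:4, each = 2))
  sc <- sufficient_stats(dc)
  expect_true(sc$s_bx <= 0)
  expect_equal(sc$s_bxy, 0)
  expect_error(ml_estimate(sc), "degenerate")
  # zero between covariance with positive between variance gives estimate 0
  s0 <- sufficient_stats(grouped_data(rep(c(-1, 0, 1), each = 2),
                                      rep(0, 6), rep(1:3, each = 2)))
  expect_equal(ml_estimate(s0), 0)
})

test_that("estimators agree with an independent ANOVA-route computation", {
  set.seed(42)
  for (k in 1:5) {
    d <- oracle_draw(J = 5, n = 5, icc_x = 0.3, icc_y = 0.2, bb = 0.5, bw = 0.5)
    s <- sufficient_stats(d)
    o <- oracle_stats(d$x, d$y, d$group)
    expect_equal(s$swx, o$s_wx, tolerance = 1e-12)
    expect_equal(s$s_bx, o$s_bx, tolerance = 1e-12)
    expect_equal(s$swxy, o$s_wxy, tolerance = 1e-12)
    expect_equal(s$s_bxy, o$s_bxy, tolerance = 1e-12)
    expect_equal(ml_estimate(s), o$s_bxy / o$s_bx, tolerance = 1e-12)
  }
})

test_that("estimators are invariant to permutations and equivariant to scale", {
  set.seed(7)
  d <- oracle_draw(10, 4, 0.3, 0.2, 0.5, 0.5)
  s <- sufficient_stats(d)
  perm <- sample(length(d$x))
  s2 <- sufficient_stats(grouped_data(d$x[perm], d$y[perm], d$group[perm]))
  expect_equal(s2$s_bx, s$s_bx)
  expect_equal(s2$s_bxy, s$s_bxy)
  expect_equal(s2$swx, s$swx)
  # y -> c*y multiplies the slope by c; x -> c*x divides it by c
  b <- ml_estimate(s)
  expect_equal(ml_estimate(sufficient_stats(
    grouped_data(d$x, 3 * d$y, d$group))), 3 * b)
  expect_equal(ml_estimate(sufficient_stats(
    grouped_data(2 * d$x, d$y, d$group))), b / 2)
})

test_that("the between-group variance estimator is unbiased", {
  # vectorized Monte Carlo at J = 30, n = 15: the mean of s_bx over
  # replications must match sigma2_bx within 3 MC standard errors,
  # pinning the J-1 / J(n-1) denominator convention
  J <- 30; n <- 15; s2bx <- 0.1; s2wx <- 0.9; reps <- 10000
  set.seed(101)
  U <- matrix(rnorm(J * reps, 0, sqrt(s2bx)), J, reps)
  sbx <- numeric(reps)
  for (r in seq_len(reps)) {
    R <- matrix(rnorm(J * n, 0, sqrt(s2wx)), J, n)
    xb <- U[, r] + rowMeans(R)
    swx <- sum((R - rowMeans(R))^2) / (J * (n - 1))
    sbx[r] <- sum((xb - mean(xb))^2) / (J - 1) - swx / n
  }
  mcse <- sd(sbx) / sqrt(reps)
  expect_lt(abs(mean(sbx) - s2bx), 3 * mcse)
})

test_that("small between-variance generation recovers the target on average", {
  # many small groups, tiny latent variance: mean of s_bx across one large
  # draw approximates sigma2_bx
  spec <- scenario_spec(icc_x = 0.05, J = 400, n = 5, seed = 5)
  vals <- vapply(1:25, function(r) sufficient_stats(generate_dataset(spec, r))$s_bx,
                 numeric(1))
  expect_lt(abs(mean(vals) - 0.05), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("the ML estimator is consistent at large samples", {
  spec <- scenario_spec(icc_x = 0.5, J = 1000, n = 30, seed = 31)
  est <- vapply(1:10, function(r) ml_estimate(sufficient_stats(generate_dataset(spec, r))),
                numeric(1))
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(length(est)) + 0.005)
})
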