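# Independent oracle implementations used across tests.

# ANOVA-route sufficient statistics computed through anova(lm(.)) mean
# squares and the polarization identity for covariances -- a code path
# independent of sufficient_stats().
oracle_stats <- function(x, y, g) {
  g <- factor(g)
  J <- nlevels(g); n <- length(x) / J
  ms <- function(v) {
    a <- anova(lm(v ~ g))
    c(msb = a$`Mean Sq`[1], msw = a$`Mean Sq`[2])
  }
  vx <- ms(x); vy <- ms(y); vs <- ms(x + y); vd <- ms(x - y)
  list(
    s_wx = unname(vx["msw"]),
    s_bx = unname((vx["msb"] - vx["msw"]) / n),
    s_wxy = unname((vs["msw"] - vd["msw"]) / 4),
    s_bxy = unname(((vs["msb"] - vs["msw"]) / n - (vd["msb"] - vd["msw"]) / n) / 4))
}

# draw a balanced dataset directly from the model (independent of the
# package's generator)
oracle_draw <- function(J, n, icc_x, icc_y, bb, bw) {
  s2bx <- icc_x; s2wx <- 1 - icc_x
  s2eb <- icc_y - bb^2 * s2bx; s2ew <- (1 - icc_y) - bw^2 * s2wx
  U <- rnorm(J, 0, sqrt(s2bx)); R <- matrix(rnorm(J * n, 0, sqrt(s2wx)), J, n)
  eb <- rnorm(J, 0, sqrt(s2eb)); ew <- matrix(rnorm(J * n, 0, sqrt(s2ew)), J, n)
  X <- U + R; Y <- bb * U + bw * R + eb + ew
  grouped_data(as.vector(t(X)), as.vector(t(Y)), rep(seq_len(J), each = n))
}

# numeric-integration oracle for the inverse gamma moments
oracle_inverse_moments <- function(k, m) {
  th <- m / k
  list(
    i1 = integrate(function(x) dgamma(x, shape = k, scale = th) / x,
                   0, Inf, rel.tol = 1e-10)$value,
    i2 = integrate(function(x) dgamma(x, shape = k, scale = th) / x^2,
                   0, Inf, rel.tol = 1e-10)$value)
}
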