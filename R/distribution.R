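# Closed-form first two moments of the between-group (co)variance estimators.
#
# With balanced data the group means are iid normal with
#   var(xbar_j) = v_x = sigma2_bx + sigma2_wx/n
#   var(ybar_j) = v_y = beta_b^2 sigma2_bx + sigma2_eb + sigma2_wy/n
#   cov         = c_b = beta_b sigma2_bx + beta_w sigma2_wx/n,
# where sigma2_wy = beta_w^2 sigma2_wx + sigma2_ew.  The between mean squares
# are then Wishart-type quadratic forms with J-1 degrees of freedom and the
# pooled within estimators are independent forms with J(n-1) degrees of
# freedom, which gives the exact moments below.

moment_bundle <- function(p) {
  J <- p$J; n <- p$n
  s2wy <- p$beta_w^2 * p$sigma2_wx + p$sigma2_ew
  vx <- p$sigma2_bx + p$sigma2_wx / n
  vy <- p$beta_b^2 * p$sigma2_bx + p$sigma2_eb + s2wy / n
  cb <- p$beta_b * p$sigma2_bx + p$beta_w * p$sigma2_wx / n
  cw <- p$beta_w * p$sigma2_wx
  list(
    vx = vx, vy = vy, cb = cb, cw = cw, s2wy = s2wy,
    mean_sbx  = p$sigma2_bx,
    var_sbx   = 2 * vx^2 / (J - 1) + 2 * p$sigma2_wx^2 / (n^2 * J * (n - 1)),
    mean_sbxy = p$beta_b * p$sigma2_bx,
    var_sbxy  = (cb^2 + vx * vy) / (J - 1) +
                (cw^2 + p$sigma2_wx * s2wy) / (J * (n - 1) * n^2))
}

# Inverse moments of a Gamma(shape = k, scale = th) variable; the shape is
# allowed to be +Inf (degenerate at the mean m = k*th), in which case the
# moments are 1/m and 1/m^2.  Shapes <= order have no finite inverse moment.
gamma_inverse_moments <- function(k, m) {
  big <- !is.finite(k) | k > 1e12
  th <- ifelse(big, NA_real_, m / k)
  i1 <- ifelse(big, 1 / m, ifelse(k > 1, 1 / (th * (k - 1)), NA_real_))
  i2 <- ifelse(big, 1 / m^2,
               ifelse(k > 2, 1 / (th^2 * (k - 1) * (k - 2)), NA_real_))
  list(i1 = i1, i2 = i2)
}

#' Sampling distribution of a between-group slope estimator
#'
#' Derives the approximate sampling distribution of the maximum likelihood
#' or the Bayesian shrinkage estimator of the between-group slope at given
#' model parameters, and from it the analytic mean, variance, mean squared
#' error and standard error.
#'
#' The construction represents the numerator \eqn{\lambda \hat\sigma_{bxy}}
#' by its exact first two moments and the denominator
#' \eqn{\lambda\hat\sigma_{bx} + (1-\lambda)\omega} by a gamma variable in
#' the chi-square(J-1) shape family: shape
#' \eqn{k_D = \frac{J-1}{2}\,(m_D/(\lambda\sigma^2_{bx}))^2} with the exact
#' mean \eqn{m_D}. Treating numerator and denominator as independent gammas
#' makes the ratio a scaled F variable; its moments give
#' \deqn{E[\hat\beta] = \lambda\,\beta_b\sigma^2_{bx}\,E[1/D], \qquad
#'       E[\hat\beta^2] = \lambda^2\,(\beta_b^2\sigma^4_{bx} +
#'       \mathrm{var}(\hat\sigma_{bxy}))\,E[1/D^2],}
#' and \eqn{MSE = E[\hat\beta^2] - 2\beta_b E[\hat\beta] + \beta_b^2}
#' (variance plus squared bias). The variance of the F form exists only when
#' \eqn{k_D > 2}; otherwise an error of class
#' `lcmshrink_undefined_moment` is signalled, reporting the offending
#' degrees of freedom. At the ML special case (`eps = 0`, so `lambda = 1`)
#' the Bayes distribution is identical to the ML distribution.
#'
#' @param kind `"ML"` or `"Bayes"`.
#' @param params an [lcm_params()] object.
#' @param prior a [prior_params()] object (required for `kind = "Bayes"`,
#'   ignored for `"ML"`).
#' @return An object of class `estimator_dist` with fields `kind`,
#'   `c_coeffs` (scale and matched numerator/denominator gamma parameters of
#'   the F form), `df1`, `df2`, `mean`, `variance`, `mse`, `se`.
#' @export
estimator_distribution <- function(kind = c("ML", "Bayes"), params,
                                   prior = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "lcm_params"))
  if (kind == "Bayes") {
    if (is.null(prior)) stop("a prior_params object is required for kind = 'Bayes'")
    stopifnot(inherits(prior, "prior_params"))
    lam <- prior$lam; omega <- prior$omega
  } else {
    lam <- 1; omega <- 0
  }
  mom <- moment_bundle(params)
  J <- params$J
  k0 <- (J - 1) / 2
  mD <- lam * mom$mean_sbx + (1 - lam) * omega
  if (!is.finite(mD) || mD <= 0)
    stop("denominator mean is not positive; the derived distribution is degenerate")
  kD <- if (lam * mom$mean_sbx > 0) k0 * (mD / (lam * mom$mean_sbx))^2 else Inf
  inv <- gamma_inverse_moments(kD, mD)
  if (is.na(inv$i2)) {
    cond <- structure(
      class = c("lcmshrink_undefined_moment", "error", "condition"),
      list(message = sprintf(
        "variance of the F form does not exist: denominator df2 = %.3g <= 4",
        2 * kD), call = sys.call(-1)))
    stop(cond)
  }
  mN <- lam * mom$mean_sbxy
  vN <- lam^2 * mom$var_sbxy
  m1 <- mN * inv$i1
  m2 <- (mN^2 + vN) * inv$i2
  vr <- m2 - m1^2
  mse <- m2 - 2 * params$beta_b * m1 + params$beta_b^2
  kN <- if (vN > 0 && mN != 0) mN^2 / vN else NA_real_
  scl <- if (!is.na(kN) && kN > 0) (abs(mN) / mD) * sign(mN) else NA_real_
  structure(
    list(kind = kind,
         c_coeffs = c(scale = scl, k_num = kN, theta_num = if (!is.na(kN)) vN / abs(mN) else NA_real_,
                      k_den = kD, theta_den = mD / kD, shift = 0),
         df1 = 2 * kN, df2 = 2 * kD,
         mean = m1, variance = vr, mse = mse, se = sqrt(vr),
         lam = lam, omega = omega, beta_b = params$beta_b),
    class = "estimator_dist")
}

#' @export
print.estimator_dist <- function(x, ...) {
  cat(sprintf(
    "%s estimator distribution: mean %.4g, SE %.4g, MSE %.4g (df1 = %.3g, df2 = %.3g)\n",
    x$kind, x$mean, x$se, x$mse, x$df1, x$df2))
  invisible(x)
}

#' Analytic standard error of an estimator distribution
#'
#' Square root of the variance of the derived sampling distribution.
#'
#' @param dist an [estimator_distribution()] object.
#' @return The standard error.
#' @export
analytic_se <- function(dist) {
  stopifnot(inherits(dist, "estimator_dist"))
  sqrt(dist$variance)
}
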