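#' Sufficient statistics of the two-level latent covariate model
#'
#' Computes the group means and the ANOVA-type (co)variance estimators that
#' every slope estimator in the package is built from. The within-group
#' (co)variances use the pooled unbiased convention (sums of squares divided
#' by J(n-1)); the between mean squares of the group means use J-1. The
#' latent between-group (co)variance estimators subtract the within
#' contribution of the group means,
#' \deqn{\hat\sigma_{bx} = MS_b(x) - \hat\sigma_{wx}/n,}
#' which makes them unbiased for the latent components under the model. The
#' between estimate can therefore be negative in small samples; it is not
#' truncated here.
#'
#' @param data a balanced [grouped_data()] object with J >= 2 groups of
#'   n >= 2 individuals each.
#' @return An object of class `lcm_stats`: group means `xbar_j`, `ybar_j`;
#'   between mean squares `mbx`, `mby`, `mbxy`; pooled within estimators
#'   `swx`, `swy`, `swxy`; latent between estimators `s_bx`, `s_by`,
#'   `s_bxy`; and `J`, `n`.
#' @examples
#' d <- generate_dataset(scenario_spec(icc_x = 0.3, J = 20, n = 10), 1)
#' s <- sufficient_stats(d)
#' c(s$s_bx, s$s_bxy)
#' @export
sufficient_stats <- function(data) {
  stopifnot(inherits(data, "grouped_data"))
  if (!data$balanced)
    stop("balance required: groups have unequal sizes; see balance_data()")
  if (data$J < 2L) stop("at least two groups are required")
  if (data$n < 2L) stop("degenerate group: every group needs >= 2 members")
  J <- data$J; n <- data$n
  xbar <- as.numeric(tapply(data$x, data$group, mean))
  ybar <- as.numeric(tapply(data$y, data$group, mean))
  xc <- data$x - xbar[data$group]
  yc <- data$y - ybar[data$group]
  dfw <- J * (n - 1)
  swx  <- sum(xc * xc) / dfw
  swy  <- sum(yc * yc) / dfw
  swxy <- sum(xc * yc) / dfw
  mbx  <- sum((xbar - mean(xbar))^2) / (J - 1)
  mby  <- sum((ybar - mean(ybar))^2) / (J - 1)
  mbxy <- sum((xbar - mean(xbar)) * (ybar - mean(ybar))) / (J - 1)
  structure(
    list(xbar_j = xbar, ybar_j = ybar,
         mbx = mbx, mby = mby, mbxy = mbxy,
         swx = swx, swy = swy, swxy = swxy,
         s_bx = mbx - swx / n, s_by = mby - swy / n, s_bxy = mbxy - swxy / n,
         J = J, n = n),
    class = "lcm_stats")
}

#' @export
print.lcm_stats <- function(x, ...) {
  cat(sprintf("Sufficient statistics (J = %d, n = %d)\n", x$J, x$n))
  cat(sprintf("  between:  s_bx = %.4g  s_bxy = %.4g  s_by = %.4g\n",
              x$s_bx, x$s_bxy, x$s_by))
  cat(sprintf("  within:   s_wx = %.4g  s_wxy = %.4g  s_wy = %.4g\n",
              x$swx, x$swxy, x$swy))
  invisible(x)
}

#' Maximum likelihood estimate of the between-group slope
#'
#' The ratio of the latent between-group covariance and variance estimators,
#' \deqn{\hat\beta_b^{ML} = \hat\sigma_{bxy} / \hat\sigma_{bx}.}
#' No regularization is applied: when the between-group variance estimate is
#' near zero the ratio inflates, which is the documented small-sample
#' instability of this estimator. An exactly zero denominator is an error.
#'
#' @param stats an [sufficient_stats()] object.
#' @return The slope estimate (numeric scalar).
#' @export
ml_estimate <- function(stats) {
  stopifnot(inherits(stats, "lcm_stats"))
  if (stats$s_bx == 0)
    stop("degenerate between-group variance: s_bx is exactly zero")
  stats$s_bxy / stats$s_bx
}

#' Pooled within-group slope estimate
#'
#' Ratio of pooled within-group covariance and variance; a by-product used
#' as a plug-in for the within-group slope.
#'
#' @param stats an [sufficient_stats()] object.
#' @return The within-group slope estimate.
#' @export
within_estimate <- function(stats) {
  stopifnot(inherits(stats, "lcm_stats"))
  if (stats$swx == 0)
    stop("degenerate within-group variance: s_wx is zero")
  stats$swxy / stats$swx
}
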