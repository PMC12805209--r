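#' Bayesian shrinkage estimate of the between-group slope
#'
#' The Stein-type estimator
#' \deqn{\hat\beta_b^{B} = \frac{\lambda\,\hat\sigma_{bxy}}
#'   {\lambda\,\hat\sigma_{bx} + (1-\lambda)\,\omega},}
#' whose denominator mixes the observed between-group variance with the
#' prior location `omega`, bounding it away from zero. At `eps = 0`
#' (`lambda = 1`) it equals the ML estimate exactly; as `lambda` tends to 0
#' with `omega > 0` it shrinks fully toward the prior-implied slope 0.
#'
#' @param stats an [sufficient_stats()] object.
#' @param prior a [prior_params()] object.
#' @return The shrinkage estimate.
#' @export
bayes_estimate <- function(stats, prior) {
  stopifnot(inherits(stats, "lcm_stats"), inherits(prior, "prior_params"))
  den <- prior$lam * stats$s_bx + (1 - prior$lam) * prior$omega
  if (den == 0)
    stop("invalid prior/variance combination: weighted denominator is zero")
  # with no prior mass (lam = 1 or omega = 0) the ratio is the raw ML-type
  # estimator, which is allowed to carry a negative denominator; a genuine
  # prior mixture must stay positive
  if (den < 0 && prior$lam < 1 && prior$omega > 0)
    stop("invalid prior/variance combination: weighted denominator <= 0")
  prior$lam * stats$s_bxy / den
}

# Assemble plug-in model quantities from sufficient statistics.
#
# Model parameters are replaced by their sample estimates: sigma2_bx by
# max(s_bx, 0), the within slope by the pooled ratio, residual variances by
# their nonnegativity-truncated estimates.  For the grid-search criterion two
# signal summaries are produced:
#   M2: plug-in of E[s_bxy]^2 + var(s_bxy)
#   C1: plug-in of beta_b * E[s_bxy] = beta_b^2 sigma2_bx
# The between-group signal E[s_bxy] = beta_b sigma2_bx is estimated by the
# noise-corrected (James-Stein type) shrinkage of the observed covariance,
#   E_hat = s_bxy * max(s_bxy^2 - var_hat(s_bxy), 0) / s_bxy^2,
# so that pure noise in s_bxy is not mistaken for signal, and its square by
# sig2 = max(s_bxy^2 - var_hat, 0).  The slope value beta enters the same
# formula in both variants: the empirical-Bayes variant evaluates it at the
# ML estimate, the simulation-only benchmark variant at the known true
# value; only the value passed in differs, never the formula.
plugin_bundle <- function(stats, beta_plugin) {
  J <- stats$J; n <- stats$n
  bp <- beta_plugin
  bw <- if (stats$swx > 0) stats$swxy / stats$swx else 0
  s2bx <- max(stats$s_bx, 0)
  s2eb <- max(stats$s_by - bp^2 * s2bx, 0)
  s2ew <- max(stats$swy - bw^2 * stats$swx, 0)
  s2wy <- bw^2 * stats$swx + s2ew
  vx <- s2bx + stats$swx / n
  vy <- bp^2 * s2bx + s2eb + s2wy / n
  cb <- bp * s2bx + bw * stats$swx / n
  cw <- bw * stats$swx
  vN <- (cb^2 + vx * vy) / (J - 1) +
        (cw^2 + stats$swx * s2wy) / (J * (n - 1) * n^2)
  sig2 <- max(stats$s_bxy^2 - vN, 0)
  EN1 <- if (stats$s_bxy != 0) stats$s_bxy * sig2 / stats$s_bxy^2 else 0
  M2 <- sig2 + vN
  C1 <- bp * EN1
  list(bp = bp, vN = vN, M2 = M2, C1 = C1, s2bx = s2bx,
       sd_sbx_gamma = s2bx * sqrt(2 / (J - 1)),
       sd_sbx_moment = sqrt(2 * stats$mbx^2 / (J - 1) +
                            2 * stats$swx^2 / (n^2 * J * (n - 1))))
}

# Vectorized estimated-MSE kernel over grid points (lam, om).
# Returns Inf at points where the F-form variance does not exist
# (denominator shape <= 2) or the denominator mean is not positive.
mse_kernel <- function(lam, om, stats, pb) {
  J <- stats$J
  k0 <- (J - 1) / 2
  sbx <- stats$s_bx
  mD <- lam * sbx + (1 - lam) * om
  base <- lam * sbx
  kD <- ifelse(base > 0, k0 * (mD / base)^2, Inf)
  ok <- is.finite(mD) & mD > 0 & kD > 2
  inv <- gamma_inverse_moments(ifelse(ok, kD, 3), ifelse(ok, mD, 1))
  mse <- lam^2 * pb$M2 * inv$i2 - 2 * lam * pb$C1 * inv$i1 + pb$bp^2
  mse[!ok] <- Inf
  mse
}

#' Estimated mean squared error of the shrinkage estimator
#'
#' Evaluates the analytic MSE of the Bayesian estimator at a prior, with
#' model parameters replaced by their sample estimates and the between-group
#' slope by `beta_plugin` (normally the ML estimate; a known true value may
#' be supplied for the simulation-only benchmark variant; the formula is
#' the same, only the value differs). At the ML special case (`eps = 0`) this equals the
#' estimated MSE of the ML estimator under the same plug-ins.
#'
#' @param prior a [prior_params()] object.
#' @param stats an [sufficient_stats()] object.
#' @param beta_plugin finite slope plug-in.
#' @return The estimated MSE; `Inf` when the required F moment does not
#'   exist at this prior (such grid points are excluded by the search).
#' @export
estimated_mse <- function(prior, stats, beta_plugin) {
  stopifnot(inherits(prior, "prior_params"), inherits(stats, "lcm_stats"))
  if (!is.finite(beta_plugin)) stop("beta_plugin must be finite")
  pb <- plugin_bundle(stats, beta_plugin)
  mse_kernel(prior$lam, prior$omega, stats, pb)
}

#' MSE-minimizing grid search over the prior parameters
#'
#' Searches a rectangular grid over the weighting parameter `lambda`
#' (equivalently `eps`) and the prior variance location `omega` for the
#' point minimizing [estimated_mse()]. The `omega` region is `[0, d]` with
#' `d` five times the standard deviation of the between-group variance
#' estimator (taken from its derived gamma distribution, with a
#' moment-based value as a floor). The ML special case (`lambda = 1`) lies
#' in the grid, so the minimized estimated MSE never exceeds the ML value;
#' ties are broken toward the least-shrinkage (ML-closest) point. Grid
#' points with undefined F moments are excluded; if every point is excluded
#' the search falls back to ML with a warning.
#'
#' @param stats an [sufficient_stats()] object.
#' @param beta_plugin slope plug-in (normally the ML estimate).
#' @param grid_n grid resolution per dimension (default 100).
#' @param lambda_min smallest `lambda` in the grid (default 0.01).
#' @return A list with `prior` (the selected [prior_params()]), `mse_opt`,
#'   `mse_ml` (estimated MSE at the ML point, possibly `Inf`),
#'   `boundary_hit` (optimum on the search-region edge), `d` (omega bound),
#'   `grid_n`, and `n_excluded`.
#' @export
grid_search_prior <- function(stats, beta_plugin, grid_n = 100,
                              lambda_min = 0.01) {
  stopifnot(inherits(stats, "lcm_stats"))
  pb <- plugin_bundle(stats, beta_plugin)
  d <- 5 * max(pb$sd_sbx_gamma, pb$sd_sbx_moment)
  lam_grid <- seq(1, lambda_min, length.out = grid_n)
  om_grid <- seq(0, d, length.out = grid_n)
  # lambda decreasing, omega increasing: the first argmin is ML-closest
  lam <- rep(lam_grid, each = grid_n)
  om <- rep(om_grid, times = grid_n)
  mse <- mse_kernel(lam, om, stats, pb)
  mse_ml <- mse_kernel(1, 0, stats, pb)
  if (!any(is.finite(mse))) {
    warning("all grid points excluded (undefined moments); falling back to ML")
    return(list(prior = prior_params(0, 0, stats$J), mse_opt = Inf,
                mse_ml = mse_ml, boundary_hit = FALSE, d = d,
                grid_n = grid_n, n_excluded = length(mse), fallback = TRUE))
  }
  i <- which.min(mse)
  list(prior = prior_params(eps_from_lambda(lam[i], stats$J), om[i], stats$J),
       mse_opt = mse[i], mse_ml = mse_ml,
       boundary_hit = lam[i] == lambda_min || om[i] == d,
       d = d, grid_n = grid_n, n_excluded = sum(!is.finite(mse)),
       fallback = FALSE)
}

#' Regularized Bayesian estimation of the between-group slope
#'
#' The full pipeline: sufficient statistics, ML estimate, MSE-minimizing
#' grid search over the gamma-prior parameters with the ML estimate plugged
#' in for the unknown slope, shrinkage estimate at the selected prior, and a
#' standard error (analytic from the derived distribution, or delete-d
#' jackknife). Deterministic given the data and options.
#'
#' @param data a balanced [grouped_data()] object.
#' @param grid_n grid resolution per prior dimension.
#' @param se_method `"analytic"` or `"jackknife"`.
#' @param jackknife_d groups deleted per jackknife subset (default
#'   `max(1, floor(sqrt(J)))`).
#' @param seed seed for jackknife subset sampling.
#' @param benchmark_beta optional known true slope, plugged into the MSE
#'   optimization in place of the ML estimate (simulation-only benchmark).
#' @return An object of class `reglcm` with the ML and regularized-Bayes
#'   estimates, standard errors, selected prior, estimated MSE at the
#'   optimum, diagnostics and any degenerate-case advice.
#' @examples
#' d <- generate_dataset(scenario_spec(icc_x = 0.3, J = 20, n = 10), 1)
#' fit <- regularized_bayes(d)
#' fit
#' @export
regularized_bayes <- function(data, grid_n = 100,
                              se_method = c("analytic", "jackknife"),
                              jackknife_d = NULL, seed = 1L,
                              benchmark_beta = NULL) {
  se_method <- match.arg(se_method)
  stats <- sufficient_stats(data)
  fit <- rb_core(stats, grid_n = grid_n, benchmark_beta = benchmark_beta)
  advice <- character(0)
  if (stats$s_bx <= 0)
    advice <- c(advice,
      "between-group variance estimate is not positive; consider a simpler (single-level) model")
  if (stats$s_bxy == 0)
    advice <- c(advice,
      "between-group covariance is zero: no between-group effect signal; consider OLS/ML on the pooled data")
  if (abs(stats$swxy) < .Machine$double.eps * max(1, stats$swx))
    advice <- c(advice,
      "within-group covariance is zero: no within-group effect signal")
  ml_se <- tryCatch(
    analytic_se(estimator_distribution("ML", plugin_params(stats, fit$beta_ml))),
    error = function(e) NA_real_)
  if (se_method == "analytic") {
    rb_se <- tryCatch(
      analytic_se(estimator_distribution("Bayes",
                                         plugin_params(stats, fit$beta_ml),
                                         fit$prior)),
      error = function(e) NA_real_)
    se_label <- "analytic"
  } else {
    dd <- if (is.null(jackknife_d)) max(1L, floor(sqrt(stats$J))) else jackknife_d
    rb_se <- jackknife_se(data, d_groups = dd, estimator = function(dat)
      rb_core(sufficient_stats(dat), grid_n = grid_n,
              benchmark_beta = benchmark_beta)$beta_rb, seed = seed)
    se_label <- sprintf("jackknife (d = %d)", dd)
  }
  structure(
    list(method = "RegularizedBayes",
         beta_hat = fit$beta_rb, se = rb_se, se_label = se_label,
         beta_ml = fit$beta_ml, ml_se = ml_se,
         prior_star = fit$prior, mse_hat_at_opt = fit$search$mse_opt,
         mse_hat_ml = fit$search$mse_ml,
         diagnostics = fit$search[c("grid_n", "d", "boundary_hit",
                                    "n_excluded", "fallback")],
         advice = advice, stats = stats,
         benchmark = !is.null(benchmark_beta)),
    class = "reglcm")
}

# fast path shared by regularized_bayes() and the simulation engine
rb_core <- function(stats, grid_n = 100, benchmark_beta = NULL) {
  beta_ml <- stats$s_bxy / stats$s_bx
  bp <- if (is.null(benchmark_beta)) beta_ml else benchmark_beta
  search <- grid_search_prior(stats, bp, grid_n = grid_n)
  beta_rb <- if (search$fallback) beta_ml
             else bayes_estimate(stats, search$prior)
  list(beta_ml = beta_ml, beta_rb = beta_rb, prior = search$prior,
       search = search)
}

# plug-in lcm_params for the analytic SE of the fitted estimator
plugin_params <- function(stats, beta_plugin) {
  bw <- if (stats$swx > 0) stats$swxy / stats$swx else 0
  lcm_params(beta_b = beta_plugin, beta_w = bw,
             sigma2_bx = max(stats$s_bx, .Machine$double.eps),
             sigma2_wx = stats$swx,
             sigma2_eb = max(stats$s_by - beta_plugin^2 * max(stats$s_bx, 0), 0),
             sigma2_ew = max(stats$swy - bw^2 * stats$swx, 0),
             J = stats$J, n = stats$n)
}

#' Delete-d jackknife standard error over groups
#'
#' Recomputes an estimator on subsets of the data formed by deleting
#' `d_groups` whole groups at a time. All `choose(J, d)` deletion patterns
#' are enumerated when there are at most `max_subsets` of them; otherwise
#' `max_subsets` patterns are drawn at random (seeded). The standard error
#' is \deqn{SE^2 = \frac{J-d}{d\,S} \sum_s (\hat\theta_s - \bar\theta)^2,}
#' the delete-d jackknife variance with S retained subsets.
#'
#' @param data a [grouped_data()] object.
#' @param d_groups number of groups deleted per subset (>= 1, with at least
#'   two groups retained).
#' @param estimator function mapping a `grouped_data` to a numeric scalar.
#' @param seed seed used when subsets are subsampled.
#' @param max_subsets enumeration cap (default 10000).
#' @return The jackknife standard error.
#' @export
jackknife_se <- function(data, d_groups = 1L, estimator, seed = 1L,
                         max_subsets = 10000L) {
  stopifnot(inherits(data, "grouped_data"))
  J <- data$J
  if (d_groups < 1L || J - d_groups < 2L)
    stop("need d_groups >= 1 and at least two retained groups")
  n_all <- choose(J, d_groups)
  if (n_all <= max_subsets) {
    del <- utils::combn(J, d_groups)
  } else {
    del <- with_seed(seed,
      replicate(max_subsets, sort(sample.int(J, d_groups))))
    del <- matrix(del, nrow = d_groups)
  }
  subset_est <- apply(del, 2, function(drop) {
    keep <- !(data$group %in% drop)
    estimator(grouped_data(data$x[keep], data$y[keep],
                           data$labels[data$group[keep]]))
  })
  S <- length(subset_est)
  sqrt((J - d_groups) / (d_groups * S) *
         sum((subset_est - mean(subset_est))^2))
}

#' @export
print.reglcm <- function(x, ...) {
  cat("Regularized Bayesian estimation of the between-group slope\n")
  cat(sprintf("  RB estimate: %10.5f  (SE %s: %.5f)\n",
              x$beta_hat, x$se_label, x$se))
  cat(sprintf("  ML estimate: %10.5f  (SE analytic: %s)\n",
              x$beta_ml, ifelse(is.na(x$ml_se), "undefined", sprintf("%.5f", x$ml_se))))
  cat(sprintf("  selected prior: eps = %.4g, omega = %.4g (lambda = %.4g)\n",
              x$prior_star$eps, x$prior_star$omega, x$prior_star$lam))
  if (length(x$advice))
    cat("  advice:", paste(x$advice, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.reglcm <- function(object, ...) {
  x <- object
  cat("\nCall: regularized Bayesian between-group slope estimation\n\n")
  cat("Coefficients:\n")
  tab <- data.frame(
    Estimate = c(x$beta_hat, x$beta_ml),
    `Std.Error` = c(x$se, x$ml_se),
    row.names = c("beta_b (regularized Bayes)", "beta_b (ML)"),
    check.names = FALSE)
  print(format(tab, digits = 5))
  cat(sprintf("\nSelected prior: eps = %.4g, omega = %.4g, lambda = %.4g\n",
              x$prior_star$eps, x$prior_star$omega, x$prior_star$lam))
  cat(sprintf("Estimated MSE at optimum: %.5g (ML point: %s)\n",
              x$mse_hat_at_opt,
              ifelse(is.finite(x$mse_hat_ml), sprintf("%.5g", x$mse_hat_ml),
                     "undefined")))
  if (length(x$advice)) cat("Advice:", paste(x$advice, collapse = "; "), "\n")
  invisible(x)
}
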