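#' Parameters of the two-level latent covariate model
#'
#' The model decomposes the predictor of individual i in group j as
#' \deqn{X_{ij} = U_j + R_{ij},} with independent normal components
#' \eqn{U_j \sim N(\mu_x, \sigma^2_{bx})} (latent group mean) and
#' \eqn{R_{ij} \sim N(0, \sigma^2_{wx})}, and the outcome as
#' \deqn{Y_{ij} = \beta_0 + \beta_b U_j + \beta_w R_{ij} + e_{bj} + e_{wij},}
#' with normal residuals at both levels. The intraclass correlations are
#' \eqn{ICC_X = \sigma^2_{bx}/(\sigma^2_{bx}+\sigma^2_{wx})} and
#' \eqn{ICC_Y = (\beta_b^2\sigma^2_{bx}+\sigma^2_{eb}) / \mathrm{var}(Y)}.
#'
#' @param beta_b between-group slope.
#' @param beta_w within-group slope.
#' @param sigma2_bx,sigma2_wx between/within variance of the predictor.
#' @param sigma2_eb,sigma2_ew between/within residual variance of the outcome.
#' @param J number of groups (integer >= 2).
#' @param n group size (integer >= 2).
#' @param mu_x grand mean of the predictor (default 0).
#' @param intercept_b overall intercept (default 0).
#' @return An object of class `lcm_params` with the fields above plus the
#'   implied `icc_x` and `icc_y`.
#' @seealso [lcm_params_from_icc()] for the ICC-indexed parameterization.
#' @export
lcm_params <- function(beta_b, beta_w, sigma2_bx, sigma2_wx,
                       sigma2_eb, sigma2_ew, J, n,
                       mu_x = 0, intercept_b = 0) {
  vars <- c(sigma2_bx = sigma2_bx, sigma2_wx = sigma2_wx,
            sigma2_eb = sigma2_eb, sigma2_ew = sigma2_ew)
  if (any(!is.finite(c(beta_b, beta_w, vars, mu_x, intercept_b))))
    stop("non-finite model parameters")
  if (any(vars < 0))
    stop("negative variance: ", paste(names(vars)[vars < 0], collapse = ", "))
  if (J != round(J) || n != round(n) || J < 2 || n < 2)
    stop("J and n must be integers >= 2")
  tx <- sigma2_bx + sigma2_wx
  by <- beta_b^2 * sigma2_bx + sigma2_eb
  wy <- beta_w^2 * sigma2_wx + sigma2_ew
  structure(
    list(beta_b = beta_b, beta_w = beta_w,
         sigma2_bx = sigma2_bx, sigma2_wx = sigma2_wx,
         sigma2_eb = sigma2_eb, sigma2_ew = sigma2_ew,
         J = as.integer(J), n = as.integer(n),
         mu_x = mu_x, intercept_b = intercept_b,
         icc_x = if (tx > 0) sigma2_bx / tx else NA_real_,
         icc_y = if (by + wy > 0) by / (by + wy) else NA_real_),
    class = "lcm_params")
}

#' @export
print.lcm_params <- function(x, ...) {
  cat(sprintf(
    "Latent covariate model: beta_b = %.3g, beta_w = %.3g, ICC_X = %.3g, ICC_Y = %.3g, J = %d, n = %d\n",
    x$beta_b, x$beta_w, x$icc_x, x$icc_y, x$J, x$n))
  invisible(x)
}

#' Residual variances implied by target intraclass correlations
#'
#' Under the unit-total-variance normalization of both variables
#' (\eqn{\sigma^2_{bx} = ICC_X}, \eqn{\sigma^2_{wx} = 1 - ICC_X}, total
#' outcome variance 1) the residual variances are determined by the slopes:
#' \deqn{\sigma^2_{eb} = ICC_Y - \beta_b^2\, ICC_X, \qquad
#'       \sigma^2_{ew} = (1 - ICC_Y) - \beta_w^2 (1 - ICC_X).}
#' A parameter combination is feasible exactly when both are nonnegative.
#'
#' @param icc_x,icc_y target intraclass correlations in [0, 1).
#' @param beta_b,beta_w between- and within-group slopes.
#' @return A list with `sigma2_eb`, `sigma2_ew` (possibly negative when
#'   infeasible) and the predictor variances `sigma2_bx`, `sigma2_wx`.
#' @export
solve_residual_variances <- function(icc_x, icc_y, beta_b, beta_w) {
  stopifnot(icc_x >= 0, icc_x < 1, icc_y >= 0, icc_y < 1)
  list(sigma2_bx = icc_x, sigma2_wx = 1 - icc_x,
       sigma2_eb = icc_y - beta_b^2 * icc_x,
       sigma2_ew = (1 - icc_y) - beta_w^2 * (1 - icc_x))
}

#' Feasibility of an ICC-indexed parameter combination
#'
#' Checks whether nonnegative residual variances exist for the requested
#' intraclass correlations and slopes under the unit-total-variance
#' normalization (see [solve_residual_variances()]). When infeasible, the
#' binding constraint is named.
#'
#' @inheritParams solve_residual_variances
#' @return A list with `feasible` (logical), `binding` (character vector of
#'   violated constraints, empty when feasible) and the solved variances.
#' @examples
#' check_icc_feasibility(0.5, 0.2, beta_b = 0.7, beta_w = 0.5)$feasible
#' @export
check_icc_feasibility <- function(icc_x, icc_y, beta_b, beta_w) {
  s <- solve_residual_variances(icc_x, icc_y, beta_b, beta_w)
  tol <- 1e-12
  binding <- character(0)
  if (s$sigma2_eb < -tol)
    binding <- c(binding, "sigma2_eb >= 0 (beta_b^2 * icc_x <= icc_y)")
  if (s$sigma2_ew < -tol)
    binding <- c(binding, "sigma2_ew >= 0 (beta_w^2 * (1 - icc_x) <= 1 - icc_y)")
  c(list(feasible = length(binding) == 0L, binding = binding), s)
}

#' Model parameters from intraclass correlations
#'
#' Builds an [lcm_params()] object from the ICC-indexed parameterization
#' used throughout the simulation design. Errors if the combination is
#' infeasible, naming the violated nonnegativity constraint.
#'
#' @inheritParams solve_residual_variances
#' @param J,n design counts.
#' @return An `lcm_params` object.
#' @export
lcm_params_from_icc <- function(icc_x, icc_y, beta_b, beta_w, J, n) {
  chk <- check_icc_feasibility(icc_x, icc_y, beta_b, beta_w)
  if (!chk$feasible)
    stop("infeasible ICC/slope combination; violated: ",
         paste(chk$binding, collapse = "; "))
  lcm_params(beta_b, beta_w,
             sigma2_bx = chk$sigma2_bx, sigma2_wx = chk$sigma2_wx,
             sigma2_eb = max(chk$sigma2_eb, 0),
             sigma2_ew = max(chk$sigma2_ew, 0),
             J = J, n = n)
}
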