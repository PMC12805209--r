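#' Weighting parameter of the Bayesian estimator
#'
#' The gamma-prior parameter `eps` acts as prior pseudo-information added to
#' the J - 1 between-group degrees of freedom:
#' \deqn{\lambda(\epsilon, J) = \frac{J-1}{J-1+2\epsilon}.}
#' `eps = 0` gives `lambda = 1`, the maximum likelihood special case;
#' `lambda` decreases monotonically in `eps` and tends to 1 as J grows for
#' fixed `eps`, so the Bayesian estimator converges to ML.
#'
#' @param eps nonnegative gamma-prior shape parameter.
#' @param J number of groups (>= 2).
#' @return The weight `lambda` in (0, 1].
#' @examples
#' lambda_weight(0, 10)     # 1: the ML special case
#' lambda_weight(2, 1e6)    # essentially 1
#' @export
lambda_weight <- function(eps, J) {
  if (any(eps < 0)) stop("eps must be nonnegative")
  if (any(J < 2)) stop("J must be >= 2")
  (J - 1) / ((J - 1) + 2 * eps)
}

#' Gamma-prior parameters of the shrinkage estimator
#'
#' Bundles the two prior parameters: `eps`, which drives the weighting
#' parameter `lambda` (see [lambda_weight()]), and `omega`, the prior
#' location of the between-group variance that enters the denominator of the
#' shrinkage estimator. `eps = 0` is the ML special case regardless of
#' `omega`.
#'
#' @param eps nonnegative prior shape (pseudo-information) parameter.
#' @param omega nonnegative prior location for the between-group variance.
#' @param J number of groups, used to compute `lambda`.
#' @return An object of class `prior_params` with fields `eps`, `omega`,
#'   `lam` and `J`.
#' @export
prior_params <- function(eps, omega, J) {
  if (omega < 0) stop("omega must be nonnegative")
  structure(list(eps = eps, omega = omega, J = as.integer(J),
                 lam = lambda_weight(eps, J)),
            class = "prior_params")
}

#' @export
print.prior_params <- function(x, ...) {
  cat(sprintf("Gamma prior: eps = %.4g, omega = %.4g (lambda = %.4g, J = %d)\n",
              x$eps, x$omega, x$lam, x$J))
  invisible(x)
}

# eps implied by a weight lambda at J groups (inverse of lambda_weight)
eps_from_lambda <- function(lam, J) {
  (J - 1) * (1 - lam) / (2 * lam)
}
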