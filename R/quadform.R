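# Exact quadratic-form representations of the between-group (co)variance
# estimators.  The estimators are quadratic forms in the standardized vector
# z of all independent normal model components:
#   for s_bx : z = (z_U, z_R),              length J + J*n
#   for s_bxy: z = (z_U, z_R, z_eb, z_ew),  length 2*J + 2*J*n
# so that s_bx = z' A z and s_bxy = z' Q z.  Eigendecomposition turns each
# into a weighted sum of independent chi-square(1) variables; the weights of
# the between-group block of A are nonnegative (it is a sum of squares)
# while the within correction contributes negative weights.

# linear map from z to the model components, scaled by their SDs
component_maps <- function(p) {
  J <- p$J; n <- p$n
  # group-mean operator: (J x Jn), averages within each group
  Gm <- kronecker(diag(J), matrix(1 / n, 1, n))
  # centering across groups
  Cj <- diag(J) - matrix(1 / J, J, J)
  # within-group centering for individuals
  Cw <- diag(J * n) - kronecker(diag(J), matrix(1 / n, n, n))
  list(J = J, n = n, Gm = Gm, Cj = Cj, Cw = Cw)
}

#' Quadratic-form representations of the between (co)variance estimators
#'
#' Builds the symmetric coefficient matrices `A` (for the between-group
#' variance estimator of the predictor) and `Q` (for the between-group
#' covariance estimator) over the standardized vector of independent normal
#' model components, together with their eigendecompositions. Eigenvalues
#' below `1e-10` times the largest magnitude are set to zero.
#'
#' @param params an [lcm_params()] object (small J and n recommended; the
#'   matrices are dense of order `J(1+n)` and `2J(1+n)`).
#' @return An object of class `quadform_rep` with elements `A`, `Q`, the
#'   eigenvector/eigenvalue pairs `P_A`, `lambda_A`, `P_Q`, `lambda_Q`, and
#'   `dim_A`, `dim_Q`.
#' @export
build_quadform_reps <- function(params) {
  stopifnot(inherits(params, "lcm_params"))
  p <- params
  if (any(!is.finite(c(p$sigma2_bx, p$sigma2_wx, p$sigma2_eb, p$sigma2_ew))))
    stop("non-finite parameters")
  mp <- component_maps(p)
  J <- p$J; n <- p$n
  sU <- sqrt(p$sigma2_bx); sR <- sqrt(p$sigma2_wx)
  sEb <- sqrt(p$sigma2_eb); sEw <- sqrt(p$sigma2_ew)

  # centered group means of x as a linear map of (z_U, z_R)
  Mx <- cbind(mp$Cj %*% (sU * diag(J)), mp$Cj %*% (sR * mp$Gm))
  # within deviations of x as a map of (z_U, z_R): only z_R enters
  Wx <- cbind(matrix(0, J * n, J), sR * mp$Cw)
  A <- crossprod(Mx) / (J - 1) - crossprod(Wx) / (n * J * (n - 1))
  A <- (A + t(A)) / 2

  # maps over z = (z_U, z_R, z_eb, z_ew) for the covariance form
  dims <- c(J, J * n, J, J * n)
  zdim <- sum(dims)
  pad <- function(M, block) {
    out <- matrix(0, nrow(M), zdim)
    off <- c(0, cumsum(dims))[block]
    out[, (off + 1):(off + ncol(M))] <- M
    out
  }
  Mx2 <- pad(mp$Cj %*% (sU * diag(J)), 1) + pad(mp$Cj %*% (sR * mp$Gm), 2)
  My2 <- pad(mp$Cj %*% (p$beta_b * sU * diag(J)), 1) +
         pad(mp$Cj %*% (p$beta_w * sR * mp$Gm), 2) +
         pad(mp$Cj %*% (sEb * diag(J)), 3) +
         pad(mp$Cj %*% (sEw * mp$Gm), 4)
  Wx2 <- pad(sR * mp$Cw, 2)
  Wy2 <- pad(p$beta_w * sR * mp$Cw, 2) + pad(sEw * mp$Cw, 4)
  Q <- (crossprod(Mx2, My2) + crossprod(My2, Mx2)) / (2 * (J - 1)) -
       (crossprod(Wx2, Wy2) + crossprod(Wy2, Wx2)) / (2 * n * J * (n - 1))
  Q <- (Q + t(Q)) / 2

  clean <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    thr <- 1e-10 * max(abs(e$values), 1e-300)
    e$values[abs(e$values) < thr] <- 0
    e
  }
  eA <- clean(A); eQ <- clean(Q)
  structure(
    list(A = A, Q = Q,
         P_A = eA$vectors, lambda_A = eA$values,
         P_Q = eQ$vectors, lambda_Q = eQ$values,
         dim_A = nrow(A), dim_Q = nrow(Q), params = params),
    class = "quadform_rep")
}

#' @export
print.quadform_rep <- function(x, ...) {
  cat(sprintf(
    "Quadratic-form representations: A is %dx%d (rank %d), Q is %dx%d (rank %d)\n",
    x$dim_A, x$dim_A, sum(x$lambda_A != 0),
    x$dim_Q, x$dim_Q, sum(x$lambda_Q != 0)))
  invisible(x)
}

#' Gamma-sum representation of a quadratic form
#'
#' Maps each chi-square(1) term of the eigendecomposition to a scaled gamma:
#' a weight `c` on a chi-square(1) variable is Gamma(shape 1/2, scale 2c).
#' Equal eigenvalues are merged so each distinct weight with multiplicity m
#' becomes Gamma(shape m/2, scale 2c). The covariance form is indefinite:
#' its representation is the difference of the positive-weight and
#' negative-weight gamma sums.
#'
#' @param rep a [build_quadform_reps()] object.
#' @return A list with elements `bx` and `bxy`, each containing `shapes`,
#'   `scales` (signed: negative scale marks a subtracted term), and the
#'   implied analytic `mean` and `variance` of the form.
#' @export
gamma_rep_from_quadform <- function(rep) {
  stopifnot(inherits(rep, "quadform_rep"))
  one <- function(lam) {
    lam <- lam[lam != 0]
    tab <- table(signif(lam, 10))
    w <- as.numeric(names(tab))
    m <- as.numeric(tab)
    list(shapes = m / 2, scales = 2 * w,
         mean = sum(lam), variance = 2 * sum(lam^2))
  }
  list(bx = one(rep$lambda_A), bxy = one(rep$lambda_Q))
}

#' Sample a quadratic form by Monte Carlo
#'
#' Draws standard-normal working vectors and evaluates `z' M z`; used to
#' check the distributional identity between the quadratic-form route and
#' direct data simulation.
#'
#' @param rep a [build_quadform_reps()] object.
#' @param which `"bx"` or `"bxy"`.
#' @param nsim number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of `nsim` sampled values of the estimator.
#' @export
sample_quadform <- function(rep, which = c("bx", "bxy"), nsim = 1000,
                            seed = 1L) {
  stopifnot(inherits(rep, "quadform_rep"))
  which <- match.arg(which)
  M <- if (which == "bx") rep$A else rep$Q
  with_seed(seed, {
    Z <- matrix(stats::rnorm(nrow(M) * nsim), nrow(M), nsim)
    colSums((M %*% Z) * Z)
  })
}
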