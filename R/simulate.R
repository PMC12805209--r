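#' Simulation scenario specification
#'
#' One cell of the ICC-indexed simulation design: the predictor is
#' decomposed into normal between/within components with variances
#' `(icc_x, 1 - icc_x)` (unit total variance), and the outcome residual
#' variances are solved so that the outcome ICC equals `icc_y` under unit
#' total outcome variance. Intercepts and the grand mean are zero; they
#' cancel in every slope estimator.
#'
#' @param icc_x predictor intraclass correlation.
#' @param J number of groups.
#' @param n group size.
#' @param beta_b,beta_w between- and within-group slopes.
#' @param icc_y outcome intraclass correlation (default 0.2).
#' @param reps replication count carried by the spec (default 5000).
#' @param seed root seed for the scenario's replication streams.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(icc_x, J, n, beta_b = 0.5, beta_w = 0.5,
                          icc_y = 0.2, reps = 5000L, seed = 1L) {
  chk <- check_icc_feasibility(icc_x, icc_y, beta_b, beta_w)
  if (!chk$feasible)
    stop("infeasible scenario; violated: ", paste(chk$binding, collapse = "; "))
  structure(list(icc_x = icc_x, J = as.integer(J), n = as.integer(n),
                 beta_b = beta_b, beta_w = beta_w, icc_y = icc_y,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario: ICC_X = %.2f, J = %d, n = %d, beta_b = %.2f, beta_w = %.2f, ICC_Y = %.2f\n",
    x$icc_x, x$J, x$n, x$beta_b, x$beta_w, x$icc_y))
  invisible(x)
}

# counter-based child seed: independent streams per (scenario seed, rep).
# All arithmetic stays below 2^53 so it is exact in doubles.
child_seed <- function(seed, rep_index) {
  ((as.numeric(seed) %% 2147483647) * 48271 + rep_index * 9973) %% 2147483629 + 1
}

# draw the model components as J x n matrices; fast path for the study engine
draw_matrices <- function(p, seed) {
  J <- p$J; n <- p$n
  with_seed(seed, {
    U <- stats::rnorm(J, 0, sqrt(p$sigma2_bx))
    R <- matrix(stats::rnorm(J * n, 0, sqrt(p$sigma2_wx)), J, n)
    eb <- stats::rnorm(J, 0, sqrt(p$sigma2_eb))
    ew <- matrix(stats::rnorm(J * n, 0, sqrt(p$sigma2_ew)), J, n)
    list(X = p$mu_x + U + R,
         Y = p$intercept_b + p$beta_b * U + p$beta_w * R + eb + ew)
  })
}

# sufficient statistics straight from J x n matrices (no data.frame detour)
stats_from_matrices <- function(X, Y) {
  J <- nrow(X); n <- ncol(X)
  xb <- rowMeans(X); yb <- rowMeans(Y)
  xc <- X - xb; yc <- Y - yb
  dfw <- J * (n - 1)
  swx <- sum(xc * xc) / dfw; swy <- sum(yc * yc) / dfw
  swxy <- sum(xc * yc) / dfw
  mbx <- sum((xb - mean(xb))^2) / (J - 1)
  mby <- sum((yb - mean(yb))^2) / (J - 1)
  mbxy <- sum((xb - mean(xb)) * (yb - mean(yb))) / (J - 1)
  structure(
    list(xbar_j = xb, ybar_j = yb, mbx = mbx, mby = mby, mbxy = mbxy,
         swx = swx, swy = swy, swxy = swxy,
         s_bx = mbx - swx / n, s_by = mby - swy / n, s_bxy = mbxy - swxy / n,
         J = J, n = n),
    class = "lcm_stats")
}

#' Generate one balanced two-level dataset
#'
#' Draws a dataset from the scenario's data-generating process. Fully
#' reproducible: the same `(spec$seed, rep_index)` always yields the
#' identical dataset, and different replication indices use independent
#' counter-derived streams.
#'
#' @param spec a [scenario_spec()].
#' @param rep_index replication index (>= 1).
#' @return A [grouped_data()] object with groups labelled `1..J`.
#' @export
generate_dataset <- function(spec, rep_index = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  p <- lcm_params_from_icc(spec$icc_x, spec$icc_y, spec$beta_b, spec$beta_w,
                           spec$J, spec$n)
  m <- draw_matrices(p, child_seed(spec$seed, rep_index))
  grouped_data(as.vector(t(m$X)), as.vector(t(m$Y)),
               rep(seq_len(spec$J), each = spec$n))
}

#' Enumerate the factorial simulation design
#'
#' Crosses the design lists and keeps the feasible cells (each candidate is
#' screened with [check_icc_feasibility()]; excluded cells are returned as
#' an attribute). The default lists give the 540-scenario design.
#'
#' @param icc_x,J,n,beta_b,beta_w design value lists.
#' @param icc_y fixed outcome ICC.
#' @param reps,seed carried into every [scenario_spec()].
#' @return A list of `scenario_spec` objects; attribute `excluded` holds a
#'   data.frame of infeasible combinations (empty for the default design).
#' @examples
#' length(enumerate_scenarios())  # 540
#' @export
enumerate_scenarios <- function(icc_x = c(0.05, 0.1, 0.3, 0.5),
                                J = c(5, 10, 20, 30, 40),
                                n = c(5, 15, 30),
                                beta_b = c(0.2, 0.5, 0.6),
                                beta_w = c(0.2, 0.5, 0.7),
                                icc_y = 0.2, reps = 5000L, seed = 1L) {
  grid <- expand.grid(icc_x = icc_x, J = J, n = n,
                      beta_b = beta_b, beta_w = beta_w,
                      KEEP.OUT.ATTRS = FALSE)
  feasible <- vapply(seq_len(nrow(grid)), function(i)
    check_icc_feasibility(grid$icc_x[i], icc_y,
                          grid$beta_b[i], grid$beta_w[i])$feasible,
    logical(1))
  idx <- which(feasible)
  specs <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    scenario_spec(grid$icc_x[i], grid$J[i], grid$n[i],
                  grid$beta_b[i], grid$beta_w[i], icc_y,
                  reps = reps, seed = seed + 1000 * k)
  })
  structure(specs, excluded = grid[!feasible, , drop = FALSE])
}
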