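#' Run one Monte-Carlo scenario
#'
#' Replicates a scenario's data-generating process, applies the requested
#' estimators to every replication, and summarizes the errors by RMSE and
#' relative bias with Monte-Carlo standard errors. ML failures and extreme
#' values are included as computed (they are a documented property of the
#' ML estimator, and RMSE is meant to reflect them); an optional winsor
#' limit is available for diagnostics only.
#'
#' @param spec a [scenario_spec()].
#' @param estimators character subset of `c("ML", "RB", "RB_true")`, or a
#'   named list of functions mapping an `lcm_stats` object to a slope
#'   estimate (used by tests with synthetic estimators).
#' @param reps number of replications (default `spec$reps`).
#' @param grid_n grid resolution for the regularized estimators.
#' @param winsor optional symmetric absolute cap applied to estimates before
#'   summarizing (default `Inf`, i.e. off).
#' @return An object of class `scenario_result`: a list with the spec, the
#'   per-estimator `rmse`, `relbias`, their Monte-Carlo standard errors
#'   (`rmse_mcse`, `relbias_mcse`), `reps`, `n_failed`, and the raw
#'   `estimates` matrix.
#' @export
run_scenario <- function(spec, estimators = c("ML", "RB", "RB_true"),
                         reps = NULL, grid_n = 100, winsor = Inf) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(reps)) reps <- spec$reps
  p <- lcm_params_from_icc(spec$icc_x, spec$icc_y, spec$beta_b, spec$beta_w,
                           spec$J, spec$n)
  if (is.character(estimators)) {
    estimators <- match.arg(estimators, c("ML", "RB", "RB_true"),
                            several.ok = TRUE)
    fns <- list()
    if ("ML" %in% estimators)
      fns$ML <- function(st) st$s_bxy / st$s_bx
    if ("RB" %in% estimators)
      fns$RB <- function(st) rb_core(st, grid_n = grid_n)$beta_rb
    if ("RB_true" %in% estimators)
      fns$RB_true <- function(st)
        rb_core(st, grid_n = grid_n, benchmark_beta = spec$beta_b)$beta_rb
  } else {
    fns <- estimators
    stopifnot(is.list(fns), !is.null(names(fns)))
  }
  est <- matrix(NA_real_, reps, length(fns),
                dimnames = list(NULL, names(fns)))
  n_failed <- integer(length(fns)); names(n_failed) <- names(fns)
  for (r in seq_len(reps)) {
    m <- draw_matrices(p, child_seed(spec$seed, r))
    st <- stats_from_matrices(m$X, m$Y)
    for (e in names(fns)) {
      v <- tryCatch(fns[[e]](st), error = function(err) NA_real_)
      if (!is.finite(v)) n_failed[e] <- n_failed[e] + 1L
      est[r, e] <- v
    }
  }
  est_w <- pmin(pmax(est, -winsor), winsor)
  err <- est_w - spec$beta_b
  rmse <- sqrt(colMeans(err^2, na.rm = TRUE))
  rmse_mcse <- apply(err, 2, function(x) {
    x <- x[is.finite(x)]
    stats::sd(x^2) / (2 * sqrt(mean(x^2)) * sqrt(length(x)))
  })
  if (spec$beta_b == 0) {
    relbias <- rep(NA_real_, length(fns)); names(relbias) <- names(fns)
    relbias_mcse <- relbias
  } else {
    relbias <- colMeans(err, na.rm = TRUE) / spec$beta_b
    relbias_mcse <- apply(err, 2, function(x) {
      x <- x[is.finite(x)]
      stats::sd(x) / (abs(spec$beta_b) * sqrt(length(x)))
    })
  }
  structure(
    list(spec = spec, rmse = rmse, relbias = relbias,
         rmse_mcse = rmse_mcse, relbias_mcse = relbias_mcse,
         reps = reps, n_failed = n_failed, estimates = est),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$spec)
  tab <- data.frame(RMSE = x$rmse, `MC SE` = x$rmse_mcse,
                    RelBias = x$relbias, check.names = FALSE)
  print(format(tab, digits = 4))
  invisible(x)
}

#' Tidy table of scenario results
#'
#' @param results list of [run_scenario()] results.
#' @return A long data.frame: one row per (scenario, estimator).
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(icc_x = r$spec$icc_x, J = r$spec$J, n = r$spec$n,
               beta_b = r$spec$beta_b, beta_w = r$spec$beta_w,
               estimator = names(r$rmse),
               rmse = as.numeric(r$rmse),
               rmse_mcse = as.numeric(r$rmse_mcse),
               relbias = as.numeric(r$relbias),
               relbias_mcse = as.numeric(r$relbias_mcse),
               reps = r$reps, row.names = NULL)
  }))
}

#' Average results within each (n, J) design cell
#'
#' Averages RMSE and relative bias over the remaining design factors within
#' each combination of group size `n` and number of groups `J`, and flags
#' the estimator with the smallest RMSE and smallest absolute relative bias
#' per cell. Missing cells are reported, not imputed.
#'
#' @param results list of [run_scenario()] results (or a data.frame from
#'   [results_table()]).
#' @return A data.frame keyed by `(n, J, estimator)` with columns `rmse`,
#'   `relbias`, `n_scenarios`, `best_rmse`, `best_bias`.
#' @export
summarize_by_design <- function(results) {
  tab <- if (is.data.frame(results)) results else results_table(results)
  agg <- stats::aggregate(cbind(rmse, relbias) ~ n + J + estimator,
                          data = tab, FUN = mean)
  cnt <- stats::aggregate(rmse ~ n + J + estimator, data = tab, FUN = length)
  names(cnt)[4] <- "n_scenarios"
  agg <- merge(agg, cnt, by = c("n", "J", "estimator"))
  agg$best_rmse <- FALSE
  agg$best_bias <- FALSE
  for (cell in split(seq_len(nrow(agg)),
                     interaction(agg$n, agg$J, drop = TRUE))) {
    agg$best_rmse[cell[which.min(agg$rmse[cell])]] <- TRUE
    agg$best_bias[cell[which.min(abs(agg$relbias[cell]))]] <- TRUE
  }
  expected <- length(unique(tab$n)) * length(unique(tab$J))
  got <- nrow(unique(agg[c("n", "J")]))
  if (got < expected)
    message(sprintf("note: %d of %d (n, J) cells present", got, expected))
  agg[order(agg$n, agg$J, agg$estimator), ]
}
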