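# Fitting criteria: log10 residuals, the single-objective sum-of-squares
# function, the two-component multi-objective vector, the ABC fitness, and
# the percent-contribution decomposition.

.KIN_PENALTY_TOTAL <- 1e12

#' Log10 residuals of a prediction against a dataset
#'
#' Residuals are computed on the log10 scale, which places substrate and
#' cell measurements on equivalent scales and removes magnitude bias:
#' `r[i] = log10(obs[i]) - log10(max(pred[i], 1e-12))`.
#'
#' @param dataset a [batch_dataset()].
#' @param prediction a [integrate_trajectory()] result evaluated at exactly
#'   the dataset's times.
#' @return List with numeric vectors `r_subs` and `r_cells`, and logical
#'   `penalty` (TRUE when the prediction carries an integration-failure
#'   penalty, in which case the residuals are a sentinel yielding a total
#'   objective of 1e12).
#' @export
residuals_log10 <- function(dataset, prediction) {
  stopifnot(inherits(dataset, "batch_dataset"),
            inherits(prediction, "trajectory_prediction"))
  if (prediction$penalty) {
    n <- length(dataset$times)
    s <- sqrt(.KIN_PENALTY_TOTAL / 2 / n)
    return(list(r_subs = rep(s, n), r_cells = rep(s, n), penalty = TRUE))
  }
  if (length(prediction$times) != length(dataset$times) ||
      any(abs(prediction$times - dataset$times) > 1e-9))
    stop("prediction must be evaluated at exactly the dataset's times",
         call. = FALSE)
  list(
    r_subs = log10(dataset$S_obs) - log10(pmax(prediction$S_pred, 1e-12)),
    r_cells = log10(dataset$C_obs) - log10(pmax(prediction$C_pred, 1e-12)),
    penalty = FALSE
  )
}

#' Objective value with percent-contribution decomposition
#'
#' Assemble an objective value from per-variable sums of squared log10
#' residuals.  The total is the unweighted sum (the per-variable standard
#' deviation weights are dropped when replicate-averaged data are fitted);
#' percent contributions dissect the total into its substrate and cell
#' shares.
#'
#' @param ssr_subs,ssr_cells sums of squared log10 residuals (>= 0).
#' @param penalty logical penalty flag to propagate.
#' @return An object of class `objective_value`: `ssr_subs`, `ssr_cells`,
#'   `total`, `pct_subs`, `pct_cells`, `degenerate` (TRUE when total is 0
#'   and the 50/50 split convention applies), `penalty`.
#' @export
objective_value <- function(ssr_subs, ssr_cells, penalty = FALSE) {
  stopifnot(ssr_subs >= 0, ssr_cells >= 0)
  total <- ssr_subs + ssr_cells
  degenerate <- total <= 0
  pct_subs <- if (degenerate) 50 else 100 * ssr_subs / total
  structure(
    list(ssr_subs = ssr_subs, ssr_cells = ssr_cells, total = total,
         pct_subs = pct_subs,
         pct_cells = 100 - pct_subs,   # complement: shares sum to 100 exactly
         degenerate = degenerate, penalty = penalty),
    class = "objective_value"
  )
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("<objective_value> total = %.6g (subs %.6g [%.1f%%], cells %.6g [%.1f%%])%s\n",
              x$total, x$ssr_subs, x$pct_subs, x$ssr_cells, x$pct_cells,
              if (x$penalty) " [PENALTY]" else ""))
  invisible(x)
}

#' Single-objective fitting criterion
#'
#' The joint objective minimized in the global single-objective stage: the
#' sum over both variables of squared log10 residuals, with unit variance
#' weights (`sigma_weights` restores the per-variable `1/sigma^2` weighting
#' for users with enough replicates to estimate overall variances).
#'
#' @inheritParams residuals_log10
#' @param sigma_weights optional `c(sigma_subs, sigma_cells)` overall
#'   standard deviations; default `c(1, 1)` (weights dropped).
#' @return An [objective_value()].
#' @export
of1 <- function(dataset, prediction, sigma_weights = c(1, 1)) {
  r <- residuals_log10(dataset, prediction)
  objective_value(sum(r$r_subs^2) / sigma_weights[1]^2,
                  sum(r$r_cells^2) / sigma_weights[2]^2,
                  penalty = r$penalty)
}

#' Multi-objective fitting criterion
#'
#' The two-component objective vector minimized jointly in the
#' multi-objective stage: per-variable sums of squared log10 residuals.
#' Identical to the components of [of1()].
#'
#' @inheritParams residuals_log10
#' @return Numeric vector `c(ssr_subs, ssr_cells)`.
#' @export
of_mo <- function(dataset, prediction) {
  v <- of1(dataset, prediction)
  c(ssr_subs = v$ssr_subs, ssr_cells = v$ssr_cells)
}

#' ABC target: observed summary statistics and tolerances
#'
#' The observed summary statistics are the per-variable sums of squared
#' residuals of the best compromise solution (normally from the
#' multi-objective stage); `epsilons` are the per-statistic tolerances
#' defining the behavioral region.  The default tolerance is
#' `max(0.05 * S_j, 0.01)` per statistic.
#'
#' @param observed_stats numeric vector `c(ssr_subs, ssr_cells)` (>= 0).
#' @param epsilons per-statistic tolerances (> 0); recycled if length 1.
#' @return An object of class `abc_target`.
#' @export
abc_target <- function(observed_stats,
                       epsilons = pmax(0.05 * observed_stats, 0.01)) {
  if (any(observed_stats < 0)) stop("observed_stats must be >= 0",
                                    call. = FALSE)
  epsilons <- rep_len(epsilons, length(observed_stats))
  if (any(epsilons <= 0)) stop("epsilons must be > 0", call. = FALSE)
  structure(list(observed_stats = unname(observed_stats),
                 epsilons = unname(epsilons)),
            class = "abc_target")
}

#' ABC fitness of simulated summary statistics
#'
#' The likelihood-free fitness maximized by the ABC stage:
#' \deqn{OF_2 = \min_{j=1:m} \{\epsilon_j - |S_j - \hat S_j|\},}
#' where \eqn{S_j} are the observed and \eqn{\hat S_j} the simulated
#' summary statistics.  A candidate is *behavioral* (inside the tolerance
#' region) iff the fitness is >= 0.
#'
#' @param simulated_stats numeric vector, same length as the target's
#'   observed statistics.
#' @param target an [abc_target()].
#' @return Scalar fitness (to maximize).
#' @examples
#' t <- abc_target(c(1, 2), epsilons = c(0.1, 0.1))
#' of2_abc(c(1, 2), t)        # 0.1: zero distance returns min epsilon
#' of2_abc(c(1.05, 2.5), t)   # -0.4
#' @export
of2_abc <- function(simulated_stats, target) {
  stopifnot(inherits(target, "abc_target"))
  if (length(simulated_stats) != length(target$observed_stats))
    stop("simulated_stats length (", length(simulated_stats),
         ") does not match target (", length(target$observed_stats), ")",
         call. = FALSE)
  min(target$epsilons - abs(target$observed_stats - simulated_stats))
}

# Objective closure over log10-scaled parameter vectors, shared by the
# optimizers and the ABC sampler.  `component` selects what fn() returns.
# `fixed` holds parameters excluded from the search at known values
# (restricted fits, e.g. when Y or b are known from independent assays).
.kin_objective <- function(spec, dataset, bounds = default_bounds(spec),
                           component = c("total", "subs", "cells", "vector"),
                           sigma_weights = c(1, 1), fixed = list()) {
  spec <- kin_model(spec)
  component <- match.arg(component)
  pn <- setdiff(spec$param_names, names(fixed))
  if (!length(pn)) stop("no free parameters left to fit", call. = FALSE)
  if (length(fixed) && !all(names(fixed) %in% spec$param_names))
    stop("fixed names unknown to ", spec$name, " model: ",
         paste(setdiff(names(fixed), spec$param_names), collapse = ", "),
         call. = FALSE)
  bounds <- bounds[pn]
  if (any(vapply(bounds, is.null, logical(1))))
    stop("bounds must cover parameters: ", paste(pn, collapse = ", "),
         call. = FALSE)
  lower <- log10(vapply(bounds, `[`, numeric(1), 1))
  upper <- log10(vapply(bounds, `[`, numeric(1), 2))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite and strictly positive", call. = FALSE)
  fixed_vec <- unlist(fixed)
  to_params <- function(z) {
    v <- c(stats::setNames(10^z, pn), fixed_vec)
    kin_params_from_vector(v[spec$param_names], spec)
  }
  eval_obj <- function(z) {
    p <- to_params(z)
    pred <- integrate_trajectory(spec, p, dataset$S0, dataset$C0,
                                 dataset$times)
    of1(dataset, pred, sigma_weights)
  }
  fn <- switch(component,
    total = function(z) eval_obj(z)$total,
    subs = function(z) eval_obj(z)$ssr_subs,
    cells = function(z) eval_obj(z)$ssr_cells,
    vector = function(z) { v <- eval_obj(z); c(v$ssr_subs, v$ssr_cells) }
  )
  list(fn = fn, lower = lower, upper = upper, to_params = to_params,
       eval_obj = eval_obj, param_names = pn)
}
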