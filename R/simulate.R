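# Forward integration of the coupled batch ODEs and generation of synthetic
# batch datasets emulating sparse, noisy, replicated biodegradation
# experiments.

#' Integrate the coupled batch ODE system
#'
#' Solve the substrate/biomass system forward in time from `S(0) = S0`,
#' `X(0) = b * C0` with an adaptive, stiff-capable solver
#' ([deSolve::lsoda()] driving the package's compiled right-hand side).
#' The initial biomass is always recomputed from the candidate `b`, so the
#' initial condition moves consistently with the parameter vector during
#' fitting.
#'
#' If the integrator fails (step-size collapse, non-finite states) the
#' returned prediction carries `penalty = TRUE` instead of raising, so that
#' objective functions can map it to a large finite value and optimizers
#' keep running.
#'
#' @inheritParams growth_rate
#' @param S0 initial substrate concentration, mg/L (> 0).
#' @param C0 initial cell measurement (OD or counts, > 0).
#' @param times output times in hours, sorted, starting at 0.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return An object of class `trajectory_prediction`: list with `times`,
#'   `S_pred`, `X_pred` (mg/L), `C_pred = X_pred / b` (measurement units),
#'   all floored at `1e-12`, and a logical `penalty` flag.
#' @examples
#' p <- kinetic_params(mu_max = 0.3, Ks = 5, Y = 0.4, kd = 0.01, b = 1)
#' tr <- integrate_trajectory("Monod", p, S0 = 50, C0 = 1,
#'                            times = seq(0, 24, by = 6))
#' tr$S_pred
#' @export
integrate_trajectory <- function(spec, params, S0, C0, times,
                                 rtol = 1e-8, atol = 1e-10) {
  spec <- kin_model(spec)
  .kin_validate_params(spec, params)
  if (S0 <= 0 || C0 <= 0) stop("S0 and C0 must be > 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  X0 <- params$b * C0
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(
      y = c(S0, X0), times = times, func = "kinfit_derivs",
      parms = .kin_parms_vector(spec, params), dllname = "kinfit",
      initfunc = "kinfit_init", rtol = rtol, atol = atol
    )),
    error = function(e) NULL
  )
  bad <- is.null(out) || nrow(out) < length(times) || any(!is.finite(out))
  if (bad) {
    return(structure(
      list(times = times, S_pred = rep(NA_real_, length(times)),
           X_pred = rep(NA_real_, length(times)),
           C_pred = rep(NA_real_, length(times)), penalty = TRUE),
      class = "trajectory_prediction"))
  }
  S <- pmax(out[, 2], 1e-12)
  X <- pmax(out[, 3], 1e-12)
  structure(
    list(times = times, S_pred = S, X_pred = X, C_pred = X / params$b,
         penalty = FALSE),
    class = "trajectory_prediction"
  )
}

#' @export
print.trajectory_prediction <- function(x, ...) {
  cat("<trajectory_prediction: ", length(x$times), " timepoints",
      if (x$penalty) ", PENALTY (integration failure)" else "", ">\n",
      sep = "")
  print(utils::head(data.frame(time_h = x$times, S_pred = x$S_pred,
                               C_pred = x$C_pred), 10))
  invisible(x)
}

#' Batch-experiment dataset
#'
#' Container for an observed two-variable batch time series: per-timepoint
#' replicate means of substrate (mg/L) and of the cell measurement (OD or
#' counts), with optional replicate standard deviations and the known
#' initial conditions.
#'
#' @param times hours, strictly increasing, first entry 0.
#' @param S_obs mean substrate concentration per timepoint, mg/L (> 0).
#' @param C_obs mean cell measurement per timepoint (> 0).
#' @param S_sd,C_sd optional per-timepoint replicate standard deviations
#'   (`NULL` or `NA` when unavailable).
#' @param S0,C0 initial conditions; default to the first observations.
#' @param meta optional list of provenance metadata.
#' @return An object of class `batch_dataset`.
#' @export
batch_dataset <- function(times, S_obs, C_obs, S_sd = NULL, C_sd = NULL,
                          S0 = S_obs[1], C0 = C_obs[1], meta = list()) {
  n <- length(times)
  if (length(S_obs) != n || length(C_obs) != n)
    stop("times, S_obs and C_obs must have equal lengths", call. = FALSE)
  if (!is.null(S_sd) && length(S_sd) != n)
    stop("S_sd length must match times", call. = FALSE)
  if (!is.null(C_sd) && length(C_sd) != n)
    stop("C_sd length must match times", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (times[1] != 0)
    stop("first timepoint must be 0 h", call. = FALSE)
  bad <- which(!is.finite(S_obs) | S_obs <= 0 | !is.finite(C_obs) | C_obs <= 0)
  if (length(bad))
    stop("non-positive observation at row ", bad[1],
         " (log10 objective requires positive data)", call. = FALSE)
  if (S0 <= 0 || C0 <= 0) stop("S0 and C0 must be > 0", call. = FALSE)
  structure(
    list(times = times, S_obs = S_obs, C_obs = C_obs,
         S_sd = S_sd, C_sd = C_sd, S0 = S0, C0 = C0, meta = meta),
    class = "batch_dataset"
  )
}

#' @export
print.batch_dataset <- function(x, ...) {
  cat("<batch_dataset: ", length(x$times), " timepoints over ",
      max(x$times), " h; S0 = ", x$S0, " mg/L, C0 = ", x$C0, ">\n", sep = "")
  df <- data.frame(time_h = x$times, S_mean = x$S_obs, C_mean = x$C_obs)
  if (!is.null(x$S_sd)) df$S_sd <- x$S_sd
  if (!is.null(x$C_sd)) df$C_sd <- x$C_sd
  print(df)
  invisible(x)
}

#' Synthetic-experiment design
#'
#' Defaults emulate the structure of published batch biodegradation
#' experiments: a handful of roughly daily observations of substrate decay
#' and biomass growth over several days, at most three replicates, and
#' noise that is homoscedastic on the log10 scale.
#'
#' @param S0 initial substrate, mg/L.
#' @param C0 initial cell measurement (e.g. OD).
#' @param n_timepoints number of sampling times (>= 4), equally spaced.
#' @param duration_h experiment duration, hours.
#' @param n_replicates replicate experiments per timepoint.
#' @param noise_sd_log10 standard deviation of the observation noise on the
#'   log10 scale (0 for noise-free data).
#' @return A list of class `synth_design`.
#' @export
synth_design <- function(S0 = 50, C0 = 0.05, n_timepoints = 8,
                         duration_h = 96, n_replicates = 3,
                         noise_sd_log10 = 0.05) {
  if (n_timepoints < 4) stop("n_timepoints must be >= 4", call. = FALSE)
  if (noise_sd_log10 < 0) stop("noise_sd_log10 must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(S0 = S0, C0 = C0, n_timepoints = n_timepoints,
                 duration_h = duration_h, n_replicates = n_replicates,
                 noise_sd_log10 = noise_sd_log10),
            class = "synth_design")
}

#' Generate a synthetic batch dataset
#'
#' Integrates the true trajectory for `params` and perturbs it with
#' multiplicative lognormal noise: each replicate observation is
#' `truth * 10^eps` with `eps ~ Normal(0, noise_sd_log10)` i.i.d. per
#' variable and timepoint, i.e. noise additive and homoscedastic on the
#' log10 scale -- the error model the fitting objective assumes.  Replicate
#' means and standard deviations are returned; the generation is fully
#' reproducible from `seed`.
#'
#' @inheritParams growth_rate
#' @param design a [synth_design()] (or list coercible to one).
#' @param seed integer seed for the noise draws.
#' @return A [batch_dataset()] whose `meta` records the model, true
#'   parameters, design and seed.
#' @examples
#' p <- kinetic_params(mu_max = 0.1, Ks = 20, Y = 0.4, kd = 0.005, b = 2,
#'                     n = 1.5)
#' ds <- generate_synthetic("Moser", p, synth_design(), seed = 1)
#' @export
generate_synthetic <- function(spec, params, design = synth_design(),
                               seed = 1) {
  spec <- kin_model(spec)
  .kin_validate_params(spec, params)
  if (!inherits(design, "synth_design")) design <- do.call(synth_design, design)
  times <- seq(0, design$duration_h, length.out = design$n_timepoints)
  truth <- integrate_trajectory(spec, params, design$S0, design$C0, times)
  if (truth$penalty)
    stop("integration of the true trajectory failed; check parameters",
         call. = FALSE)
  if (any(truth$S_pred < 1e-10) || any(truth$C_pred < 1e-10))
    stop("true trajectory falls below 1e-10 at a sampled time; ",
         "log-scale noise is undefined near 0 -- use a shorter duration_h",
         call. = FALSE)
  n <- length(times)
  R <- design$n_replicates
  sim <- withr::with_seed(as.integer(seed), {
    eps_S <- matrix(stats::rnorm(n * R, 0, design$noise_sd_log10), n, R)
    eps_C <- matrix(stats::rnorm(n * R, 0, design$noise_sd_log10), n, R)
    list(S = truth$S_pred * 10^eps_S, C = truth$C_pred * 10^eps_C)
  })
  S_sd <- if (R > 1) apply(sim$S, 1, stats::sd) else NULL
  C_sd <- if (R > 1) apply(sim$C, 1, stats::sd) else NULL
  batch_dataset(
    times = times,
    S_obs = rowMeans(sim$S), C_obs = rowMeans(sim$C),
    S_sd = S_sd, C_sd = C_sd,
    S0 = design$S0, C0 = design$C0,
    meta = list(model = spec$name, model_id = spec$id,
                true_params = kin_params_vector(params),
                design = unclass(design), seed = as.integer(seed),
                replicates = sim, synthetic = TRUE)
  )
}
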