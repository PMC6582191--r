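# Step 3: multi-chain approximate Bayesian computation with
# differential-evolution proposals sampled from an archive of past states,
# targeting the compromise solution's summary statistics.

#' Configuration for the ABC stage
#'
#' Defaults follow the published run conditions: 6 parallel chains and
#' 150,000 generations (900,000 model evaluations overall), with
#' convergence declared when the overall Gelman-Rubin statistic falls
#' below 1.2.  Desk-scale runs use far fewer generations.
#'
#' @param n_chains number of chains (>= 3).
#' @param n_generations generations per chain.
#' @param seed RNG seed.
#' @param thin_archive append current chain states to the past-states
#'   archive every this many generations.
#' @param monitor_interval generations between Gelman-Rubin evaluations.
#' @param gamma_jump fraction of proposals using the full jump `gamma = 1`
#'   (mode-hopping moves); the rest use `2.38 / sqrt(2 d)`.
#' @param jitter_rel relative scale (fraction of each coordinate's prior
#'   width) of the small Gaussian jitter added to every proposal.
#' @return A list of class `abc_config`.
#' @export
abc_config <- function(n_chains = 6, n_generations = 150000, seed = 1,
                       thin_archive = 10, monitor_interval = 500,
                       gamma_jump = 0.1, jitter_rel = 1e-6) {
  stopifnot(n_chains >= 3, n_generations >= 10, thin_archive >= 1,
            monitor_interval >= 2)
  structure(list(n_chains = as.integer(n_chains),
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed),
                 thin_archive = as.integer(thin_archive),
                 monitor_interval = as.integer(monitor_interval),
                 gamma_jump = gamma_jump, jitter_rel = jitter_rel),
            class = "abc_config")
}

#' Multi-chain ABC sampling of the behavioral parameter region
#'
#' Chains are initialized uniformly in the (log10-scaled) prior box.
#' Proposals are differential-evolution moves built from the difference of
#' two distinct members of a thinned past-states archive, scaled by
#' `gamma = 2.38 / sqrt(2 d)` (with a 10% fraction of full `gamma = 1`
#' jumps) plus a small Gaussian jitter, reflected at the prior bounds.
#' Acceptance is likelihood-free and monotone: while a chain is outside
#' the behavioral region (fitness < 0) a candidate is accepted iff its
#' [of2_abc()] fitness is at least the current one (hill-climb toward the
#' region); once inside, any behavioral candidate (fitness >= 0) is
#' accepted, yielding uniform exploration of the region.
#'
#' @inheritParams fit_so
#' @param target an [abc_target()] built from the compromise solution's
#'   per-variable sums of squared residuals.
#' @param config an [abc_config()].
#' @param bounds named list of natural-scale prior bounds (uniform on the
#'   log10 scale); defaults to [default_bounds()].
#' @param fixed named list of parameters held fixed (restricted fits).
#' @return An object of class `abc_history`: `samples` (array chains x
#'   generations x parameters, natural scale), `fitness` (chains x
#'   generations matrix of OF2 values), `accepted` (logical matrix),
#'   `R_trace` (data.frame generation/R), `target`, `config`,
#'   `param_names`, `acceptance_rate`, `model`.
#' @export
abc_sample <- function(spec, dataset, target, config = abc_config(),
                       bounds = default_bounds(spec), fixed = list()) {
  spec <- kin_model(spec)
  stopifnot(inherits(target, "abc_target"))
  obj <- .kin_objective(spec, dataset, bounds, component = "vector",
                        fixed = fixed)
  d <- length(obj$lower)
  nc <- config$n_chains
  ng <- config$n_generations
  lower <- obj$lower; upper <- obj$upper
  width <- upper - lower
  jit <- config$jitter_rel * width
  gamma0 <- 2.38 / sqrt(2 * d)
  reflect <- function(x) {
    for (k in 1:6) {
      lo <- x < lower; x[lo] <- 2 * lower[lo] - x[lo]
      hi <- x > upper; x[hi] <- 2 * upper[hi] - x[hi]
      if (!any(x < lower | x > upper)) break
    }
    pmin(pmax(x, lower), upper)
  }
  withr::with_seed(config$seed, {
    n0 <- max(10 * d, nc)
    Z <- matrix(stats::runif(n0 * d, rep(lower, each = n0),
                             rep(upper, each = n0)), n0, d)
    states <- Z[seq_len(nc), , drop = FALSE]
    fit <- apply(states, 1, function(z) of2_abc(obj$fn(z), target))
    samples <- array(NA_real_, c(nc, ng, d))
    fitness <- matrix(NA_real_, nc, ng)
    accepted <- matrix(FALSE, nc, ng)
    R_gen <- integer(0); R_val <- numeric(0)
    for (g in seq_len(ng)) {
      for (ci in seq_len(nc)) {
        zz <- Z[sample.int(nrow(Z), 2), , drop = FALSE]
        gamma <- if (stats::runif(1) < config$gamma_jump) 1 else gamma0
        prop <- states[ci, ] +
          gamma * (1 + stats::runif(1, -0.1, 0.1)) * (zz[1, ] - zz[2, ]) +
          stats::rnorm(d, 0, jit)
        prop <- reflect(prop)
        fprop <- of2_abc(obj$fn(prop), target)
        ok <- if (fit[ci] < 0) fprop >= fit[ci] else fprop >= 0
        if (ok) {
          states[ci, ] <- prop
          fit[ci] <- fprop
          accepted[ci, g] <- TRUE
        }
        samples[ci, g, ] <- states[ci, ]
        fitness[ci, g] <- fit[ci]
      }
      if (g %% config$thin_archive == 0) Z <- rbind(Z, states)
      if (g %% config$monitor_interval == 0 && g >= 20) {
        R_gen <- c(R_gen, g)
        R_val <- c(R_val, gelman_rubin(samples[, seq_len(g), , drop = FALSE]))
      }
    }
    if (all(fit < 0))
      stop("no chain reached the behavioral region (OF2 >= 0) within ",
           ng, " generations; increase the epsilons or n_generations",
           call. = FALSE)
    samples_nat <- 10^samples
    dimnames(samples_nat) <- list(NULL, NULL, obj$param_names)
    structure(
      list(samples = samples_nat, fitness = fitness, accepted = accepted,
           R_trace = data.frame(generation = R_gen, R = R_val),
           target = target, config = config,
           param_names = obj$param_names,
           acceptance_rate = mean(accepted), model = spec$name,
           bounds = bounds[obj$param_names], fixed = fixed),
      class = "abc_history"
    )
  })
}

#' @export
print.abc_history <- function(x, ...) {
  dims <- dim(x$samples)
  cat("<abc_history: ", dims[1], " chains x ", dims[2], " generations x ",
      dims[3], " parameters (", x$model, ")>\n", sep = "")
  cat(sprintf("  acceptance rate %.3f; final R = %.4f\n", x$acceptance_rate,
              utils::tail(x$R_trace$R, 1)))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Univariate potential scale reduction per parameter from between- and
#' within-chain variances, computed on the second half of each chain
#' (standard burn-in discard); the overall statistic is the maximum over
#' parameters.  With `m` chains of `n` retained draws, chain means
#' \eqn{\bar\theta_j} and within-chain variances \eqn{s_j^2}:
#' \deqn{W = \tfrac1m \sum s_j^2, \quad B = \tfrac{n}{m-1}\sum
#'   (\bar\theta_j - \bar\theta)^2, \quad
#'   \hat R = \sqrt{\tfrac{n-1}{n} + \tfrac{B}{nW}}.}
#' Values below 1.2 are conventionally taken as converged.
#'
#' @param samples array `chains x generations x parameters` (a matrix is
#'   treated as one parameter), on any fixed transformation of the
#'   parameters.
#' @param use_second_half discard the first half of each chain (default);
#'   set `FALSE` to use all provided draws.
#' @return Overall R (max over parameters), with per-parameter values in
#'   attribute `"per_parameter"`.  If every chain has zero within-chain
#'   variance for some parameter the result is `NA` with a warning
#'   (degenerate chains).
#' @export
gelman_rubin <- function(samples, use_second_half = TRUE) {
  if (is.matrix(samples)) samples <- array(samples, c(dim(samples), 1))
  stopifnot(length(dim(samples)) == 3, dim(samples)[1] >= 2)
  ng <- dim(samples)[2]
  if (use_second_half) {
    keep <- (floor(ng / 2) + 1):ng
    samples <- samples[, keep, , drop = FALSE]
  }
  n <- dim(samples)[2]
  m <- dim(samples)[1]
  if (n < 10) stop("need >= 10 retained draws per chain", call. = FALSE)
  np <- dim(samples)[3]
  Rp <- numeric(np)
  for (k in seq_len(np)) {
    x <- samples[, , k, drop = TRUE]          # m x n
    means <- rowMeans(x)
    W <- mean(apply(x, 1, stats::var))
    B <- n * stats::var(means)
    if (W <= 0) {
      Rp[k] <- if (B <= 0) 1 else NA_real_
      next
    }
    Rp[k] <- sqrt((n - 1) / n + B / (n * W))
  }
  names(Rp) <- dimnames(samples)[[3]]
  if (anyNA(Rp))
    warning("zero within-chain variance with nonzero between-chain ",
            "variance: degenerate chains", call. = FALSE)
  structure(max(Rp), per_parameter = Rp)
}

#' Summarize an ABC run as a posterior
#'
#' Discards `burn_in_fraction` of each chain, pools the remaining draws,
#' and reports per-parameter posterior mean, sd and 2.5/97.5 percentiles
#' plus two pointwise 95% trajectory bands: the *parameter* uncertainty
#' band (percentiles of trajectories integrated at posterior draws) and
#' the *predictive* uncertainty band (the parameter band widened on the
#' log10 scale by 1.96 times the residual noise scale, estimated from the
#' best-fitness draw's residual standard deviation, since sparse replicate
#' counts preclude per-point noise estimates).
#'
#' @inheritParams fit_so
#' @param history an [abc_sample()] result.
#' @param burn_in_fraction fraction of each chain discarded.
#' @param times trajectory evaluation grid (default: 50 points spanning
#'   the dataset's time range).
#' @param n_traj maximum number of posterior draws integrated for the
#'   bands.
#' @param check_convergence require overall R < 1.2 (set `FALSE` to
#'   override explicitly).
#' @return An object of class `posterior_summary`: `params` (data.frame
#'   mean/sd/q2.5/q97.5 per parameter), `bands` (data.frame with time and
#'   the S/C parameter and predictive band columns plus the posterior
#'   median trajectory), `R`, `n_draws`, `sigma_res`.
#' @export
summarize_posterior <- function(history, spec, dataset,
                                burn_in_fraction = 0.5, times = NULL,
                                n_traj = 500, check_convergence = TRUE) {
  stopifnot(inherits(history, "abc_history"))
  spec <- kin_model(spec)
  ng <- dim(history$samples)[2]
  nc <- dim(history$samples)[1]
  keep <- (floor(ng * burn_in_fraction) + 1):ng
  R <- gelman_rubin(log10(history$samples), use_second_half = TRUE)
  if (check_convergence && (is.na(R) || R >= 1.2))
    stop("chains not converged (overall R = ", signif(R, 4),
         " >= 1.2); rerun longer or pass check_convergence = FALSE",
         call. = FALSE)
  draws <- do.call(rbind, lapply(seq_len(nc), function(ci)
    history$samples[ci, keep, , drop = TRUE]))
  colnames(draws) <- history$param_names
  fixed_vec <- unlist(history$fixed)
  full <- function(v) {
    vv <- c(stats::setNames(v, history$param_names), fixed_vec)
    kin_params_from_vector(vv[spec$param_names], spec)
  }
  if (nrow(draws) < 500)
    stop("too few post-burn-in draws (", nrow(draws), " < 500)",
         call. = FALSE)
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  params <- data.frame(
    parameter = history$param_names,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, q, 0.025),
    q97.5 = apply(draws, 2, q, 0.975),
    row.names = NULL
  )
  if (is.null(times))
    times <- seq(0, max(dataset$times), length.out = 50)
  # residual noise scale from the best-fitness draw (compromise proxy)
  best <- which(history$fitness == max(history$fitness),
                arr.ind = TRUE)[1, ]
  best_params <- full(history$samples[best[1], best[2], ])
  best_pred <- integrate_trajectory(spec, best_params, dataset$S0,
                                    dataset$C0, dataset$times)
  rr <- residuals_log10(dataset, best_pred)
  sigma_res <- stats::sd(c(rr$r_subs, rr$r_cells))
  if (!is.finite(sigma_res)) sigma_res <- 0
  idx <- unique(round(seq(1, nrow(draws),
                          length.out = min(n_traj, nrow(draws)))))
  Smat <- matrix(NA_real_, length(idx), length(times))
  Cmat <- matrix(NA_real_, length(idx), length(times))
  for (i in seq_along(idx)) {
    p <- full(draws[idx[i], ])
    tr <- integrate_trajectory(spec, p, dataset$S0, dataset$C0, times)
    if (!tr$penalty) { Smat[i, ] <- tr$S_pred; Cmat[i, ] <- tr$C_pred }
  }
  ok <- stats::complete.cases(Smat)
  Smat <- Smat[ok, , drop = FALSE]; Cmat <- Cmat[ok, , drop = FALSE]
  band <- function(M, p) apply(M, 2, q, p)
  widen <- 10^(1.96 * sigma_res)
  bands <- data.frame(
    time_h = times,
    S_median = band(Smat, 0.5), C_median = band(Cmat, 0.5),
    S_lo = band(Smat, 0.025), S_hi = band(Smat, 0.975),
    C_lo = band(Cmat, 0.025), C_hi = band(Cmat, 0.975)
  )
  bands$S_pred_lo <- bands$S_lo / widen
  bands$S_pred_hi <- bands$S_hi * widen
  bands$C_pred_lo <- bands$C_lo / widen
  bands$C_pred_hi <- bands$C_hi * widen
  structure(
    list(params = params, bands = bands, R = as.numeric(R),
         n_draws = nrow(draws), sigma_res = sigma_res,
         burn_in_fraction = burn_in_fraction, model = spec$name),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary: ", x$model, ", ", x$n_draws, " draws, R = ",
      signif(x$R, 4), ">\n", sep = "")
  print(transform(x$params, mean = signif(mean, 5), sd = signif(sd, 4),
                  q2.5 = signif(q2.5, 5), q97.5 = signif(q97.5, 5)))
  invisible(x)
}

#' Cross-chain mean parameter trace
#'
#' The per-generation mean of each parameter across chains: the standard
#' identifiability diagnostic for ABC runs (a converged, identifiable run
#' shows the trace flattening, typically well before the Gelman-Rubin
#' threshold is crossed).
#'
#' @param history an [abc_sample()] result.
#' @return Matrix `generations x parameters` of cross-chain means.
#' @export
chain_mean_trace <- function(history) {
  stopifnot(inherits(history, "abc_history"))
  tr <- apply(history$samples, c(2, 3), mean)
  colnames(tr) <- history$param_names
  tr
}

#' Stabilization of a mean-parameter trace
#'
#' Maximum over parameters of the relative spread (range over absolute
#' mean) of the trace within its final fraction of generations.
#'
#' @param trace a [chain_mean_trace()] matrix.
#' @param final_fraction window measured, as a fraction of generations.
#' @return Scalar maximum relative drift.
#' @export
trace_drift <- function(trace, final_fraction = 0.2) {
  ng <- nrow(trace)
  win <- trace[max(1, floor(ng * (1 - final_fraction))):ng, , drop = FALSE]
  drifts <- apply(win, 2, function(x)
    (max(x) - min(x)) / max(abs(mean(x)), .Machine$double.eps))
  max(drifts)
}
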