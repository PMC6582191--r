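# Global single-objective stage: self-adaptive differential evolution (saDE)
# locating the best compromise solution (joint fit) and the two extreme
# solutions (per-variable fits).

#' Configuration for the single-objective stage
#'
#' Defaults follow the published run conditions for global single-objective
#' calibration of batch kinetic models: a budget of 500,000 function
#' evaluations, termination when the population's objective range falls
#' below 1e-8 or its parameter range below 1e-2, and five independent
#' seeded repetitions to assess the spread of the estimates.
#'
#' @param max_evals function-evaluation budget per repetition.
#' @param pop_size population size (>= 5).
#' @param obj_range_tol terminate when `max(f) - min(f)` over the
#'   population is below this.
#' @param param_range_tol terminate when every coordinate's population
#'   range (on the internal search scale) is below this.
#' @param seed base seed; repetition `i` uses `seed + i - 1`.
#' @param n_repetitions independent repetitions for [fit_so()].
#' @param lp learning period (generations) of the self-adaptation memory.
#' @return A list of class `so_config`.
#' @export
so_config <- function(max_evals = 500000, pop_size = 50,
                      obj_range_tol = 1e-8, param_range_tol = 1e-2,
                      seed = 1, n_repetitions = 5, lp = 50) {
  stopifnot(pop_size >= 5, obj_range_tol > 0, param_range_tol > 0,
            max_evals >= pop_size, n_repetitions >= 1, lp >= 1)
  structure(list(max_evals = as.integer(max_evals),
                 pop_size = as.integer(pop_size),
                 obj_range_tol = obj_range_tol,
                 param_range_tol = param_range_tol,
                 seed = as.integer(seed),
                 n_repetitions = as.integer(n_repetitions),
                 lp = as.integer(lp)),
            class = "so_config")
}

#' Self-adaptive differential evolution minimizer
#'
#' Minimizes a scalar function over a box by differential evolution with
#' self-adaptation: each individual picks between the exploratory
#' `rand/1/bin` and the exploitative `current-to-best/2/bin` mutation
#' strategies with a probability learned from their recent success rates
#' (over a sliding window of `lp` generations); crossover rates are drawn
#' per strategy from a normal memory `N(CRm, 0.1)` whose mean adapts to the
#' median of recently successful CR values; the scale factor is drawn
#' `F ~ N(0.5, 0.3)` truncated to (0, 2].  Out-of-bounds mutants are
#' reflected back into the box.
#'
#' Termination occurs on the first of: evaluation budget exhausted
#' (`"budget"`), population objective range below `obj_range_tol`
#' (`"obj_range"`), or population parameter range below `param_range_tol`
#' in every coordinate (`"param_range"`).  The run is deterministic given
#' `config$seed`.
#'
#' @param fn scalar objective; must return a finite value (use a large
#'   finite penalty for failures).
#' @param lower,upper numeric bound vectors of equal length.
#' @param config an [so_config()].
#' @return An object of class `sade_result`: `par` (best coordinates),
#'   `value`, `n_evals`, `termination_reason`, `trace` (best objective per
#'   generation), `population` and `pop_values` at termination.
#' @examples
#' sphere <- function(x) sum(x^2)
#' r <- sade_minimize(sphere, rep(-5, 3), rep(5, 3),
#'                    so_config(max_evals = 20000, seed = 1))
#' r$value
#' @export
sade_minimize <- function(fn, lower, upper, config = so_config()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower), all(is.finite(lower)),
            all(is.finite(upper)))
  np <- config$pop_size
  lp <- config$lp
  withr::with_seed(config$seed, {
    pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                               rep(upper, each = np)), np, d)
    fvals <- apply(pop, 1, fn)
    if (any(!is.finite(fvals)))
      stop("objective returned non-finite value on the initial population",
           call. = FALSE)
    n_evals <- np
    p1 <- 0.5                      # probability of strategy 1 (rand/1/bin)
    crm <- c(0.5, 0.5)             # CR memory per strategy
    ns <- list(); nf <- list()     # per-generation success/failure counts
    cr_success <- list()           # successful CR values (strategy, CR)
    best_idx <- which.min(fvals)
    best_x <- pop[best_idx, ]; best_f <- fvals[best_idx]
    trace <- best_f
    reason <- "budget"
    reflect <- function(x) {
      for (k in 1:6) {
        lo <- x < lower; x[lo] <- 2 * lower[lo] - x[lo]
        hi <- x > upper; x[hi] <- 2 * upper[hi] - x[hi]
        if (!any(x < lower | x > upper)) break
      }
      pmin(pmax(x, lower), upper)
    }
    repeat {
      if (max(fvals) - min(fvals) < config$obj_range_tol) {
        reason <- "obj_range"; break
      }
      if (all(apply(pop, 2, function(col) max(col) - min(col)) <
              config$param_range_tol)) {
        reason <- "param_range"; break
      }
      if (n_evals + np > config$max_evals) { reason <- "budget"; break }
      gen_ns <- c(0, 0); gen_nf <- c(0, 0); gen_cr <- list(c(), c())
      trials <- matrix(0, np, d)
      strat <- integer(np); crs <- numeric(np)
      for (i in seq_len(np)) {
        k <- if (stats::runif(1) < p1) 1L else 2L
        strat[i] <- k
        cr <- stats::rnorm(1, crm[k], 0.1)
        cr <- min(max(cr, 0), 1)
        crs[i] <- cr
        Fi <- 0
        while (Fi <= 0 || Fi > 2) Fi <- stats::rnorm(1, 0.5, 0.3)
        idx <- sample.int(np, 5)
        idx <- idx[idx != i][1:4]
        v <- if (k == 1L) {
          pop[idx[1], ] + Fi * (pop[idx[2], ] - pop[idx[3], ])
        } else {
          pop[i, ] + Fi * (best_x - pop[i, ]) +
            Fi * (pop[idx[1], ] - pop[idx[2], ]) +
            Fi * (pop[idx[3], ] - pop[idx[4], ])
        }
        v <- reflect(v)
        jrand <- sample.int(d, 1)
        cross <- stats::runif(d) < cr
        cross[jrand] <- TRUE
        u <- pop[i, ]
        u[cross] <- v[cross]
        trials[i, ] <- u
      }
      fu <- apply(trials, 1, fn)
      n_evals <- n_evals + np
      for (i in seq_len(np)) {
        k <- strat[i]
        if (is.finite(fu[i]) && fu[i] <= fvals[i]) {
          if (fu[i] < fvals[i]) {
            gen_ns[k] <- gen_ns[k] + 1
            gen_cr[[k]] <- c(gen_cr[[k]], crs[i])
          } else {
            gen_nf[k] <- gen_nf[k] + 1
          }
          pop[i, ] <- trials[i, ]
          fvals[i] <- fu[i]
          if (fu[i] < best_f) { best_f <- fu[i]; best_x <- trials[i, ] }
        } else {
          gen_nf[k] <- gen_nf[k] + 1
        }
      }
      ns[[length(ns) + 1]] <- gen_ns
      nf[[length(nf) + 1]] <- gen_nf
      cr_success[[length(cr_success) + 1]] <- gen_cr
      if (length(ns) > lp) {
        ns <- ns[-1]; nf <- nf[-1]; cr_success <- cr_success[-1]
      }
      if (length(ns) == lp) {
        s <- Reduce(`+`, ns); f <- Reduce(`+`, nf)
        r1 <- (s[1] + 0.01) / (s[1] + f[1] + 0.02)
        r2 <- (s[2] + 0.01) / (s[2] + f[2] + 0.02)
        p1 <- min(max(r1 / (r1 + r2), 0.05), 0.95)
        for (k in 1:2) {
          crk <- unlist(lapply(cr_success, `[[`, k))
          if (length(crk) >= 5) crm[k] <- stats::median(crk)
        }
      }
      trace <- c(trace, best_f)
    }
    structure(
      list(par = best_x, value = best_f, n_evals = n_evals,
           termination_reason = reason, trace = trace,
           population = pop, pop_values = fvals),
      class = "sade_result"
    )
  })
}

#' Fit a kinetic model by global single-objective search
#'
#' Runs [sade_minimize()] on the chosen fitting criterion over log10-scaled
#' parameters (the search operates on decades because kinetic parameter
#' magnitudes commonly span 1e-4 to 1e3), repeating `config$n_repetitions`
#' times with consecutive seeds and returning the best repetition together
#' with the per-repetition records used to assess estimate stability.
#'
#' @inheritParams growth_rate
#' @param dataset a [batch_dataset()].
#' @param bounds named list of `c(low, high)` natural-scale bounds per
#'   parameter; defaults to [default_bounds()].
#' @param config an [so_config()].
#' @param component which criterion to minimize: `"total"` (the compromise,
#'   joint objective), `"subs"` or `"cells"` (the extreme solutions).
#' @param fixed named list of parameters held fixed at known values and
#'   excluded from the search (restricted fits).
#' @return An object of class `so_result`: `best_params`
#'   ([kinetic_params()]), `best_objective` ([objective_value()] with the
#'   full decomposition at the optimum), `value` (the minimized component),
#'   `component`, `n_evals`, `termination_reason`, and `repetitions` (a
#'   data.frame of per-repetition parameter estimates, objective values,
#'   seeds and termination reasons).
#' @export
fit_so <- function(spec, dataset, bounds = default_bounds(spec),
                   config = so_config(), component = "total",
                   fixed = list()) {
  spec <- kin_model(spec)
  obj <- .kin_objective(spec, dataset, bounds, component = component,
                        fixed = fixed)
  reps <- vector("list", config$n_repetitions)
  for (i in seq_len(config$n_repetitions)) {
    ci <- config
    ci$seed <- config$seed + i - 1L
    reps[[i]] <- sade_minimize(obj$fn, obj$lower, obj$upper, ci)
  }
  vals <- vapply(reps, `[[`, numeric(1), "value")
  best <- which.min(vals)
  best_params <- obj$to_params(reps[[best]]$par)
  rep_pars <- t(vapply(reps, function(r) 10^r$par,
                       numeric(length(obj$param_names))))
  colnames(rep_pars) <- obj$param_names
  if (ncol(rep_pars) == 1) rep_pars <- as.data.frame(rep_pars)
  rep_df <- data.frame(
    repetition = seq_along(reps),
    seed = config$seed + seq_along(reps) - 1L,
    value = vals,
    n_evals = vapply(reps, `[[`, numeric(1), "n_evals"),
    termination = vapply(reps, `[[`, character(1), "termination_reason"),
    rep_pars, check.names = FALSE
  )
  structure(
    list(best_params = best_params,
         best_objective = obj$eval_obj(reps[[best]]$par),
         value = vals[best], component = component,
         n_evals = sum(rep_df$n_evals),
         termination_reason = reps[[best]]$termination_reason,
         repetitions = rep_df, trace = reps[[best]]$trace,
         seed = config$seed, model = spec$name, fixed = fixed,
         free_params = obj$param_names),
    class = "so_result"
  )
}

#' @export
print.so_result <- function(x, ...) {
  cat("<so_result: ", x$model, ", component = ", x$component, ">\n", sep = "")
  cat("  best value:", format(x$value, digits = 6),
      " (", x$termination_reason, ", ", x$n_evals, " evals total)\n")
  print(x$best_objective)
  print(x$best_params)
  invisible(x)
}

#' Locate the extreme and best-compromise solutions
#'
#' Step 1 of the calibration workflow: three independent seeded global
#' searches minimizing, respectively, the substrate-only error (extreme
#' substrate solution), the cell-only error (extreme cell solution), and
#' the joint total (best compromise solution).  The extreme solutions
#' bracket the ends of the compromise curve that the multi-objective stage
#' traces in full.
#'
#' @inheritParams fit_so
#' @return List with `so_result` elements `extreme_subs`, `extreme_cells`,
#'   `compromise`.
#' @export
fit_extremes_and_compromise <- function(spec, dataset,
                                        bounds = default_bounds(spec),
                                        config = so_config(),
                                        fixed = list()) {
  mk <- function(component, offset) {
    ci <- config
    ci$seed <- config$seed + offset
    fit_so(spec, dataset, bounds, ci, component = component, fixed = fixed)
  }
  list(extreme_subs = mk("subs", 101L),
       extreme_cells = mk("cells", 202L),
       compromise = mk("total", 0L))
}
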