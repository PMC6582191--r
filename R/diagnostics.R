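# Residual-assumption checks and cross-stage reporting.

#' Moment and assumption statistics of a residual vector
#'
#' The fitting objective assumes residuals on the log10 scale are
#' independent, normally distributed with zero mean, and homoscedastic.
#' This helper reports the descriptive evidence for one residual vector:
#' moments (mean, sd, skewness, excess kurtosis), an omnibus normality
#' test (Shapiro-Wilk for n <= 5000, Anderson-Darling beyond), the lag-1
#' autocorrelation (Pearson correlation of consecutive residuals), and a
#' descriptive homoscedasticity ratio (variance of the second half over
#' the first half) -- formal heteroscedasticity test batteries are
#' deliberately not attempted because the handful of timepoints in a batch
#' experiment cannot support them.
#'
#' @param r numeric residual vector.
#' @return List with `n`, `mean`, `sd`, `skewness`, `kurtosis_excess`,
#'   `normality` (list `statistic`, `p_value`, `method`; NULL when n < 4),
#'   `lag1_autocorrelation` (NA, flagged `degenerate`, for constant
#'   residuals), `var_ratio_halves`, `degenerate`.
#' @export
residual_stats <- function(r) {
  r <- as.numeric(r)
  n <- length(r)
  out <- list(n = n, mean = mean(r), sd = stats::sd(r),
              skewness = NA_real_, kurtosis_excess = NA_real_,
              normality = NULL, lag1_autocorrelation = NA_real_,
              var_ratio_halves = NA_real_, degenerate = FALSE)
  if (n < 2) return(out)
  if (out$sd == 0) {
    out$degenerate <- TRUE
    return(out)
  }
  out$skewness <- e1071::skewness(r)
  out$kurtosis_excess <- e1071::kurtosis(r)
  if (n >= 4) {
    nt <- if (n <= 5000) stats::shapiro.test(r) else nortest::ad.test(r)
    out$normality <- list(statistic = unname(nt$statistic),
                          p_value = nt$p.value, method = nt$method)
    h1 <- r[1:floor(n / 2)]
    h2 <- r[(floor(n / 2) + 1):n]
    out$var_ratio_halves <- stats::var(h2) / stats::var(h1)
  }
  if (n >= 3) {
    a <- r[-n]; b <- r[-1]
    if (stats::sd(a) > 0 && stats::sd(b) > 0)
      out$lag1_autocorrelation <- stats::cor(a, b)
  }
  out
}

#' Residual-assumption report for a fitted prediction
#'
#' Computes [residual_stats()] on the log10-scale residuals of each
#' variable (substrate and cells).  With fewer than 4 timepoints only the
#' moments are reported and the tests are skipped with a notice.
#'
#' @inheritParams residuals_log10
#' @return An object of class `residual_report`: lists `subs` and `cells`
#'   of [residual_stats()], the raw residual vectors, and `notice`.
#' @export
residual_report <- function(dataset, prediction) {
  r <- residuals_log10(dataset, prediction)
  if (r$penalty)
    stop("cannot build a residual report from a penalty-marked prediction",
         call. = FALSE)
  notice <- if (length(r$r_subs) < 4)
    "fewer than 4 timepoints: moments only, tests skipped" else NULL
  structure(
    list(subs = residual_stats(r$r_subs), cells = residual_stats(r$r_cells),
         r_subs = r$r_subs, r_cells = r$r_cells, notice = notice),
    class = "residual_report"
  )
}

#' @export
print.residual_report <- function(x, ...) {
  fmt <- function(s, label) {
    cat(sprintf("  %s: n = %d, mean = %.4g, sd = %.4g", label, s$n, s$mean,
                s$sd))
    if (s$degenerate) cat("  [degenerate: constant residuals]")
    cat("\n")
    if (!is.null(s$normality))
      cat(sprintf("    skew %.3g, ex.kurt %.3g, lag-1 acf %.3g, %s p = %.3g, var ratio (2nd/1st half) %.3g\n",
                  s$skewness, s$kurtosis_excess, s$lag1_autocorrelation,
                  s$normality$method, s$normality$p_value,
                  s$var_ratio_halves))
  }
  cat("<residual_report> (log10-scale residuals)\n")
  fmt(x$subs, "substrate")
  fmt(x$cells, "cells")
  if (!is.null(x$notice)) cat(" ", x$notice, "\n")
  invisible(x)
}

#' Consolidated cross-stage workflow report
#'
#' Tabulates, for whichever stages have completed, the best objective and
#' its percent decomposition (recomputed from the stored parameters by
#' re-integrating the model -- never cached from optimizer internals), the
#' relative gap between the single- and multi-objective compromise totals,
#' the ABC convergence status, and the posterior parameter summaries.
#'
#' @inheritParams fit_so
#' @param so result of [fit_extremes_and_compromise()] (or NULL).
#' @param mo result of [fit_mo()] (or NULL).
#' @param abc result of [abc_sample()] (or NULL).
#' @param posterior result of [summarize_posterior()] (or NULL).
#' @return An object of class `workflow_report`: `stages` data.frame
#'   (stage, status, total, pct_subs, pct_cells), `verification`,
#'   `abc_status`, `posterior`, `model`.
#' @export
workflow_report <- function(spec, dataset, so = NULL, mo = NULL, abc = NULL,
                            posterior = NULL) {
  spec <- kin_model(spec)
  reval <- function(params) {
    pred <- integrate_trajectory(spec, params, dataset$S0, dataset$C0,
                                 dataset$times)
    of1(dataset, pred)
  }
  rows <- list()
  add <- function(stage, status, ov = NULL) {
    rows[[length(rows) + 1]] <<- data.frame(
      stage = stage, status = status,
      total = if (is.null(ov)) NA_real_ else ov$total,
      pct_subs = if (is.null(ov)) NA_real_ else ov$pct_subs,
      pct_cells = if (is.null(ov)) NA_real_ else ov$pct_cells
    )
  }
  if (!is.null(so)) {
    add("so_extreme_subs", "done", reval(so$extreme_subs$best_params))
    add("so_extreme_cells", "done", reval(so$extreme_cells$best_params))
    add("so_compromise", "done", reval(so$compromise$best_params))
  } else add("so_compromise", "not run")
  if (!is.null(mo)) {
    add("mo_compromise", "done", reval(mo$compromise_params))
  } else add("mo_compromise", "not run")
  verification <- if (!is.null(so) && !is.null(mo))
    verify_against_so(mo$compromise$obj, so$compromise$best_objective)
  else NULL
  abc_status <- NULL
  if (!is.null(abc)) {
    Rfin <- utils::tail(abc$R_trace$R, 1)
    abc_status <- list(
      final_R = Rfin,
      converged = is.finite(Rfin) && Rfin < 1.2,
      acceptance_rate = abc$acceptance_rate,
      n_generations = abc$config$n_generations,
      n_chains = abc$config$n_chains
    )
    ng <- dim(abc$samples)[2]
    keep <- (floor(ng / 2) + 1):ng
    draws <- do.call(rbind, lapply(seq_len(dim(abc$samples)[1]),
      function(ci) abc$samples[ci, keep, , drop = TRUE]))
    draws <- draws[unique(round(seq(1, nrow(draws), length.out = 200))), ,
                   drop = FALSE]
    fixed_vec <- unlist(abc$fixed)
    mean_stats <- colMeans(t(apply(draws, 1, function(v) {
      vv <- c(stats::setNames(v, abc$param_names), fixed_vec)
      p <- kin_params_from_vector(vv[spec$param_names], spec)
      of_mo(dataset, integrate_trajectory(spec, p, dataset$S0,
                                          dataset$C0, dataset$times))
    })))
    add("abc_posterior_mean_stats",
        if (abc_status$converged) "done" else "done (R >= 1.2)",
        objective_value(mean_stats[1], mean_stats[2]))
  } else add("abc", "not run")
  structure(
    list(stages = do.call(rbind, rows), verification = verification,
         abc_status = abc_status, posterior = posterior,
         model = spec$name),
    class = "workflow_report"
  )
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report: ", x$model, ">\n", sep = "")
  df <- x$stages
  df$total <- signif(df$total, 5)
  df$pct_subs <- round(df$pct_subs, 1)
  df$pct_cells <- round(df$pct_cells, 1)
  print(df, row.names = FALSE)
  if (!is.null(x$verification)) print(x$verification)
  if (!is.null(x$abc_status))
    cat(sprintf("  ABC: R = %.4f (%s), acceptance %.3f\n",
                x$abc_status$final_R,
                if (x$abc_status$converged) "converged" else "NOT converged",
                x$abc_status$acceptance_rate))
  if (!is.null(x$posterior)) print(x$posterior)
  invisible(x)
}
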