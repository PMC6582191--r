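# Orchestration of the three-step calibration pipeline.

#' Workflow configuration
#'
#' Bundles the model choice, dataset, bounds and stage configurations.
#' Stage seeds are derived deterministically from the master seed
#' (`seed + 1` for the single-objective stage, `+ 2` for the
#' multi-objective stage, `+ 3` for ABC) so a rerun with the same master
#' seed reproduces every artifact bit for bit.
#'
#' @param model model id (1--8) or name.
#' @param dataset a [batch_dataset()] or a CSV path in the package dialect.
#' @param bounds named list of natural-scale parameter bounds; default
#'   [default_bounds()].
#' @param so an [so_config()].
#' @param mo an [mo_config()].
#' @param abc an [abc_config()].
#' @param seed master seed.
#' @param skip_mo omit the multi-objective stage and target ABC at the
#'   single-objective compromise instead (a documented reduced-cost mode).
#' @param outdir optional artifact directory (written when non-NULL).
#' @param epsilons optional explicit ABC tolerances (default:
#'   `max(0.05 * S_j, 0.01)` per statistic).
#' @param fixed named list of parameters held at known values in every
#'   stage (restricted fits).
#' @return A list of class `workflow_config`.
#' @export
workflow_config <- function(model, dataset, bounds = NULL,
                            so = so_config(), mo = mo_config(),
                            abc = abc_config(), seed = 1,
                            skip_mo = FALSE, outdir = NULL,
                            epsilons = NULL, fixed = list()) {
  spec <- kin_model(model)
  if (is.character(dataset)) dataset <- read_batch_dataset(dataset)
  stopifnot(inherits(dataset, "batch_dataset"))
  if (is.null(bounds)) bounds <- default_bounds(spec)
  seed <- as.integer(seed)
  so$seed <- seed + 1L
  mo$seed <- seed + 2L
  abc$seed <- seed + 3L
  structure(list(spec = spec, dataset = dataset, bounds = bounds,
                 so = so, mo = mo, abc = abc, seed = seed,
                 skip_mo = isTRUE(skip_mo), outdir = outdir,
                 epsilons = epsilons, fixed = fixed),
            class = "workflow_config")
}

#' Run the full three-step calibration workflow
#'
#' Executes, in order: (1) the global single-objective stage locating the
#' two extreme solutions and the best compromise solution; (2) the global
#' multi-objective stage evolving the Pareto front and selecting its
#' compromise member, verified against stage 1 (a warning is emitted if
#' the totals disagree beyond the verification tolerance); (3) the ABC
#' stage targeting the compromise per-variable error sums, followed by
#' posterior summarization, residual diagnostics of the compromise fit,
#' and a consolidated report.  With `skip_mo = TRUE` the ABC target falls
#' back to the single-objective compromise statistics, which reduces the
#' computational burden at some loss of redundancy.
#'
#' A stage failure halts the pipeline with a stage-tagged error; artifacts
#' of completed stages are preserved in the returned condition and, when
#' `outdir` is set, on disk.
#'
#' @param config a [workflow_config()].
#' @return Invisibly, a list of artifacts: `so`, `mo`, `verification`,
#'   `target`, `abc`, `posterior`, `residuals`, `report`, `config_hash`,
#'   `seed`.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  spec <- config$spec
  dataset <- config$dataset
  config_hash <- rlang::hash(list(
    model = spec$id, bounds = config$bounds, so = unclass(config$so),
    mo = unclass(config$mo), abc = unclass(config$abc),
    seed = config$seed, skip_mo = config$skip_mo, fixed = config$fixed,
    dataset = dataset[c("times", "S_obs", "C_obs", "S0", "C0")]))
  arts <- list(config_hash = config_hash, seed = config$seed)
  persist <- function() {
    if (!is.null(config$outdir)) write_artifacts(arts, config$outdir)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      stop("workflow stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  arts$so <- stage("fit-so", fit_extremes_and_compromise(
    spec, dataset, config$bounds, config$so, fixed = config$fixed))
  if (!config$skip_mo) {
    arts$mo <- stage("fit-mo", fit_mo(spec, dataset, config$bounds,
                                      config$mo, fixed = config$fixed))
    arts$verification <- verify_against_so(
      arts$mo$compromise$obj, arts$so$compromise$best_objective)
    if (!arts$verification$pass)
      warning("single- and multi-objective compromise totals disagree ",
              "(relative gap ", signif(arts$verification$gap, 3),
              "); the ABC target may not reflect the global compromise",
              call. = FALSE)
    target_stats <- arts$mo$compromise$obj
  } else {
    v <- arts$so$compromise$best_objective
    target_stats <- c(v$ssr_subs, v$ssr_cells)
  }
  arts$target <- if (is.null(config$epsilons)) abc_target(target_stats)
                 else abc_target(target_stats, config$epsilons)
  arts$abc <- stage("abc", abc_sample(spec, dataset, arts$target,
                                      config$abc, config$bounds,
                                      fixed = config$fixed))
  arts$posterior <- stage("posterior", summarize_posterior(
    arts$abc, spec, dataset, check_convergence = FALSE))
  best_pred <- integrate_trajectory(
    spec, arts$so$compromise$best_params, dataset$S0, dataset$C0,
    dataset$times)
  arts$residuals <- residual_report(dataset, best_pred)
  arts$report <- workflow_report(spec, dataset, so = arts$so, mo = arts$mo,
                                 abc = arts$abc,
                                 posterior = arts$posterior)
  persist()
  invisible(arts)
}
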