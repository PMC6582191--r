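# Dataset CSV dialect and result serialization.
#
# Dataset files are plain CSV with header `time_h,S_mean,S_sd,C_mean,C_sd`;
# missing standard deviations are written as empty fields; `#`-prefixed
# comment lines carry the initial conditions and units, e.g.
#   # S0: 50
#   # C0: 0.05
#   # units: mg/L, OD600

#' Read a batch dataset from CSV
#'
#' Parses the package's dataset dialect and validates it (sorted times
#' starting at 0, strictly positive observations -- the log10 objective
#' cannot accept zeros).  Missing standard-deviation fields are parsed as
#' absent, not zero.
#'
#' @param path CSV file path.
#' @return A [batch_dataset()].
#' @export
read_batch_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), comments, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^\\s*#\\s*", key, "\\s*:\\s*"), "", hit[1])
  }
  df <- utils::read.csv(text = lines[!grepl("^\\s*#", lines)],
                        stringsAsFactors = FALSE)
  need <- c("time_h", "S_mean", "C_mean")
  if (!all(need %in% names(df)))
    stop("dataset must have columns time_h, S_mean, C_mean ",
         "(optionally S_sd, C_sd)", call. = FALSE)
  bad <- which(!is.finite(df$S_mean) | df$S_mean <= 0 |
               !is.finite(df$C_mean) | df$C_mean <= 0)
  if (length(bad))
    stop("non-positive observation at data row ", bad[1],
         " of ", path, " (log10 objective requires positive values)",
         call. = FALSE)
  if (is.unsorted(df$time_h, strictly = TRUE))
    stop("time_h must be strictly increasing in ", path, call. = FALSE)
  sd_col <- function(nm) {
    if (!nm %in% names(df)) return(NULL)
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (all(is.na(v))) NULL else v
  }
  S0 <- get_meta("S0"); C0 <- get_meta("C0")
  batch_dataset(
    times = df$time_h, S_obs = df$S_mean, C_obs = df$C_mean,
    S_sd = sd_col("S_sd"), C_sd = sd_col("C_sd"),
    S0 = if (is.null(S0)) df$S_mean[1] else as.numeric(S0),
    C0 = if (is.null(C0)) df$C_mean[1] else as.numeric(C0),
    meta = list(path = path, units = get_meta("units"))
  )
}

#' Write a batch dataset to CSV
#'
#' @param dataset a [batch_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_batch_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "batch_dataset"))
  num <- function(x) formatC(x, format = "g", digits = 17)
  blank_na <- function(x, n) {
    if (is.null(x)) rep("", n) else ifelse(is.na(x), "", num(x))
  }
  n <- length(dataset$times)
  lines <- c(
    paste0("# S0: ", num(dataset$S0)),
    paste0("# C0: ", num(dataset$C0)),
    paste0("# units: ",
           if (!is.null(dataset$meta$units)) dataset$meta$units
           else "mg/L, measurement units"),
    "time_h,S_mean,S_sd,C_mean,C_sd",
    paste(num(dataset$times), num(dataset$S_obs),
          blank_na(dataset$S_sd, n), num(dataset$C_obs),
          blank_na(dataset$C_sd, n), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

# Serialize stage results to JSON (numbers at full precision).
.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.obj_as_list <- function(ov) {
  list(ssr_subs = ov$ssr_subs, ssr_cells = ov$ssr_cells, total = ov$total,
       pct_subs = ov$pct_subs, pct_cells = ov$pct_cells)
}

#' Write workflow artifacts to a directory
#'
#' Serializes stage results as JSON (parameters, objective decompositions,
#' per-repetition records, seeds) and the Pareto front and ABC samples as
#' CSV.  Every artifact embeds the workflow config hash and master seed so
#' that [read_artifacts()]/`kinfit report` can refuse mixed-provenance
#' directories.
#'
#' @param artifacts list as produced by [run_workflow()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_artifacts <- function(artifacts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = artifacts$config_hash,
                seed = artifacts$seed, schema_version = "1.0")
  so <- artifacts$so
  if (!is.null(so)) {
    .write_json(c(stamp, list(
      stages = lapply(so, function(r) list(
        component = r$component,
        best_params = as.list(kin_params_vector(r$best_params)),
        best_objective = .obj_as_list(r$best_objective),
        termination = r$termination_reason, n_evals = r$n_evals,
        repetitions = r$repetitions))
    )), file.path(dir, "so_result.json"))
  }
  mo <- artifacts$mo
  if (!is.null(mo)) {
    .write_json(c(stamp, list(
      compromise_params = as.list(kin_params_vector(mo$compromise_params)),
      compromise_objective = .obj_as_list(mo$compromise_objective),
      n_members = nrow(mo$members$objs),
      verification = if (is.null(artifacts$verification)) NULL else
        unclass(artifacts$verification)
    )), file.path(dir, "mo_result.json"))
    front_df <- data.frame(ssr_subs = mo$members$objs[, 1],
                           ssr_cells = mo$members$objs[, 2],
                           mo$members$pars, check.names = FALSE)
    utils::write.csv(front_df, file.path(dir, "pareto_front.csv"),
                     row.names = FALSE)
  }
  abc <- artifacts$abc
  if (!is.null(abc)) {
    .write_json(c(stamp, list(
      target = unclass(abc$target),
      acceptance_rate = abc$acceptance_rate,
      final_R = utils::tail(abc$R_trace$R, 1),
      n_chains = abc$config$n_chains,
      n_generations = abc$config$n_generations
    )), file.path(dir, "abc_result.json"))
    utils::write.csv(abc$R_trace, file.path(dir, "abc_r_trace.csv"),
                     row.names = FALSE)
    ng <- dim(abc$samples)[2]
    thin <- unique(round(seq(1, ng, length.out = min(ng, 2000))))
    rows <- do.call(rbind, lapply(seq_len(dim(abc$samples)[1]),
      function(ci) data.frame(chain = ci, generation = thin,
                              abc$samples[ci, thin, , drop = TRUE],
                              OF2 = abc$fitness[ci, thin],
                              check.names = FALSE)))
    utils::write.csv(rows, file.path(dir, "abc_samples.csv"),
                     row.names = FALSE)
  }
  if (!is.null(artifacts$posterior)) {
    .write_json(c(stamp, list(
      R = artifacts$posterior$R, n_draws = artifacts$posterior$n_draws,
      sigma_res = artifacts$posterior$sigma_res,
      params = artifacts$posterior$params
    )), file.path(dir, "posterior_summary.json"))
    utils::write.csv(artifacts$posterior$bands,
                     file.path(dir, "posterior_bands.csv"),
                     row.names = FALSE)
  }
  if (!is.null(artifacts$report)) {
    .write_json(c(stamp, list(stages = artifacts$report$stages)),
                file.path(dir, "report.json"))
    txt <- utils::capture.output(print(artifacts$report))
    writeLines(txt, file.path(dir, "report.txt"))
  }
  .write_json(stamp, file.path(dir, "run_meta.json"))
  invisible(dir)
}

#' Read back the JSON artifacts of a workflow directory
#'
#' Refuses directories whose artifacts carry mixed config hashes.
#'
#' @param dir artifact directory.
#' @return Named list of parsed JSON artifacts.
#' @export
read_artifacts <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no JSON artifacts in ", dir, call. = FALSE)
  arts <- lapply(files, jsonlite::read_json, simplifyVector = TRUE)
  names(arts) <- sub("\\.json$", "", basename(files))
  hashes <- unique(unlist(lapply(arts, `[[`, "config_hash")))
  if (length(hashes) > 1)
    stop("artifact directory ", dir, " mixes config hashes: ",
         paste(hashes, collapse = ", "), call. = FALSE)
  arts
}
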