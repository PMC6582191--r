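test_that("dataset CSV writing and reading round-trips losslessly", {
  ds <- noisy_ds("Moser", moser_truth(), seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_batch_dataset(ds, path)
  back <- read_batch_dataset(path)
  expect_equal(back$times, ds$times)
  expect_equal(back$S_obs, ds$S_obs)
  expect_equal(back$C_obs, ds$C_obs)
  expect_equal(back$S_sd, ds$S_sd)
  expect_equal(back$C_sd, ds$C_sd)
  expect_equal(back$S0, ds$S0)
  expect_equal(back$C0, ds$C0)
})

test_that("missing standard deviations are parsed as absent, not zero", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# S0: 50", "# C0: 0.1",
               "time_h,S_mean,S_sd,C_mean,C_sd",
               "0,50,,0.1,", "24,20,,1,", "48,5,,2,"), path)
  ds <- read_batch_dataset(path)
  expect_null(ds$S_sd)
  expect_null(ds$C_sd)
})

test_that("invalid datasets are rejected with the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,S_mean,S_sd,C_mean,C_sd",
               "0,50,,0.1,", "24,20,,0,", "48,5,,2,"), path)
  expect_error(read_batch_dataset(path), "row 2")
  writeLines(c("time_h,S_mean,S_sd,C_mean,C_sd",
               "0,50,,0.1,", "48,20,,1,", "24,5,,2,"), path)
  expect_error(read_batch_dataset(path), "increasing")
})

test_that("stage seeds derive deterministically from the master seed", {
  ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
  cfg <- workflow_config("Monod", ds, seed = 100)
  expect_identical(cfg$so$seed, 101L)
  expect_identical(cfg$mo$seed, 102L)
  expect_identical(cfg$abc$seed, 103L)
})

# desk-scale end-to-end run shared by the tests below
wf_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
      outdir <- file.path(tempdir(), "kinfit-wf-test")
      cfg <- workflow_config(
        "Monod", ds, bounds = restricted_bounds(),
        so = so_config(max_evals = 5000, n_repetitions = 1),
        mo = mo_config(n_generations = 150, pop_size = 40),
        abc = abc_config(n_chains = 6, n_generations = 1500,
                         monitor_interval = 250),
        seed = 50, outdir = outdir, fixed = monod_fixed_yb())
      # near-zero totals make the SO/MO relative gap ill-conditioned, so
      # the verification warning is expected here
      val <<- list(cfg = cfg, arts = suppressWarnings(run_workflow(cfg)))
    }
    val
  }
})

test_that("the end-to-end workflow recovers the truth on zero-noise data", {
  fx <- wf_fixture()
  arts <- fx$arts
  expect_lt(arts$so$compromise$best_objective$total, 1e-6)
  # both frameworks collapse to the same near-zero compromise; the
  # *relative* gap is ill-conditioned at zero, so compare absolutely
  expect_lt(arts$verification$total_mo, 1e-3)
  expect_lt(abs(arts$verification$total_mo - arts$verification$total_so),
            1e-3)
  truth <- kin_params_vector(monod_truth())
  for (pn in c("mu_max", "Ks")) {
    est <- kin_params_vector(arts$so$compromise$best_params)[[pn]]
    expect_lt(abs(est - truth[[pn]]) / truth[[pn]], 0.01)
    # the posterior interval covers the truth
    row <- arts$posterior$params[arts$posterior$params$parameter == pn, ]
    expect_gte(truth[[pn]], row$q2.5)
    expect_lte(truth[[pn]], row$q97.5)
  }
  expect_true(all(c("so_result.json", "mo_result.json", "abc_result.json",
                    "pareto_front.csv", "report.json", "report.txt") %in%
                    list.files(fx$cfg$outdir)))
})

test_that("artifacts embed a consistent config hash and reload cleanly", {
  fx <- wf_fixture()
  arts <- read_artifacts(fx$cfg$outdir)
  hashes <- unique(unlist(lapply(arts, `[[`, "config_hash")))
  expect_identical(hashes, fx$arts$config_hash)
  # tampering with one artifact's hash must be refused
  bad_dir <- file.path(tempdir(), "kinfit-wf-bad")
  dir.create(bad_dir, showWarnings = FALSE)
  file.copy(list.files(fx$cfg$outdir, full.names = TRUE), bad_dir,
            overwrite = TRUE)
  meta <- jsonlite::read_json(file.path(bad_dir, "run_meta.json"))
  meta$config_hash <- "deadbeef"
  jsonlite::write_json(meta, file.path(bad_dir, "run_meta.json"),
                       auto_unbox = TRUE)
  expect_error(read_artifacts(bad_dir), "mixes config hashes")
})

test_that("skip_mo falls back to the single-objective compromise target", {
  ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
  cfg <- workflow_config(
    "Monod", ds, bounds = restricted_bounds(),
    so = so_config(max_evals = 3000, n_repetitions = 1),
    abc = abc_config(n_chains = 4, n_generations = 1200,
                     monitor_interval = 300),
    seed = 60, skip_mo = TRUE, fixed = monod_fixed_yb())
  arts <- run_workflow(cfg)
  v <- arts$so$compromise$best_objective
  expect_identical(arts$target$observed_stats, c(v$ssr_subs, v$ssr_cells))
  expect_null(arts$mo)
})

test_that("rerunning with the same master seed reproduces the artifacts", {
  ds <- zero_noise_ds("Monod", monod_truth(), n_timepoints = 8)
  mk <- function() {
    cfg <- workflow_config(
      "Monod", ds, bounds = restricted_bounds(),
      so = so_config(max_evals = 2000, n_repetitions = 1),
      abc = abc_config(n_chains = 4, n_generations = 1200,
                       monitor_interval = 300),
      seed = 70, skip_mo = TRUE, fixed = monod_fixed_yb())
    run_workflow(cfg)
  }
  a1 <- mk(); a2 <- mk()
  expect_identical(a1$config_hash, a2$config_hash)
  expect_identical(kin_params_vector(a1$so$compromise$best_params),
                   kin_params_vector(a2$so$compromise$best_params))
  expect_identical(a1$abc$samples, a2$abc$samples)
})
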