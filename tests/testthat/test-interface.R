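test_that("a written trial reads back bit-identically", {
  st <- synthesize_trial(toy_targets(), subject = "S001", condition = "pre")
  base <- file.path(withr::local_tempdir(), "S001_pre")
  write_trial(st$trial, base)
  back <- read_trial(base)
  expect_identical(back$subject, "S001")
  expect_identical(back$condition, "pre")
  expect_identical(back$mass, st$trial$mass)
  expect_identical(back$grf$time, st$trial$grf$time)
  expect_identical(back$grf$fz, st$trial$grf$fz)
  expect_identical(back$grf$rate, st$trial$grf$rate)
  expect_identical(back$kin$time, st$trial$kin$time)
  expect_identical(back$kin$angle, st$trial$kin$angle)
  expect_identical(back$kin$moment, st$trial$kin$moment)
  # and the pipeline result is therefore identical too
  expect_identical(extract_discrete_variables(back),
                   extract_discrete_variables(st$trial))
})

test_that("malformed trial files fail with precise messages", {
  dir <- withr::local_tempdir()
  st <- synthesize_trial(toy_targets(), subject = "S001", condition = "pre")
  base <- file.path(dir, "t")
  write_trial(st$trial, base)

  expect_error(read_trial(file.path(dir, "nope")), "not found")

  corrupt <- function(mutate) {
    lines <- readLines(paste0(base, "_grf.csv"))
    writeLines(mutate(lines), paste0(base, "_grf.csv"))
  }
  orig <- readLines(paste0(base, "_grf.csv"))

  # rename a required column
  corrupt(function(l) {
    i <- grep("^time_s", l)[1]
    l[i] <- sub("grf_z_N", "force", l[i])
    l
  })
  expect_error(read_trial(base), "missing column")
  writeLines(orig, paste0(base, "_grf.csv"))

  # NaN cell, reported with its data row number
  corrupt(function(l) {
    i <- grep("time_s", l)[1] + 3L
    l[i] <- sub(",.*$", ",NaN", l[i])
    l
  })
  expect_error(read_trial(base), "at data row 3")
  writeLines(orig, paste0(base, "_grf.csv"))

  # shuffled time, reported at the first offending row
  corrupt(function(l) {
    i <- grep("time_s", l)[1]
    c(l[seq_len(i)], l[c(i + 2L, i + 1L)], l[-seq_len(i + 2L)])
  })
  expect_error(read_trial(base), "strictly increasing")
  writeLines(orig, paste0(base, "_grf.csv"))

  # non-uniform sampling: nudge one timestamp but keep it monotone
  corrupt(function(l) {
    i <- grep("^time_s", l)[1] + 2L
    t2 <- as.numeric(sub(",.*$", "", l[i]))
    l[i] <- sub("^[^,]*", sprintf("%.17g", t2 - 2e-4), l[i])
    l
  })
  expect_error(read_trial(base), "uniformly sampled")
})

test_that("cohort write/read round-trips trials and ground truth", {
  coh <- generate_cohort(tiny_spec(n = 3, seed = 8))
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_identical(nrow(man), 6L)
  expect_true(file.exists(file.path(dir, "cohort_manifest.csv")))
  back <- read_cohort(dir)
  expect_identical(length(back$trials), 6L)
  expect_equal(back$ground_truth$value, coh$ground_truth$value,
               tolerance = 1e-15)
  tab_a <- cohort_discrete_table(coh$trials)
  tab_b <- cohort_discrete_table(back$trials)
  expect_equal(tab_a, tab_b, tolerance = 1e-15)
})

test_that("run_all produces the full artifact set with right cardinalities", {
  dir <- withr::local_tempdir()
  cfg <- run_config(population = tiny_spec(n = 12, seed = 7),
                    n_perm = 200L, seed = 7L, out_dir = dir)
  res <- run_all(cfg)
  expected <- c(
    "ground_truth.csv", "discrete_variables.csv", "plsr_q2_trace.csv",
    "plsr_coefficients.csv", "plsr_predictions.csv", "plsr_summary.csv",
    "predictor_stats.csv", "perturbation_grid.csv",
    "sensitivity_predictions.csv", "direction_summary.csv",
    "group_comparison.csv", "waveform_tests.csv", "manifest.csv"
  )
  expect_true(all(file.exists(file.path(dir, expected))))
  expect_false(file.exists(file.path(dir, "FAILED")))

  expect_identical(nrow(res$discrete), 24L)
  expect_identical(dim(res$grid), c(13L, 4L))
  expect_identical(nrow(res$directions), 24L) # 4 predictors x 6 responses
  expect_identical(nrow(res$waveforms), 9L * 101L)
  n_vars <- sum(vapply(res$discrete, is.numeric, logical(1)))
  expect_identical(nrow(res$comparison), n_vars)
  expect_true(all(c("ankle_pos_work", "stance_duration") %in%
                    res$comparison$variable))

  # determinism: a rerun into a fresh directory reproduces everything
  dir2 <- withr::local_tempdir()
  cfg2 <- run_config(population = tiny_spec(n = 12, seed = 7),
                     n_perm = 200L, seed = 7L, out_dir = dir2)
  res2 <- run_all(cfg2)
  expect_equal(res$discrete, res2$discrete, tolerance = 1e-15)
  expect_equal(res$comparison$t, res2$comparison$t, tolerance = 1e-15)
  h <- function(r) r$manifest$value[r$manifest$key == "config_hash"]
  expect_identical(h(res), h(res2))
})

test_that("an undersized cohort fails at the model stage, by name", {
  dir <- withr::local_tempdir()
  # 4 subjects = 8 trials: enough to simulate, too few for the model fit
  cfg <- run_config(population = tiny_spec(n = 4, seed = 2),
                    n_perm = 200L, out_dir = dir)
  expect_error(run_all(cfg), "stage 'plsr' failed")
  expect_true(file.exists(file.path(dir, "FAILED")))
  marker <- readLines(file.path(dir, "FAILED"))
  expect_match(marker, "plsr")
})

test_that("the command-line front end simulates a readable cohort", {
  cli <- system.file("cli", "gaitwork.R", package = "gaitwork")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- file.path(withr::local_tempdir(), "cohort")
  status <- system2(rscript,
                    c(cli, "simulate", "--n-subjects", "2", "--seed", "5",
                      "--out", out, "--log-level", "quiet"),
                    stdout = TRUE, stderr = TRUE)
  expect_identical(attr(status, "status"), NULL)
  expect_true(file.exists(file.path(out, "cohort_manifest.csv")))
  coh <- read_cohort(out)
  expect_identical(length(coh$trials), 4L)

  bad <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = TRUE, stderr = TRUE)
  )
  expect_identical(attr(bad, "status"), 2L)
})
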