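#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its conventional default:
#' 15 Hz kinematic and 50 Hz kinetic low-pass cutoffs, net filter order 4,
#' 30 N stance threshold, 101 normalization points, Q-squared threshold
#' 0.0975, 80% training fraction, the 13-level perturbation grid, and the
#' permutation count of the waveform test. All randomness flows from
#' explicit seeds.
#'
#' @param population A [population_spec()] describing the cohort to simulate.
#' @param cutoff_kinematic,cutoff_kinetic Low-pass cutoffs in Hz.
#' @param filter_order Net Butterworth order.
#' @param grf_threshold Stance threshold in N.
#' @param n_points Time-normalization length.
#' @param q2_threshold Component-selection threshold.
#' @param train_fraction Training-set fraction for the PLS evaluation.
#' @param perturb_levels Range fractions of the perturbation grid.
#' @param grid_mode `"formula"` or `"printed-compat"`.
#' @param n_perm Permutations for the waveform test.
#' @param alpha Significance level.
#' @param seed Master seed for the split and the permutations.
#' @param out_dir Output directory for [run_all()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(population = population_spec(),
                       cutoff_kinematic = 15,
                       cutoff_kinetic = 50,
                       filter_order = 4L,
                       grf_threshold = 30,
                       n_points = 101L,
                       q2_threshold = 0.0975,
                       train_fraction = 0.8,
                       perturb_levels = c(-0.1, seq(0, 1, by = 0.1), 2),
                       grid_mode = "formula",
                       n_perm = 500L,
                       alpha = 0.05,
                       seed = 1L,
                       out_dir = tempfile("gaitwork_run_")) {
  cfg <- structure(
    list(population = population,
         cutoff_kinematic = cutoff_kinematic,
         cutoff_kinetic = cutoff_kinetic,
         filter_order = as.integer(filter_order),
         grf_threshold = grf_threshold,
         n_points = as.integer(n_points),
         q2_threshold = q2_threshold,
         train_fraction = train_fraction,
         perturb_levels = perturb_levels,
         grid_mode = grid_mode,
         n_perm = as.integer(n_perm),
         alpha = alpha,
         seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
  validate_population_spec(cfg$population)
  cfg
}

#' Time-normalized stance curves for one signal across a cohort
#'
#' Conditions each trial (filtering, stance detection, cropping), derives the
#' requested signal and normalizes it to `n_points` samples over the stance.
#'
#' @param trials List of `trial_time_series` / `synthetic_trial`.
#' @param signal One of `"angle"`, `"moment"`, `"power"`.
#' @param joint One of `"ankle"`, `"knee"`, `"hip"`.
#' @param config A [run_config()].
#' @return Matrix (trials x `n_points`) with subject/condition in
#'   `attr(, "meta")`.
#' @export
stance_curves <- function(trials, signal = c("angle", "moment", "power"),
                          joint = c("ankle", "knee", "hip"),
                          config = run_config()) {
  signal <- match.arg(signal)
  joint <- match.arg(joint)
  rows <- lapply(trials, function(st) {
    tr <- if (inherits(st, "synthetic_trial")) st$trial else st
    seg <- detect_stance(tr$grf$fz, tr$grf$rate,
                         threshold = config$grf_threshold)
    k0 <- which.min(abs(tr$kin$time - tr$grf$time[seg$start]))
    k1 <- which.min(abs(tr$kin$time - tr$grf$time[seg$end]))
    rate <- tr$kin$rate
    ang <- butterworth_lowpass(tr$kin$angle[, joint], rate,
                               config$cutoff_kinematic,
                               order = config$filter_order)
    mom <- butterworth_lowpass(tr$kin$moment[, joint], rate,
                               config$cutoff_kinetic,
                               order = config$filter_order)
    ang <- ang[k0:k1]
    mom <- mom[k0:k1]
    x <- switch(signal,
                angle = ang,
                moment = mom,
                power = joint_power(mom, angular_velocity(ang, rate)))
    list(curve = time_normalize(x, config$n_points)$values,
         subject = tr$subject, condition = tr$condition)
  })
  m <- do.call(rbind, lapply(rows, `[[`, "curve"))
  attr(m, "meta") <- data.frame(
    subject = vapply(rows, `[[`, "", "subject"),
    condition = vapply(rows, `[[`, "", "condition"),
    stringsAsFactors = FALSE
  )
  m
}

#' Run the whole pipeline
#'
#' Simulate (or ingest) a paired cohort, condition the signals and extract
#' the discrete energetics table, fit and evaluate the PLS model with
#' cross-validity component selection, build the perturbation sensitivity
#' analysis, and compute the paired group statistics (discrete variables and
#' permutation waveform tests). Every artifact is written as CSV under
#' `config$out_dir` together with a manifest recording the configuration
#' hash and seeds. Any stage failure aborts with the stage name and leaves a
#' `FAILED` marker next to the partial outputs.
#'
#' @param config A [run_config()].
#' @param trials Optional list of `trial_time_series` to analyse instead of
#'   simulating from `config$population`.
#' @return Invisibly, a list with `discrete`, `comparison`, `evaluation`,
#'   `stats` (predictor stats), `grid`, `curves`, `directions`,
#'   `waveforms`, `manifest`.
#' @export
run_all <- function(config = run_config(), trials = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, " -- ",
                        conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ground_truth <- NULL
  trials <- stage("simulate", {
    if (is.null(trials)) {
      cohort <- generate_cohort(config$population)
      ground_truth <- cohort$ground_truth
      write_csv_exact(ground_truth,
                      file.path(config$out_dir, "ground_truth.csv"),
                      comments = "# synthetic ground truth (tidy)")
      cohort$trials
    } else {
      trials
    }
  })

  discrete <- stage("energetics", {
    tab <- cohort_discrete_table(
      trials, filter = TRUE,
      cutoff_kinematic = config$cutoff_kinematic,
      cutoff_kinetic = config$cutoff_kinetic,
      filter_order = config$filter_order,
      threshold = config$grf_threshold
    )
    write_csv_exact(tab, file.path(config$out_dir, "discrete_variables.csv"),
                    comments = paste0("# per-trial discrete variables; ",
                                      "angles deg, moments Nm/kg, powers ",
                                      "W/kg, works J/kg"))
    tab
  })

  evaluation <- stage("plsr", {
    ds <- build_plsr_dataset(discrete)
    ev <- train_test_evaluate(ds$X, ds$Y,
                              train_fraction = config$train_fraction,
                              seed = config$seed,
                              threshold = config$q2_threshold)
    write_csv_exact(ev$model$selection,
                    file.path(config$out_dir, "plsr_q2_trace.csv"),
                    comments = "# PRESS/SS/Q2 per candidate component")
    cf <- coef(ev$model)
    coefs <- data.frame(predictor = rownames(cf$slopes),
                        cf$slopes, row.names = NULL)
    write_csv_exact(coefs,
                    file.path(config$out_dir, "plsr_coefficients.csv"),
                    comments = "# original-unit slopes, one row per predictor")
    pred <- predict(ev$model, ds$X)
    preds <- data.frame(id = ds$ids, pred, row.names = NULL)
    write_csv_exact(preds,
                    file.path(config$out_dir, "plsr_predictions.csv"),
                    comments = "# in-sample predicted joint works, J/kg")
    summ <- data.frame(
      key = c("n_components", "train_accuracy_pct", "test_accuracy_pct",
              "n_train", "n_test"),
      value = c(ev$model$ncomp, ev$train_accuracy, ev$test_accuracy,
                length(ev$train_rows), length(ev$test_rows))
    )
    write_csv_exact(summ, file.path(config$out_dir, "plsr_summary.csv"),
                    comments = "# accuracy = 100 * (1 - RMSE / range)")
    ev
  })

  sens <- stage("sensitivity", {
    ds <- build_plsr_dataset(discrete)
    st <- predictor_stats(ds$X)
    grid <- build_grid(st, levels = config$perturb_levels,
                       mode = config$grid_mode)
    curves <- sensitivity_curves(evaluation$model, st, grid)
    dirs <- direction_summary(curves)
    write_csv_exact(st, file.path(config$out_dir, "predictor_stats.csv"),
                    comments = "# predictor summary statistics, deg")
    gdf <- data.frame(level = rownames(grid), k = attr(grid, "levels"),
                      unclass(grid)[, , drop = FALSE], row.names = NULL)
    write_csv_exact(gdf, file.path(config$out_dir, "perturbation_grid.csv"),
                    comments = paste0("# mode: ", attr(grid, "mode")))
    write_csv_exact(curves,
                    file.path(config$out_dir, "sensitivity_predictions.csv"),
                    comments = "# one predictor varied, others at average")
    write_csv_exact(dirs,
                    file.path(config$out_dir, "direction_summary.csv"),
                    comments = "# sign of top-level minus bottom-level")
    list(stats = st, grid = grid, curves = curves, directions = dirs)
  })

  comparison <- stage("group-stats", {
    cmp <- compare_conditions(discrete)
    write_csv_exact(cmp, file.path(config$out_dir, "group_comparison.csv"),
                    comments = paste0("# paired t per variable, two-sided, ",
                                      "alpha = ", config$alpha,
                                      ", no multiplicity correction"))
    cmp
  })

  waveforms <- stage("waveform-stats", {
    rows <- list()
    for (sig in c("angle", "moment", "power")) {
      for (j in c("ankle", "knee", "hip")) {
        m <- stance_curves(trials, signal = sig, joint = j, config = config)
        meta <- attr(m, "meta")
        ord_pre <- order(meta$subject[meta$condition == "pre"])
        ord_post <- order(meta$subject[meta$condition == "post"])
        pre <- m[meta$condition == "pre", , drop = FALSE][ord_pre, ,
                                                          drop = FALSE]
        post <- m[meta$condition == "post", , drop = FALSE][ord_post, ,
                                                            drop = FALSE]
        wt <- waveform_paired_test(pre, post, n_perm = config$n_perm,
                                   alpha = config$alpha, seed = config$seed)
        in_cluster <- abs(wt$t) > wt$threshold
        rows[[paste(sig, j)]] <- data.frame(
          signal = sig, joint = j, node_pct = wt$percent, t = wt$t,
          threshold = wt$threshold, in_cluster = in_cluster,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    write_csv_exact(out, file.path(config$out_dir, "waveform_tests.csv"),
                    comments = paste0("# paired t per stance node; ",
                                      "permutation family-wise threshold"))
    out
  })

  manifest <- stage("manifest", {
    mf <- data.frame(
      key = c("config_hash", "seed", "population_seed", "n_subjects",
              "n_trials", "n_discrete_rows", "n_grid_levels",
              "n_predictors", "package_version"),
      value = c(rlang::hash(unclass(config)[setdiff(names(config),
                                                    "out_dir")]),
                config$seed, config$population$seed,
                config$population$n_subjects, length(trials),
                nrow(discrete), nrow(sens$grid), ncol(sens$grid),
                tryCatch(as.character(utils::packageVersion("gaitwork")),
                         error = function(e) "0.0.0")),
      stringsAsFactors = FALSE
    )
    write_csv_exact(mf, file.path(config$out_dir, "manifest.csv"),
                    comments = "# run manifest")
    mf
  })

  invisible(list(discrete = discrete, comparison = comparison,
                 evaluation = evaluation, stats = sens$stats,
                 grid = sens$grid, curves = sens$curves,
                 directions = sens$directions, waveforms = waveforms,
                 manifest = manifest))
}
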