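#' Write one trial to CSV files
#'
#' A trial is stored as two RFC-4180 CSV files sharing a base path, because
#' the force platform and the motion capture run at different rates:
#' `<base>_grf.csv` (columns `time_s`, `grf_z_N`) and `<base>_kin.csv`
#' (columns `time_s`, `ankle_angle_deg`, `knee_angle_deg`, `hip_angle_deg`,
#' `ankle_moment_Nmkg`, `knee_moment_Nmkg`, `hip_moment_Nmkg`). Units are
#' part of the column names; subject, condition, body mass and sampling rate
#' are recorded in `#`-prefixed header comments. Values are written with 17
#' significant digits so a read round-trips bit-identically.
#'
#' @param trial A `trial_time_series`.
#' @param base Path prefix (without the `_grf.csv` / `_kin.csv` suffix).
#' @return Invisibly, the two file paths.
#' @export
write_trial <- function(trial, base) {
  grf_path <- paste0(base, "_grf.csv")
  kin_path <- paste0(base, "_kin.csv")
  hdr <- function(rate) c(
    sprintf("# subject: %s", trial$subject),
    sprintf("# condition: %s", trial$condition),
    sprintf("# mass_kg: %.17g", trial$mass),
    sprintf("# rate_hz: %.17g", rate)
  )
  g <- data.frame(time_s = trial$grf$time, grf_z_N = trial$grf$fz)
  k <- data.frame(
    time_s = trial$kin$time,
    ankle_angle_deg = trial$kin$angle[, "ankle"],
    knee_angle_deg = trial$kin$angle[, "knee"],
    hip_angle_deg = trial$kin$angle[, "hip"],
    ankle_moment_Nmkg = trial$kin$moment[, "ankle"],
    knee_moment_Nmkg = trial$kin$moment[, "knee"],
    hip_moment_Nmkg = trial$kin$moment[, "hip"]
  )
  write_csv_exact(g, grf_path, comments = hdr(trial$grf$rate))
  write_csv_exact(k, kin_path, comments = hdr(trial$kin$rate))
  invisible(c(grf = grf_path, kin = kin_path))
}

write_csv_exact <- function(df, path, comments = character(0)) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(comments, con)
  utils::write.table(out, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Read one trial from its CSV files
#'
#' Reads and validates the pair of files written by [write_trial()]:
#' required columns present, no missing cells (reported with the offending
#' row number), and a strictly increasing, uniform time column per file.
#'
#' @param base Path prefix used at write time.
#' @return A `trial_time_series`.
#' @export
read_trial <- function(base) {
  grf <- read_trial_csv(paste0(base, "_grf.csv"),
                        c("time_s", "grf_z_N"))
  kin_cols <- c("time_s", "ankle_angle_deg", "knee_angle_deg",
                "hip_angle_deg", "ankle_moment_Nmkg", "knee_moment_Nmkg",
                "hip_moment_Nmkg")
  kin <- read_trial_csv(paste0(base, "_kin.csv"), kin_cols)
  meta <- kin$meta
  angle <- as.matrix(kin$data[, c("ankle_angle_deg", "knee_angle_deg",
                                  "hip_angle_deg")])
  moment <- as.matrix(kin$data[, c("ankle_moment_Nmkg", "knee_moment_Nmkg",
                                   "hip_moment_Nmkg")])
  colnames(angle) <- colnames(moment) <- c("ankle", "knee", "hip")
  structure(
    list(
      subject = meta$subject, condition = meta$condition,
      mass = meta$mass_kg,
      grf = list(time = grf$data$time_s, fz = grf$data$grf_z_N,
                 rate = grf$meta$rate_hz),
      kin = list(time = kin$data$time_s, angle = angle, moment = moment,
                 rate = meta$rate_hz)
    ),
    class = "trial_time_series"
  )
}

read_trial_csv <- function(path, required) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  lines <- readLines(path)
  cmt <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in cmt) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  for (k in c("mass_kg", "rate_hz")) {
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad)) {
    stop("missing/NaN cell in ", path, " at data row ", bad[1])
  }
  tm <- df$time_s
  dt <- diff(tm)
  nonmono <- which(dt <= 0)
  if (length(nonmono)) {
    stop("time not strictly increasing in ", path, " at data row ",
         nonmono[1] + 1L)
  }
  if (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("time not uniformly sampled in ", path)
  }
  list(data = df, meta = meta)
}

#' Write a synthetic cohort to disk
#'
#' Writes every trial via [write_trial()], a tidy ground-truth table
#' (`ground_truth.csv`: subject, condition, variable, value), and a cohort
#' manifest (`cohort_manifest.csv`: subject, condition, base path, mass and
#' the two sampling rates).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$trials, function(st) {
    tr <- st$trial
    base <- file.path(dir, paste(tr$subject, tr$condition, sep = "_"))
    write_trial(tr, base)
    data.frame(subject = tr$subject, condition = tr$condition,
               base = base, mass_kg = tr$mass,
               grf_rate_hz = tr$grf$rate, kin_rate_hz = tr$kin$rate,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_csv_exact(manifest, file.path(dir, "cohort_manifest.csv"),
                  comments = "# cohort manifest: one row per trial")
  write_csv_exact(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                  comments = paste0("# ground truth targets; angles deg, ",
                                    "moments Nm/kg, powers W/kg, works J/kg"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort_manifest.csv`.
#' @return List with `trials` (list of `trial_time_series`) and
#'   `ground_truth` if present.
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "cohort_manifest.csv"),
                         comment.char = "#", stringsAsFactors = FALSE)
  trials <- lapply(man$base, read_trial)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) {
    utils::read.csv(gt_path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    NULL
  }
  list(trials = trials, ground_truth = gt)
}
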