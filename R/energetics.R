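#' Joint angular velocity from an angle curve
#'
#' Central differences at interior samples, one-sided differences at the two
#' endpoints, with degrees converted to radians. Derivatives are taken on the
#' real-time axis at the kinematic rate (never on percent-stance curves, which
#' would distort the time base).
#'
#' @param angle_deg Joint angle curve in degrees (length >= 3).
#' @param rate Sampling rate in Hz.
#' @return Angular velocity in rad/s, same length as the input.
#' @export
angular_velocity <- function(angle_deg, rate) {
  n <- length(angle_deg)
  if (n < 3L) stop("angle curve must have at least 3 samples")
  rad <- angle_deg * pi / 180
  dt <- 1 / rate
  omega <- numeric(n)
  omega[1] <- (rad[2] - rad[1]) / dt
  omega[n] <- (rad[n] - rad[n - 1]) / dt
  omega[2:(n - 1)] <- (rad[3:n] - rad[1:(n - 2)]) / (2 * dt)
  omega
}

#' Instantaneous joint power
#'
#' Elementwise product of the mass-normalized joint moment and the joint
#' angular velocity. Positive values indicate energy generation, negative
#' values energy absorption.
#'
#' @param moment Moment curve in Nm/kg.
#' @param omega Angular velocity curve in rad/s, same length.
#' @return Power curve in W/kg.
#' @export
joint_power <- function(moment, omega) {
  if (length(moment) != length(omega)) {
    stop("moment and angular velocity curves must have equal length")
  }
  moment * omega
}

#' Positive, negative and total joint work
#'
#' Trapezoidal time integrals over the stance of the positive part, the
#' negative part, and the whole power curve. Total equals positive plus
#' negative work to machine tolerance by construction.
#'
#' @param power Power curve in W/kg (length >= 2).
#' @param rate Sampling rate in Hz.
#' @return Named list `positive`, `negative`, `total` in J/kg.
#' @export
joint_work <- function(power, rate) {
  if (length(power) < 2L) stop("power curve must have at least 2 samples")
  dt <- 1 / rate
  list(
    positive = trapz_uniform(pmax(power, 0), dt),
    negative = trapz_uniform(pmin(power, 0), dt),
    total = trapz_uniform(power, dt)
  )
}

trapz_uniform <- function(y, dt) {
  dt * (sum(y) - (y[1] + y[length(y)]) / 2)
}

#' Discrete kinematic summaries of one joint over stance
#'
#' @param angle_deg Conditioned angle curve over the stance frames, degrees.
#' @return Named list: `ic` (angle at the first stance frame), `max_angle`,
#'   `min_angle`, and `rom = max - min`.
#' @export
discrete_kinematics <- function(angle_deg) {
  mx <- max(angle_deg)
  mn <- min(angle_deg)
  list(ic = angle_deg[1], max_angle = mx, min_angle = mn, rom = mx - mn)
}

#' Discrete kinetic summaries of one joint over stance
#'
#' Peak positive power is the maximum of the power curve (0 if no sample is
#' positive); peak negative power the minimum (0 if none negative). Peak
#' moments are reported signed: most-positive (dorsiflexion/flexion) and
#' most-negative (plantarflexion/extension) values, floored/capped at 0 when
#' the curve never takes that sign.
#'
#' @param power Power curve in W/kg.
#' @param moment Moment curve in Nm/kg.
#' @return Named list `peak_pos_power`, `peak_neg_power`, `peak_pos_moment`,
#'   `peak_neg_moment`.
#' @export
discrete_kinetics <- function(power, moment) {
  list(
    peak_pos_power = max(c(power, 0)),
    peak_neg_power = min(c(power, 0)),
    peak_pos_moment = max(c(moment, 0)),
    peak_neg_moment = min(c(moment, 0))
  )
}

#' Extract all discrete variables from one trial
#'
#' Runs the conditioning chain on a trial: stance detection at the GRF
#' threshold on the raw force signal, optional zero-phase low-pass filtering
#' of the kinematic (default 15 Hz) and kinetic (default 50 Hz) channels over
#' the full record, cropping to the stance window (nearest kinematic samples
#' to the GRF-rate stance boundaries), then angular velocity, power, works and
#' the discrete kinematic/kinetic summaries per joint.
#'
#' @param trial A `trial_time_series` (see [read_trial()] or
#'   [synthesize_trial()]).
#' @param filter Apply the Butterworth conditioning before extraction
#'   (default `TRUE`).
#' @param cutoff_kinematic,cutoff_kinetic Low-pass cutoffs in Hz for angles
#'   and moments.
#' @param filter_order Net Butterworth order (default 4).
#' @param threshold GRF stance threshold in N (default 30).
#' @return One-row data frame: `subject`, `condition`, then per joint
#'   (`ankle`, `knee`, `hip`) the columns `_ic`, `_max_angle`, `_min_angle`,
#'   `_rom` (deg), `_peak_pos_power`, `_peak_neg_power` (W/kg),
#'   `_peak_pos_moment`, `_peak_neg_moment` (Nm/kg), `_pos_work`,
#'   `_neg_work`, `_total_work` (J/kg); plus `stance_duration` (s).
#' @export
extract_discrete_variables <- function(trial, filter = TRUE,
                                       cutoff_kinematic = 15,
                                       cutoff_kinetic = 50,
                                       filter_order = 4L,
                                       threshold = 30) {
  seg <- detect_stance(trial$grf$fz, trial$grf$rate, threshold = threshold)
  t0 <- trial$grf$time[seg$start]
  t1 <- trial$grf$time[seg$end]
  k0 <- which.min(abs(trial$kin$time - t0))
  k1 <- which.min(abs(trial$kin$time - t1))
  if (k1 - k0 < 2L) stop("stance window too short at the kinematic rate")

  rate <- trial$kin$rate
  out <- list(subject = trial$subject, condition = trial$condition)
  for (j in c("ankle", "knee", "hip")) {
    ang <- trial$kin$angle[, j]
    mom <- trial$kin$moment[, j]
    if (filter) {
      ang <- butterworth_lowpass(ang, rate, cutoff_kinematic,
                                 order = filter_order)
      mom <- butterworth_lowpass(mom, rate, cutoff_kinetic,
                                 order = filter_order)
    }
    ang <- ang[k0:k1]
    mom <- mom[k0:k1]
    omega <- angular_velocity(ang, rate)
    pw <- joint_power(mom, omega)
    wk <- joint_work(pw, rate)
    kin <- discrete_kinematics(ang)
    kin2 <- discrete_kinetics(pw, mom)
    vals <- c(kin, kin2,
              list(pos_work = wk$positive, neg_work = wk$negative,
                   total_work = wk$total))
    names(vals) <- paste0(j, "_", names(vals))
    out <- c(out, vals)
  }
  out$stance_duration <- (k1 - k0) / rate
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Discrete-variable table for a whole cohort
#'
#' Applies [extract_discrete_variables()] to every trial of a cohort.
#'
#' @param trials List of `trial_time_series` or `synthetic_trial` objects.
#' @param ... Passed to [extract_discrete_variables()].
#' @return Data frame, one row per trial.
#' @export
cohort_discrete_table <- function(trials, ...) {
  rows <- lapply(trials, function(tr) {
    if (inherits(tr, "synthetic_trial")) tr <- tr$trial
    extract_discrete_variables(tr, ...)
  })
  do.call(rbind, rows)
}
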