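#' Synthesize one stance-phase trial from discrete targets
#'
#' Builds a physically plausible sagittal stance trial whose discrete
#' summaries match the prescribed targets:
#'
#' * Angle curves are piecewise-cosine interpolations through control points
#'   (zero slope at each node, so extrema are exact): ankle from initial
#'   contact to peak dorsiflexion near 45% stance to peak plantarflexion at
#'   toe-off; knee from initial contact to peak flexion near 40% to the
#'   toe-off angle; hip a single flexion-to-extension sweep. Control-point
#'   stance fractions are snapped to the sampling grid so the sampled extrema
#'   equal the targets exactly.
#' * Moment curves are raised-cosine template bumps scaled so the sampled
#'   peak moments match the targets: ankle a small early dorsiflexor bump and
#'   a dominant mid-stance plantarflexor bump; knee a flexor bump; hip an
#'   early extensor and a late flexor bump.
#' * The moment is then rescaled over the intervals where instantaneous power
#'   is positive (with cosine blending inside each interval edge, width 5% of
#'   stance) so that the trapezoidal integral of the positive power equals the
#'   target positive work exactly. Negative work, peak powers and
#'   (post-rescale) peak moments are therefore emergent rather than
#'   calibrated.
#' * Vertical GRF is a half-sine bump from exactly 30 N at the stance
#'   boundary samples to 2.5 body weight at midstance, padded with 50 ms of
#'   zero force on both sides. The kinematic channels are padded by constant
#'   extension (the templates end with zero slope, so the extension is C1).
#'
#' Synthesis is deterministic given the targets.
#'
#' @param targets Named list of discrete targets for one subject-condition,
#'   as produced by [sample_subject_targets()] (`$pre` or `$post`).
#' @param duration Stance duration in s (> 0.1); snapped to the kinematic
#'   sampling grid.
#' @param mass Body mass in kg (GRF scaling only; kinetics are
#'   mass-normalized).
#' @param grf_rate,kin_rate Sampling rates in Hz.
#' @param subject,condition Identifiers stored with the trial.
#' @return A `synthetic_trial`: list with `trial` (a `trial_time_series`),
#'   `targets` (the ground truth actually enforced, including derived ROM and
#'   the grid-snapped `stance_duration`), `subject` and `condition`.
#' @export
synthesize_trial <- function(targets, duration = targets$stance_duration,
                             mass = targets$mass,
                             grf_rate = 1000, kin_rate = 200,
                             subject = "S1", condition = "pre") {
  if (is.null(duration) || duration <= 0.1) {
    stop("stance duration must exceed 0.1 s")
  }
  n_kin <- round(duration * kin_rate) + 1L
  dur_eff <- (n_kin - 1L) / kin_rate
  s <- seq(0, 1, length.out = n_kin)

  ang <- sapply(c("ankle", "knee", "hip"), function(j) {
    angle_template(targets, j, n_kin)
  })
  mom <- sapply(c("ankle", "knee", "hip"), function(j) {
    moment_template(targets, j, s)
  })

  # enforce positive joint work per joint by piecewise gain on the moment
  for (j in c("ankle", "knee", "hip")) {
    omega <- angular_velocity(ang[, j], kin_rate)
    mom[, j] <- rescale_positive_work(
      mom[, j], omega, kin_rate,
      target = targets[[paste0(j, "_pos_work")]],
      joint = j
    )
  }

  npad_k <- round(0.05 * kin_rate)
  kin_time <- (seq_len(n_kin + 2L * npad_k) - npad_k - 1L) / kin_rate
  pad_mat <- function(m) {
    apply(m, 2, function(col) {
      c(rep(col[1], npad_k), col, rep(col[length(col)], npad_k))
    })
  }
  ang_full <- pad_mat(ang)
  mom_full <- apply(mom, 2, function(col) c(rep(0, npad_k), col,
                                            rep(0, npad_k)))
  colnames(ang_full) <- colnames(mom_full) <- c("ankle", "knee", "hip")

  # GRF: exactly 30 N at the boundary samples, > 30 N strictly inside
  n_g <- round(dur_eff * grf_rate) + 1L
  sg <- seq(0, 1, length.out = n_g)
  fpeak <- 2.5 * mass * 9.81
  fz <- 30 + (fpeak - 30) * sin(pi * sg)
  fz[1] <- 30
  fz[n_g] <- 30
  npad_g <- round(0.05 * grf_rate)
  fz_full <- c(rep(0, npad_g), fz, rep(0, npad_g))
  grf_time <- (seq_len(n_g + 2L * npad_g) - npad_g - 1L) / grf_rate

  trial <- structure(
    list(
      subject = subject, condition = condition, mass = mass,
      grf = list(time = grf_time, fz = fz_full, rate = grf_rate),
      kin = list(time = kin_time, angle = ang_full, moment = mom_full,
                 rate = kin_rate)
    ),
    class = "trial_time_series"
  )
  gt <- targets
  gt$stance_duration <- dur_eff
  gt$mass <- mass
  structure(
    list(trial = trial, targets = gt, subject = subject,
         condition = condition),
    class = "synthetic_trial"
  )
}

# Cosine interpolation through control points with the interior node snapped
# to the sampling grid, so sampled extrema equal the control values exactly.
angle_template <- function(targets, joint, n_kin) {
  if (joint == "hip") {
    nodes_idx <- c(1L, n_kin)
    vals <- c(targets$hip_max_angle, targets$hip_min_angle)
  } else {
    mid_frac <- if (joint == "ankle") 0.45 else 0.40
    mid <- max(2L, min(n_kin - 1L, round(mid_frac * (n_kin - 1L)) + 1L))
    nodes_idx <- c(1L, mid, n_kin)
    vals <- c(targets[[paste0(joint, "_ic")]],
              if (joint == "ankle") targets$ankle_max_angle
              else targets$knee_max_angle,
              targets[[paste0(joint, "_min_angle")]])
  }
  out <- numeric(n_kin)
  for (seg in seq_len(length(nodes_idx) - 1L)) {
    i0 <- nodes_idx[seg]
    i1 <- nodes_idx[seg + 1L]
    u <- (seq(i0, i1) - i0) / (i1 - i0)
    out[i0:i1] <- vals[seg] + (vals[seg + 1L] - vals[seg]) *
      (1 - cos(pi * u)) / 2
  }
  out
}

# Raised-cosine bump with support [a, b] and peak at c, amplitude A, evaluated
# on the stance fraction grid, then rescaled so the sampled extremum is
# exactly A.
cosine_bump <- function(s, a, c, b, A) {
  y <- numeric(length(s))
  rise <- s >= a & s <= c
  fall <- s > c & s <= b
  y[rise] <- (1 - cos(pi * (s[rise] - a) / (c - a))) / 2
  y[fall] <- (1 + cos(pi * (s[fall] - c) / (b - c))) / 2
  m <- max(y)
  if (m > 0 && A != 0) y <- y * (A / m) else y <- y * 0
  y
}

moment_template <- function(targets, joint, s) {
  g <- function(nm) {
    v <- targets[[paste0(joint, "_", nm)]]
    if (is.null(v)) 0 else v
  }
  if (joint == "ankle") {
    cosine_bump(s, 0.00, 0.10, 0.20, g("peak_pos_moment")) +
      cosine_bump(s, 0.20, 0.50, 1.00, g("peak_neg_moment"))
  } else if (joint == "knee") {
    cosine_bump(s, 0.05, 0.45, 0.95, g("peak_pos_moment"))
  } else {
    cosine_bump(s, 0.00, 0.22, 0.50, g("peak_neg_moment")) +
      cosine_bump(s, 0.50, 0.75, 1.00, g("peak_pos_moment"))
  }
}

# Piecewise gain over positive-power intervals so that the trapezoidal
# integral of the positive power equals `target` exactly. The gain is 1
# outside those intervals, blends with a cosine ramp (5% of stance) inside
# each interval edge, and is constant in the core. Because the gain is
# non-negative, the sign pattern of the power is unchanged and the achieved
# positive work is linear in the core gain, which is therefore solved in
# closed form.
rescale_positive_work <- function(moment, omega, rate, target, joint) {
  if (is.null(target)) return(moment)
  if (target < 0) stop("positive-work target must be >= 0 for ", joint)
  p <- joint_power(moment, omega)
  dt <- 1 / rate
  w0 <- trapz_uniform(pmax(p, 0), dt)
  if (target == 0) {
    if (w0 < 1e-12) return(moment)
    stop("cannot achieve zero positive work for ", joint,
         ": template already generates energy")
  }
  if (w0 <= 0) {
    stop("degenerate template for ", joint,
         ": no positive power to rescale toward the work target")
  }
  # Start from a 5%-of-stance blend; if the unblended edge contribution alone
  # already exceeds a small target, narrow the ramp (down to none) until a
  # non-negative core gain exists.
  blend <- max(1L, round(0.05 * (length(p) - 1L)))
  repeat {
    w <- blend_weight(p > 0, blend = blend)
    iw <- trapz_uniform(w * pmax(p, 0), dt)
    if (iw <= 0) {
      stop("degenerate template for ", joint,
           ": positive-power intervals too short to rescale")
    }
    cg <- 1 + (target - w0) / iw
    if (cg >= 0 || blend == 0L) break
    blend <- blend %/% 2L
  }
  if (cg < 0) {
    stop("cannot achieve positive-work target for ", joint,
         " with a non-negative gain (degenerate template)")
  }
  gain <- 1 + (cg - 1) * w
  out <- moment * gain
  achieved <- trapz_uniform(pmax(joint_power(out, omega), 0), dt)
  if (abs(achieved - target) > 0.01 * max(target, 1e-9)) {
    stop("positive-work rescaling failed for ", joint, ": achieved ",
         signif(achieved, 6), " vs target ", signif(target, 6))
  }
  out
}

# Per-run cosine blending weight: 0 at each run edge, 1 in the core, ramp
# length `blend` samples (clipped to half the run).
blend_weight <- function(pos, blend) {
  w <- numeric(length(pos))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    len <- length(idx)
    ramp <- min(blend, floor(len / 2))
    if (ramp < 1L) {
      w[idx] <- 1
      next
    }
    d <- pmin(seq_len(len) - 1L, len - seq_len(len))
    w[idx] <- ifelse(d >= ramp, 1, (1 - cos(pi * d / ramp)) / 2)
  }
  w
}

#' Generate a paired pre/post cohort of synthetic trials
#'
#' Samples each subject's paired discrete targets with
#' [sample_subject_targets()] and synthesizes one trial per condition with
#' [synthesize_trial()]. Fully reproducible from `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return List with `trials` (list of `synthetic_trial`, ordered subject by
#'   subject, pre then post) and `ground_truth` (tidy data frame: `subject`,
#'   `condition`, `variable`, `value`, row-aligned with the trials).
#' @export
generate_cohort <- function(spec) {
  validate_population_spec(spec)
  trials <- vector("list", spec$n_subjects * 2L)
  gt_rows <- vector("list", spec$n_subjects * 2L)
  k <- 0L
  for (i in seq_len(spec$n_subjects)) {
    drawn <- sample_subject_targets(spec, i)
    sid <- sprintf("S%03d", i)
    for (cond in spec$conditions) {
      k <- k + 1L
      st <- synthesize_trial(drawn[[cond]],
                             grf_rate = spec$grf_rate,
                             kin_rate = spec$kin_rate,
                             subject = sid, condition = cond)
      trials[[k]] <- st
      tg <- st$targets
      gt_rows[[k]] <- data.frame(
        subject = sid, condition = cond,
        variable = names(tg), value = unlist(tg, use.names = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  list(trials = trials, ground_truth = do.call(rbind, gt_rows))
}
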