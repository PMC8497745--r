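#' Sample one subject's paired discrete targets
#'
#' Draws every discrete variable of the population table for one subject from
#' a bivariate Gaussian: pre and post values share correlation `spec$rho` and
#' use the condition-specific means and SDs. Sign-constrained variables
#' (works, peak powers, peak moments) are redrawn (up to `max_attempts` per
#' variable) until the constraint holds in both conditions. Stance duration
#' is sampled the same paired way; body mass once per subject, truncated to
#' `[40, 120]` kg.
#'
#' Range of motion is derived afterwards from the realized angle control
#' points (`<joint>_rom = max - min` over initial-contact, mid-stance and
#' toe-off values), so the angle-consistency invariant holds by construction.
#'
#' @param spec A [population_spec()].
#' @param subject_index Subject number (1-based); together with `spec$seed`
#'   it fully determines the draw.
#' @param max_attempts Bound on redraws per sign-constrained variable.
#' @return A list with elements `pre` and `post`, each a named list of
#'   discrete targets (including derived `*_rom`), plus `mass` and the
#'   subject's `stance` durations.
#' @export
sample_subject_targets <- function(spec, subject_index, max_attempts = 100L) {
  validate_population_spec(spec)
  with_local_seed(subject_seed(spec$seed, subject_index), {
    v <- spec$variables
    draws <- matrix(NA_real_, nrow(v), 2,
                    dimnames = list(v$variable, c("pre", "post")))
    for (i in seq_len(nrow(v))) {
      draws[i, ] <- draw_paired(
        v$pre_mean[i], v$pre_sd[i], v$post_mean[i], v$post_sd[i],
        rho = spec$rho, sign = v$sign[i],
        max_attempts = max_attempts, label = v$variable[i]
      )
    }
    stance <- draw_paired(spec$stance_mean, spec$stance_sd,
                          spec$stance_mean, spec$stance_sd,
                          rho = spec$rho, sign = "pos",
                          max_attempts = max_attempts,
                          label = "stance_duration")
    # stance must also exceed the synthesis minimum of 0.1 s
    attempts <- 0L
    while (any(stance <= 0.1)) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) stop("could not draw a valid stance duration")
      stance <- draw_paired(spec$stance_mean, spec$stance_sd,
                            spec$stance_mean, spec$stance_sd,
                            rho = spec$rho, sign = "pos",
                            max_attempts = max_attempts,
                            label = "stance_duration")
    }
    mass <- min(max(stats::rnorm(1, spec$mass_mean, spec$mass_sd), 40), 120)

    build <- function(cond) {
      t <- as.list(draws[, cond])
      for (j in c("ankle", "knee", "hip")) {
        ctrl <- joint_control_values(t, j)
        t[[paste0(j, "_max_angle")]] <- max(ctrl)
        t[[paste0(j, "_min_angle")]] <- min(ctrl)
        t[[paste0(j, "_rom")]] <- max(ctrl) - min(ctrl)
      }
      t$stance_duration <- unname(stance[[cond]])
      t$mass <- mass
      t
    }
    list(pre = build("pre"), post = build("post"),
         mass = mass,
         stance = c(pre = unname(stance[["pre"]]),
                    post = unname(stance[["post"]])))
  })
}

# The waveform control values of one joint: initial contact, mid-stance
# extremum and toe-off. The hip template is a two-point sweep whose initial
# contact equals its flexion maximum.
joint_control_values <- function(targets, joint) {
  if (joint == "hip") {
    c(targets$hip_max_angle, targets$hip_min_angle)
  } else {
    c(targets[[paste0(joint, "_ic")]],
      targets[[paste0(joint, "_max_angle")]],
      targets[[paste0(joint, "_min_angle")]])
  }
}

# One bivariate-Gaussian (pre, post) pair with optional sign constraint
# applied to both coordinates via bounded reject-and-resample.
draw_paired <- function(m1, s1, m2, s2, rho, sign = NA,
                        max_attempts = 100L, label = "variable") {
  ok <- function(x) {
    if (is.na(sign)) TRUE
    else if (sign == "pos") all(x >= 0)
    else all(x <= 0)
  }
  for (k in seq_len(max_attempts)) {
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
    x <- c(pre = m1 + s1 * z1, post = m2 + s2 * z2)
    if (ok(x)) return(x)
  }
  stop("sign constraint for '", label, "' not satisfied after ",
       max_attempts, " attempts")
}
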