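# Shared fixtures: small deterministic objects built in code.

# A minimal set of discrete targets for direct waveform synthesis.
toy_targets <- function(ankle_pos_work = 0.63) {
  list(
    ankle_ic = 9.23, ankle_max_angle = 22.20, ankle_min_angle = -19.16,
    knee_ic = 19.17, knee_max_angle = 44.13, knee_min_angle = 16.90,
    hip_max_angle = 35.87, hip_min_angle = -9.98,
    ankle_peak_pos_moment = 0.42, ankle_peak_neg_moment = -2.34,
    knee_peak_pos_moment = 3.34,
    hip_peak_pos_moment = 1.37, hip_peak_neg_moment = -1.58,
    ankle_pos_work = ankle_pos_work, knee_pos_work = 0.60,
    hip_pos_work = 0.06,
    stance_duration = 0.24, mass = 65.39
  )
}

# A small cohort spec for fast end-to-end paths.
tiny_spec <- function(n = 6, seed = 101, rho = 0.7) {
  population_spec(n_subjects = n, seed = seed, rho = rho)
}

# Random PLS problem with known coefficients.
random_pls_data <- function(n = 50, k = 4, j = 6, noise_sd = 0.3,
                            seed = 2024) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
  B <- matrix(runif(k * j, -1, 1), k, j)
  Y <- X %*% B + matrix(rnorm(n * j, sd = noise_sd), n, j)
  colnames(Y) <- paste0("y", 1:j)
  list(X = X, Y = Y, B = B)
}

# Predictor summary statistics matching the published perturbation anchors
# (ankle IC, knee IC, ankle ROM, knee ROM; degrees).
published_predictor_stats <- function() {
  data.frame(
    predictor = c("ankle_ic", "knee_ic", "ankle_rom", "knee_rom"),
    ave = c(8.21, 19.22, 43.82, 27.01),
    max = c(16.58, 29.85, 80.41, 37.51),
    min = c(1.97, 8.44, 22.53, 18.34),
    dif = c(14.61, 21.41, 57.88, 19.17),
    stringsAsFactors = FALSE
  )
}
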