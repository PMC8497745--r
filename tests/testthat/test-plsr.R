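test_that("standardization z-scores every column with N - 1 denominator", {
  s <- standardize(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(s$scaled), c(-1, 0, 1))

  set.seed(14)
  m <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4)
  s2 <- standardize(m)
  expect_lt(max(abs(colMeans(s2$scaled))), 1e-12)
  expect_lt(max(abs(apply(s2$scaled, 2, sd) - 1)), 1e-12)
  # idempotence
  s3 <- standardize(s2$scaled)
  expect_equal(s3$scaled, s2$scaled, tolerance = 1e-12,
               ignore_attr = TRUE)

  bad <- matrix(c(1, 1, 1, 2, 3, 4), ncol = 2,
                dimnames = list(NULL, c("flat", "ok")))
  expect_error(standardize(bad), "flat")
})

test_that("a single noise-free direction is fit exactly by one component", {
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 1)
  Y <- 2 * X
  m <- plsr_fit(X, Y, ncomp = 1)
  expect_equal(predict(m, X), Y, tolerance = 1e-12, ignore_attr = TRUE)
  Xn <- matrix(rnorm(10), ncol = 1)
  expect_equal(predict(m, Xn), 2 * Xn, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("full-component PLS equals ordinary least squares", {
  d <- random_pls_data()
  m <- plsr_fit(d$X, d$Y, ncomp = 4)
  pls_fitted <- predict(m, d$X)
  ols_fitted <- sapply(seq_len(ncol(d$Y)),
                       function(j) fitted(lm(d$Y[, j] ~ d$X)))
  expect_lt(max(abs(pls_fitted - ols_fitted)), 1e-8)
})

test_that("X-scores are orthogonal and deflation conserves the X norm", {
  d <- random_pls_data(seed = 77)
  m <- plsr_fit(d$X, d$Y, ncomp = 4)
  G <- crossprod(m$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  Xs <- standardize(d$X)$scaled
  recon <- sum(vapply(seq_len(m$ncomp), function(h) {
    sum(m$T[, h]^2) * sum(m$P[, h]^2)
  }, numeric(1))) + sum(m$E^2)
  expect_equal(sum(Xs^2), recon, tolerance = 1e-10)
})

test_that("bilinear reconstruction X = TP' + E and Y = (sum t q') + F holds", {
  d <- random_pls_data(seed = 5)
  sx <- standardize(d$X)
  sy <- standardize(d$Y)
  f <- nipals_fit(sx$scaled, sy$scaled, ncomp = 3)
  expect_equal(f$T %*% t(f$P) + f$E, sx$scaled, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(f$T %*% t(f$Q) + f$F, sy$scaled, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("predictions are invariant to affine rescaling of a predictor", {
  d <- random_pls_data(seed = 31)
  m1 <- plsr_fit(d$X, d$Y, ncomp = 3)
  X2 <- d$X
  X2[, 2] <- 100 * X2[, 2] - 7
  m2 <- plsr_fit(X2, d$Y, ncomp = 3)
  Xnew <- d$X[1:5, ]
  Xnew2 <- X2[1:5, ]
  expect_lt(max(abs(predict(m1, Xnew) - predict(m2, Xnew2))), 1e-8)
})

test_that("prediction at the predictor centroid returns the response means", {
  d <- random_pls_data(seed = 9)
  m <- plsr_fit(d$X, d$Y, ncomp = 2)
  centroid <- matrix(colMeans(d$X), nrow = 1)
  expect_equal(as.numeric(predict(m, centroid)), unname(colMeans(d$Y)),
               tolerance = 1e-10)
  # in-sample prediction is the fitted values
  ys <- standardize(d$Y)
  fitted_std <- m$T %*% t(m$Q)
  fitted_orig <- sweep(sweep(fitted_std, 2, ys$sds, "*"), 2, ys$means, "+")
  expect_equal(predict(m, d$X), fitted_orig, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(predict(m, d$X[, 1:2]), "columns")
})

test_that("the cross-validity statistic matches its defining ratio", {
  expect_equal(q2_statistic(0.95^2, 1), 0.0975)
  expect_equal(q2_statistic(0, 10), 1)
  expect_error(q2_statistic(1, 0), "positive")
})

test_that("leave-one-out PRESS equals a brute-force SVD-PLS refit loop", {
  set.seed(6)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  Y <- X %*% matrix(c(1, -2, 0.5, 1), 2, 2) + matrix(rnorm(12, sd = 0.3), 6, 2)
  colnames(Y) <- c("u", "v")

  # independent oracle: PLS2 direction from the leading left singular vector
  # of E'F, explicit deflation, same global standardization convention
  svd_pls_coef <- function(E, F, H) {
    W <- NULL; P <- NULL; Q <- NULL
    for (h in seq_len(H)) {
      w <- svd(crossprod(E, F))$u[, 1]
      tt <- E %*% w
      p <- crossprod(E, tt) / sum(tt^2)
      q <- crossprod(F, tt) / sum(tt^2)
      W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q)
      E <- E - tcrossprod(tt, p)
      F <- F - tcrossprod(tt, q)
    }
    W %*% solve(crossprod(P, W), t(Q))
  }
  Xs <- scale(X)[, , drop = FALSE]
  Ys <- scale(Y)[, , drop = FALSE]
  for (H in 1:2) {
    press_oracle <- sum(vapply(1:6, function(i) {
      B <- svd_pls_coef(Xs[-i, , drop = FALSE], Ys[-i, , drop = FALSE], H)
      sum((Ys[i, ] - Xs[i, , drop = FALSE] %*% B)^2)
    }, numeric(1)))
    cv <- press_cv(X, Y, H)
    expect_equal(cv$press, press_oracle, tolerance = 1e-8)
  }
  expect_error(press_cv(X, Y, 5), "feasible")
})

test_that("fitted scores and predictions agree with an independent PLS", {
  skip_if_not_installed("mixOmics")
  d <- random_pls_data(n = 40, seed = 12)
  m <- plsr_fit(d$X, d$Y, ncomp = 3)
  ref <- mixOmics::pls(d$X, d$Y, ncomp = 3, mode = "regression",
                       scale = TRUE)
  ref_pred <- predict(ref, d$X)$predict[, , 3]
  expect_lt(max(abs(predict(m, d$X) - ref_pred)), 1e-6)
  # scores match up to column sign and scale convention
  for (h in 1:3) {
    a <- m$T[, h]
    b <- ref$variates$X[, h]
    expect_gt(abs(cor(a, b)), 1 - 1e-8)
  }
})

test_that("component selection stops at the first sub-threshold Q2", {
  # the rule on a synthetic trace: accept while >= 0.0975, floor at 1
  pick <- function(q2s, thr = 0.0975) {
    acc <- 0L
    for (q in q2s) {
      if (q < thr) break
      acc <- acc + 1L
    }
    max(1L, acc)
  }
  expect_identical(pick(c(0.80, 0.30, 0.01)), 2L)
  expect_identical(pick(c(0.02, 0.50)), 1L)

  # rank-2 noise-free data with two strong distinct directions keeps 2
  set.seed(42)
  X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- cbind(y1 = 5 * X[, 1], y2 = 5 * X[, 2])
  sel <- select_components(X, Y)
  expect_identical(sel$ncomp, 2L)
  expect_true(all(sel$trace$accepted))
  expect_gt(min(sel$trace$q2), 0.0975)
  # and the floor: pure noise keeps exactly one
  set.seed(43)
  Yn <- matrix(rnorm(120), 60, 2)
  seln <- select_components(X, Yn)
  expect_identical(seln$ncomp, 1L)
})

test_that("train/test split is seeded and exact models score 100 percent", {
  set.seed(2)
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- cbind(y1 = 3 * X[, 1] - X[, 2], y2 = X[, 1] + 2 * X[, 2])
  e1 <- train_test_evaluate(X, Y, seed = 7)
  e2 <- train_test_evaluate(X, Y, seed = 7)
  expect_identical(e1$train_rows, e2$train_rows)
  expect_identical(e1$test_rows, e2$test_rows)
  expect_equal(e1$train_accuracy, 100, tolerance = 1e-6)
  expect_equal(e1$test_accuracy, 100, tolerance = 1e-6)

  # pure-noise responses score far below noise-free structured ones
  set.seed(77)
  Yn <- matrix(rnorm(100), 50, 2)
  en <- train_test_evaluate(X, Yn, seed = 7)
  expect_lt(en$train_accuracy, 95)
  expect_lt(en$test_accuracy, 95)

  expect_error(train_test_evaluate(X[1:5, ], Y[1:5, ], seed = 1), "N >= 10")
})

test_that("known coefficients are recovered on a large synthetic cohort", {
  set.seed(123)
  n <- 2000
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  B <- matrix(c(0.8, -0.5, 0.3, 0, 0.2, 1.1, -0.7, 0.4), 4, 2)
  sigma <- 0.5
  Y <- X %*% B + matrix(rnorm(n * 2, sd = sigma), n, 2)
  colnames(Y) <- c("y1", "y2")
  m <- plsr_fit(X, Y, ncomp = 4)
  est <- coef(m)$slopes
  se <- sigma / (sqrt(n) * apply(X, 2, sd))
  expect_true(all(abs(est - B) < 3 * se))
})
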