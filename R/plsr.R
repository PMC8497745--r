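#' Column-wise standardization (z-scoring)
#'
#' Centers each column to mean 0 and scales to unit SD (denominator `N - 1`).
#' Constant columns are an error, reported by name.
#'
#' @param m Numeric matrix or data frame with at least 2 rows.
#' @return List with `scaled` (matrix), `means`, `sds`.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("standardization needs at least 2 rows")
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  list(scaled = sweep(sweep(m, 2, mu), 2, sdv, "/"), means = mu, sds = sdv)
}

#' Fit a PLS2 model by NIPALS on standardized matrices
#'
#' Classical NIPALS with deflation of both blocks by the X-scores: for each
#' component, iterate `w = X'u / |X'u|`, `t = Xw`, `q = Y't / t't`,
#' `u = Yq / q'q` until the X-score stabilizes; then `p = X't / t't` and
#' deflate `X <- X - t p'`, `Y <- Y - t q'`. Extraction stops early with a
#' warning if the deflated X has (numerically) no variance left.
#'
#' @param Xs,Ys Standardized predictor and response matrices.
#' @param ncomp Number of components to extract
#'   (`<= min(nrow - 1, ncol(Xs))`).
#' @param tol Convergence tolerance on the relative X-score change.
#' @param maxit Maximum NIPALS iterations per component.
#' @return List with matrices `W` (weights), `T` (X-scores), `P`
#'   (X-loadings), `Q` (Y-loadings), `U` (Y-scores), residuals `E`, `F`,
#'   coefficient matrix `B` mapping standardized X to standardized Y, and
#'   `ncomp` actually extracted.
#' @export
nipals_fit <- function(Xs, Ys, ncomp, tol = 1e-10, maxit = 10000L) {
  Xs <- as.matrix(Xs)
  Ys <- as.matrix(Ys)
  n <- nrow(Xs)
  k <- ncol(Xs)
  j <- ncol(Ys)
  if (ncomp > min(n - 1L, k)) {
    stop("ncomp must not exceed min(N - 1, K) = ", min(n - 1L, k))
  }
  E <- Xs
  F <- Ys
  W <- matrix(0, k, ncomp)
  P <- matrix(0, k, ncomp)
  Q <- matrix(0, j, ncomp)
  Tm <- matrix(0, n, ncomp)
  U <- matrix(0, n, ncomp)
  extracted <- 0L
  for (h in seq_len(ncomp)) {
    if (sum(E^2) < 1e-12 * max(1, sum(Xs^2)) ||
        sum(F^2) < 1e-24 * max(1, sum(Ys^2))) {
      warning("residual variance exhausted after ", extracted,
              " components; fewer extracted than requested")
      break
    }
    u <- F[, which.max(colSums(F^2))]
    if (sum(u^2) < .Machine$double.eps) u <- E[, which.max(colSums(E^2))]
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(maxit)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      q <- crossprod(F, tt) / sum(tt^2)
      u <- F %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) {
        converged <- TRUE
        break
      }
      t_old <- tt
    }
    if (!converged) stop("NIPALS did not converge for component ", h)
    p <- crossprod(E, tt) / sum(tt^2)
    W[, h] <- w
    P[, h] <- p
    Q[, h] <- q
    Tm[, h] <- tt
    U[, h] <- u
    E <- E - tcrossprod(tt, p)
    F <- F - tcrossprod(tt, q)
    extracted <- h
  }
  idx <- seq_len(extracted)
  W <- W[, idx, drop = FALSE]
  P <- P[, idx, drop = FALSE]
  Q <- Q[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]
  U <- U[, idx, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  dimnames(B) <- list(colnames(Xs), colnames(Ys))
  list(W = W, T = Tm, P = P, Q = Q, U = U, E = E, F = F, B = B,
       ncomp = extracted)
}

#' Fit a PLS regression model with optional Q-squared component selection
#'
#' Standardizes `X` and `Y`, selects the number of components by the
#' cross-validity rule when `ncomp` is `NULL` (see [select_components()]),
#' and fits by [nipals_fit()].
#'
#' @param X,Y Predictor and response matrices/data frames in original units.
#' @param ncomp Number of components, or `NULL` to select by cross-validity.
#' @param threshold Q-squared acceptance threshold (default 0.0975).
#' @return An object of class `plsr_model` with the NIPALS matrices, the
#'   standardization constants, the coefficient matrix (standardized scale),
#'   and when selection ran, the `PRESS`/`SS`/`Q2` trace.
#' @export
plsr_fit <- function(X, Y, ncomp = NULL, threshold = 0.0975) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) <= ncol(X)) stop("fitting needs N > K")
  sx <- standardize(X)
  sy <- standardize(Y)
  trace <- NULL
  if (is.null(ncomp)) {
    sel <- select_components(X, Y, threshold = threshold)
    ncomp <- sel$ncomp
    trace <- sel$trace
  }
  fit <- nipals_fit(sx$scaled, sy$scaled, ncomp = ncomp)
  structure(
    c(fit,
      list(x_means = sx$means, x_sds = sx$sds,
           y_means = sy$means, y_sds = sy$sds,
           selection = trace, threshold = threshold)),
    class = "plsr_model"
  )
}

#' Predict responses from a fitted PLS model
#'
#' Standardizes the new predictors with the training constants, applies the
#' coefficient matrix and back-transforms to original response units.
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix or data frame with the training predictor columns.
#' @param ... Unused.
#' @return Matrix of predicted responses in original units.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_means)) {
    stop("newdata must have ", length(object$x_means), " columns")
  }
  xs <- sweep(sweep(newdata, 2, object$x_means), 2, object$x_sds, "/")
  ys <- xs %*% object$B
  sweep(sweep(ys, 2, object$y_sds, "*"), 2, object$y_means, "+")
}

#' Coefficients of a PLS model in original units
#'
#' @param object A `plsr_model`.
#' @param ... Unused.
#' @return List with `slopes` (K x J matrix) and `intercept` (length J).
#' @export
coef.plsr_model <- function(object, ...) {
  slopes <- object$B * outer(1 / object$x_sds, object$y_sds)
  intercept <- object$y_means - drop(crossprod(slopes, object$x_means))
  list(slopes = slopes, intercept = intercept)
}

#' Leave-one-out PRESS, residual SS and Q-squared for H components
#'
#' `X` and `Y` are standardized once on the full data; each leave-one-out
#' model is then refit by NIPALS on the remaining standardized rows (no
#' per-fold re-scaling) and predicts the left-out row. `PRESS(H)` sums the
#' squared leave-one-out errors over all rows and responses; `SS(H)` is the
#' residual sum of squares of the H-component model fit on all rows;
#' `SS(0)` is the total sum of squares of the standardized responses. The
#' cross-validity statistic is `Q2_H = 1 - PRESS(H) / SS(H - 1)`.
#'
#' @param X,Y Matrices in original units (N >= 3).
#' @param H Number of components (>= 1).
#' @return List `press`, `ss`, `ss_prev`, `q2`.
#' @export
press_cv <- function(X, Y, H) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out cross-validation needs N >= 3")
  if (H < 1L) stop("H must be >= 1")
  if (H > min(n - 2L, ncol(X))) {
    stop("H = ", H, " exceeds the feasible number of components")
  }
  Xs <- standardize(X)$scaled
  Ys <- standardize(Y)$scaled
  press <- 0
  for (i in seq_len(n)) {
    fit <- nipals_fit(Xs[-i, , drop = FALSE], Ys[-i, , drop = FALSE],
                      ncomp = H)
    pred <- Xs[i, , drop = FALSE] %*% fit$B
    press <- press + sum((Ys[i, ] - pred)^2)
  }
  full <- nipals_fit(Xs, Ys, ncomp = H)
  ss <- sum((Ys - Xs %*% full$B)^2)
  ss_prev <- if (H == 1L) {
    sum(Ys^2)
  } else {
    prev <- nipals_fit(Xs, Ys, ncomp = H - 1L)
    sum((Ys - Xs %*% prev$B)^2)
  }
  list(press = press, ss = ss, ss_prev = ss_prev,
       q2 = q2_statistic(press, ss_prev))
}

#' Cross-validity statistic
#'
#' `Q2 = 1 - PRESS / SS_prev`, the component-acceptance statistic of
#' PRESS-based PLS selection (e.g. `PRESS/SS_prev = 0.95^2` gives 0.0975).
#'
#' @param press Predicted residual sum of squares with H components.
#' @param ss_prev Residual sum of squares of the (H-1)-component model
#'   (total standardized SS for H = 1).
#' @return The Q-squared value.
#' @export
q2_statistic <- function(press, ss_prev) {
  if (ss_prev <= 0) stop("ss_prev must be positive")
  1 - press / ss_prev
}

#' Select the number of PLS components by the cross-validity rule
#'
#' Components are added while `Q2_H >= threshold`; extraction stops at the
#' first component whose cross-validity falls below the threshold. At least
#' one component is always kept.
#'
#' @param X,Y Matrices in original units.
#' @param threshold Acceptance threshold (default 0.0975).
#' @param max_components Upper bound (default `min(N - 2, K)`).
#' @return List `ncomp` and `trace` (data frame `H`, `press`, `ss`,
#'   `ss_prev`, `q2`, `accepted`).
#' @export
select_components <- function(X, Y, threshold = 0.0975,
                              max_components = NULL) {
  X <- as.matrix(X)
  if (is.null(max_components)) {
    max_components <- min(nrow(X) - 2L, ncol(X))
  }
  rows <- list()
  accepted <- 0L
  for (h in seq_len(max_components)) {
    cv <- press_cv(X, Y, h)
    ok <- cv$q2 >= threshold
    rows[[h]] <- data.frame(H = h, press = cv$press, ss = cv$ss,
                            ss_prev = cv$ss_prev, q2 = cv$q2, accepted = ok)
    if (!ok) break
    accepted <- h
  }
  list(ncomp = max(1L, accepted), trace = do.call(rbind, rows))
}

#' Train/test evaluation of the PLS model
#'
#' Splits the rows at random (simple random sampling, no stratification),
#' fits and selects components on the training set, and reports the
#' prediction-accuracy metric on both sets. Accuracy is defined here as
#' `100 * (1 - NRMSE)` per response, averaged over responses, where NRMSE is
#' the RMSE divided by the training-set observed range of that response.
#' This is a project definition of "prediction accuracy" (the quantity has
#' no universally agreed formula).
#'
#' @param X,Y Matrices in original units (N >= 10).
#' @param train_fraction Fraction of rows used for training (default 0.8).
#' @param seed RNG seed for the split (required for reproducibility).
#' @param threshold Q-squared selection threshold.
#' @param ncomp Fixed number of components; `NULL` (default) selects by the
#'   cross-validity rule on the training set.
#' @return List with `model`, `train_accuracy`, `test_accuracy` (percent),
#'   `train_rows`, `test_rows`.
#' @export
train_test_evaluate <- function(X, Y, train_fraction = 0.8, seed,
                                threshold = 0.0975, ncomp = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 10L) stop("train/test evaluation needs N >= 10")
  train <- with_local_seed(seed, {
    sort(sample.int(n, size = round(train_fraction * n)))
  })
  test <- setdiff(seq_len(n), train)
  model <- plsr_fit(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                    ncomp = ncomp, threshold = threshold)
  ranges <- apply(Y[train, , drop = FALSE], 2, function(col) diff(range(col)))
  acc <- function(rows) {
    pred <- predict(model, X[rows, , drop = FALSE])
    rmse <- sqrt(colMeans((Y[rows, , drop = FALSE] - pred)^2))
    mean(100 * (1 - rmse / ranges))
  }
  list(model = model, train_accuracy = acc(train), test_accuracy = acc(test),
       train_rows = train, test_rows = test)
}

#' Assemble the PLS dataset from a discrete-variable table
#'
#' Predictors: ankle and knee initial-contact angles and ranges of motion.
#' Responses: ankle and knee positive, negative and total joint works.
#'
#' @param discrete Data frame from [cohort_discrete_table()].
#' @return List with matrices `X` (N x 4) and `Y` (N x 6) and `ids`.
#' @export
build_plsr_dataset <- function(discrete) {
  xcols <- c("ankle_ic", "knee_ic", "ankle_rom", "knee_rom")
  ycols <- c("ankle_pos_work", "ankle_neg_work", "ankle_total_work",
             "knee_pos_work", "knee_neg_work", "knee_total_work")
  missing <- setdiff(c(xcols, ycols), names(discrete))
  if (length(missing)) {
    stop("discrete table lacks columns: ", paste(missing, collapse = ", "))
  }
  list(
    X = as.matrix(discrete[, xcols]),
    Y = as.matrix(discrete[, ycols]),
    ids = paste(discrete$subject, discrete$condition, sep = "_")
  )
}
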