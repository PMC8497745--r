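#' Summary statistics of the PLS predictors
#'
#' Columnwise average, maximum, minimum and range (`dif = max - min`) of the
#' predictor matrix, the anchors of the incremental perturbation grid.
#'
#' @param X Predictor matrix or data frame (>= 1 row).
#' @return Data frame with one row per predictor: `predictor`, `ave`, `max`,
#'   `min`, `dif`.
#' @export
predictor_stats <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("predictor matrix is empty")
  data.frame(
    predictor = colnames(X) %||% paste0("X", seq_len(ncol(X))),
    ave = colMeans(X),
    max = apply(X, 2, max),
    min = apply(X, 2, min),
    dif = apply(X, 2, max) - apply(X, 2, min),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the incremental perturbation grid
#'
#' Levels are fractions `k` of each predictor's range applied as
#' `min + k * dif`; the default levels are -0.1, 0, 0.1, ..., 0.9, 1.0, 2.0
#' (so `k = 1` is the observed maximum and `k = 2` the maximum plus one full
#' range). In `"printed-compat"` mode the two boundary rows instead follow
#' the archival conventions `0.9 * min` and `2 * max`; interior rows are
#' identical in both modes. Values are kept at full precision; rounding (to
#' mirror a 2-decimal printed table) is an output concern only.
#'
#' @param stats Data frame from [predictor_stats()].
#' @param levels Numeric vector of range fractions.
#' @param mode `"formula"` (default) or `"printed-compat"`.
#' @return A `perturbation_grid`: matrix (levels x predictors) with level
#'   labels as rownames and attributes `levels` and `mode`.
#' @export
build_grid <- function(stats, levels = c(-0.1, seq(0, 1, by = 0.1), 2),
                       mode = c("formula", "printed-compat")) {
  mode <- match.arg(mode)
  g <- outer(levels, stats$dif) +
    matrix(stats$min, length(levels), nrow(stats), byrow = TRUE)
  if (mode == "printed-compat") {
    lo <- which(levels < 0)
    hi <- which(levels > 1)
    if (length(lo)) g[lo, ] <- matrix(0.9 * stats$min, length(lo),
                                      nrow(stats), byrow = TRUE)
    if (length(hi)) g[hi, ] <- matrix(2 * stats$max, length(hi),
                                      nrow(stats), byrow = TRUE)
  }
  dimnames(g) <- list(level_label(levels), stats$predictor)
  structure(g, levels = levels, mode = mode, class = "perturbation_grid")
}

level_label <- function(k) {
  ifelse(k == 0, "min",
         ifelse(k == 1, "max",
                sprintf("min%+d%%dif", as.integer(round(100 * k)))))
}

#' Predicted responses along the perturbation grid
#'
#' For each predictor in turn, varies that predictor over its grid levels
#' while holding every other predictor at its average, and predicts all
#' responses from the fitted PLS model.
#'
#' @param model A `plsr_model` whose predictors match `stats$predictor` in
#'   order.
#' @param stats Data frame from [predictor_stats()].
#' @param grid A `perturbation_grid` from [build_grid()].
#' @return Long data frame: `predictor`, `level` (label), `k` (range
#'   fraction), `value` (perturbed predictor value), `response`,
#'   `prediction`.
#' @export
sensitivity_curves <- function(model, stats, grid) {
  preds <- stats$predictor
  model_preds <- names(model$x_means)
  if (!is.null(model_preds) && !identical(model_preds, preds)) {
    stop("predictor order mismatch between model and stats")
  }
  k <- attr(grid, "levels")
  out <- list()
  for (jp in seq_along(preds)) {
    Xnew <- matrix(stats$ave, nrow(grid), length(preds), byrow = TRUE)
    colnames(Xnew) <- preds
    Xnew[, jp] <- grid[, jp]
    yhat <- predict(model, Xnew)
    resp <- colnames(yhat) %||% paste0("Y", seq_len(ncol(yhat)))
    out[[jp]] <- data.frame(
      predictor = preds[jp],
      level = rep(rownames(grid), times = ncol(yhat)),
      k = rep(k, times = ncol(yhat)),
      value = rep(grid[, jp], times = ncol(yhat)),
      response = rep(resp, each = nrow(grid)),
      prediction = as.vector(yhat),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Direction-of-effect summary of the sensitivity curves
#'
#' Sign of the predicted response change from the lowest to the highest grid
#' level for every (predictor, response) pair: `"+"`, `"-"`, or `"0"` when
#' the change is below tolerance.
#'
#' @param curves Data frame from [sensitivity_curves()].
#' @param tol Absolute tolerance below which a change counts as zero.
#' @return Data frame `predictor`, `response`, `delta`, `direction`.
#' @export
direction_summary <- function(curves, tol = 1e-8) {
  pieces <- split(curves, list(curves$predictor, curves$response),
                  drop = TRUE)
  rows <- lapply(pieces, function(d) {
    d <- d[order(d$k), ]
    delta <- d$prediction[nrow(d)] - d$prediction[1]
    data.frame(
      predictor = d$predictor[1], response = d$response[1], delta = delta,
      direction = if (abs(delta) <= tol) "0" else if (delta > 0) "+" else "-",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$predictor, out$response), ]
}
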