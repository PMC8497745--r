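#' Paired pre/post comparison of one discrete variable
#'
#' Paired t-test on within-subject differences `d = post - pre`
#' (`t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from the t distribution
#' with `n - 1` df), plus a Shapiro-Wilk normality p-value on the
#' differences, reported but not gating the test. Zero-variance differences
#' are degenerate: `p = 1` when the mean difference is also zero, an error
#' otherwise.
#'
#' @param pre,post Numeric vectors of equal length (>= 2), paired by subject.
#' @param variable Variable name carried into the output.
#' @return One-row data frame: `variable`, `pre_mean`, `pre_sd`, `post_mean`,
#'   `post_sd`, `mean_diff`, `t`, `p`, `n`, `normality_p`.
#' @export
paired_t <- function(pre, post, variable = "variable") {
  if (length(pre) != length(post)) stop("pre and post must be equal length")
  n <- length(pre)
  if (n < 2L) stop("paired comparison needs at least 2 pairs")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      tval <- 0
      pval <- 1
    } else {
      stop("differences have zero variance but nonzero mean: ",
           "t statistic undefined")
    }
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    tval <- unname(tt$statistic)
    pval <- tt$p.value
  }
  norm_p <- if (n >= 3 && n <= 5000 && stats::sd(d) > 0) {
    normality_check(d)
  } else {
    NA_real_
  }
  data.frame(
    variable = variable,
    pre_mean = mean(pre), pre_sd = stats::sd(pre),
    post_mean = mean(post), post_sd = stats::sd(post),
    mean_diff = mean(d), t = tval, p = pval, n = n,
    normality_p = norm_p,
    stringsAsFactors = FALSE
  )
}

#' Shapiro-Wilk normality p-value
#'
#' @param x Numeric vector, 3 <= length <= 5000.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_check <- function(x) {
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires between 3 and 5000 observations")
  }
  stats::shapiro.test(x)$p.value
}

#' Paired comparison table across all discrete variables
#'
#' Runs [paired_t()] for every numeric discrete variable of a cohort table,
#' matching pre and post rows by subject. No multiple-testing correction is
#' applied across variables.
#'
#' @param discrete Data frame from [cohort_discrete_table()] with `subject`
#'   and `condition` columns.
#' @return Data frame, one row per variable.
#' @export
compare_conditions <- function(discrete) {
  pre <- discrete[discrete$condition == "pre", ]
  post <- discrete[discrete$condition == "post", ]
  pre <- pre[order(pre$subject), ]
  post <- post[order(post$subject), ]
  if (!identical(pre$subject, post$subject)) {
    stop("pre and post rows do not pair by subject")
  }
  vars <- setdiff(names(discrete)[vapply(discrete, is.numeric, logical(1))],
                  c("subject", "condition"))
  out <- lapply(vars, function(v) paired_t(pre[[v]], post[[v]], variable = v))
  do.call(rbind, out)
}

#' Permutation-based paired waveform test over the stance
#'
#' A whole-curve paired comparison in the spirit of one-dimensional
#' statistical parametric mapping, with the family-wise threshold obtained by
#' permutation instead of random-field theory: the pointwise paired t
#' trajectory over the (typically 101) stance nodes is compared against the
#' null distribution of the maximum absolute t under random sign flips of the
#' subject difference curves (exact under exchangeability of pre/post labels
#' within subject). The identity flip is always included, so the test is
#' valid at level `alpha`. Supra-threshold clusters are maximal runs of
#' `|t| >` threshold.
#'
#' @param pre,post Matrices (subjects x nodes) of time-normalized curves,
#'   matched by row.
#' @param n_perm Number of sign-flip permutations (>= 100; default 1000).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return A `waveform_test`: list with `t` (node trajectory), `threshold`,
#'   `clusters` (data frame `start_pct`, `end_pct` in percent stance),
#'   `percent` axis, `alpha`, `n_perm`.
#' @export
waveform_paired_test <- function(pre, post, n_perm = 1000L, alpha = 0.05,
                                 seed = 1L) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  if (!all(dim(pre) == dim(post))) stop("pre and post rows must match")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  n <- nrow(pre)
  q <- ncol(pre)
  D <- post - pre

  node_t <- function(M) {
    mu <- colMeans(M)
    v <- (colSums(M^2) - n * mu^2) / (n - 1)
    tv <- mu / sqrt(v / n)
    tv[v <= 0] <- 0
    tv
  }
  t_obs <- node_t(D)

  S <- with_local_seed(seed, {
    m <- matrix(sample(c(-1, 1), (n_perm - 1L) * n, replace = TRUE),
                n_perm - 1L, n)
    rbind(rep(1, n), m)
  })
  mu_perm <- (S %*% D) / n
  e2 <- matrix(colSums(D^2), n_perm, q, byrow = TRUE)
  v_perm <- (e2 - n * mu_perm^2) / (n - 1)
  v_perm[v_perm <= 0] <- Inf
  t_perm <- abs(mu_perm / sqrt(v_perm / n))
  max_t <- apply(t_perm, 1, max)
  threshold <- stats::quantile(max_t, 1 - alpha, type = 1, names = FALSE)

  pct <- seq(0, 100, length.out = q)
  above <- abs(t_obs) > threshold
  clusters <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start_pct = pct[starts[keep]], end_pct = pct[ends[keep]])
  } else {
    data.frame(start_pct = numeric(0), end_pct = numeric(0))
  }
  structure(
    list(t = t_obs, threshold = threshold, clusters = clusters,
         percent = pct, alpha = alpha, n_perm = n_perm),
    class = "waveform_test"
  )
}
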