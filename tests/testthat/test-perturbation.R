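test_that("predictor stats reproduce the published anchors", {
  X <- matrix(c(1.97, 16.58), ncol = 1, dimnames = list(NULL, "ankle_ic"))
  st <- predictor_stats(X)
  expect_equal(st$min, 1.97)
  expect_equal(st$max, 16.58)
  expect_equal(st$dif, 14.61)

  const <- predictor_stats(matrix(rep(4.4, 8), ncol = 1))
  expect_equal(const$dif, 0)
  expect_equal(const$ave, 4.4)
  expect_equal(const$min, const$max)

  set.seed(10)
  x <- rnorm(37)
  st2 <- predictor_stats(matrix(x, ncol = 1))
  expect_equal(st2$ave, mean(x))
  expect_equal(st2$max, max(x))
  expect_equal(st2$min, min(x))
  expect_error(predictor_stats(matrix(numeric(0), 0, 2)), "empty")
})

test_that("formula-faithful grid reproduces interior published cells", {
  g <- build_grid(published_predictor_stats())
  expect_equal(g["min+10%dif", "knee_ic"], 10.58, tolerance = 0.005)
  expect_equal(g["min+50%dif", "ankle_rom"], 51.47, tolerance = 0.005)
  expect_equal(g["min+90%dif", "knee_rom"], 35.59, tolerance = 0.005)
  expect_equal(unname(g["min", ]), published_predictor_stats()$min)
  expect_equal(unname(g["max", ]),
               published_predictor_stats()$min +
                 published_predictor_stats()$dif)
  # all interior cells to +-0.01 for knee IC / ankle ROM / knee ROM, and the
  # published two-decimal rounding for ankle IC differs by at most 0.01
  printed <- rbind(
    c(3.44, 10.58, 28.31, 20.26),
    c(4.90, 12.73, 34.10, 22.18),
    c(6.36, 14.87, 39.89, 24.09),
    c(7.82, 17.01, 45.68, 26.01),
    c(9.28, 19.15, 51.47, 27.93),
    c(10.74, 21.29, 57.25, 29.84),
    c(12.20, 23.43, 63.04, 31.76),
    c(13.66, 25.57, 68.83, 33.68),
    c(15.12, 27.71, 74.62, 35.59)
  )
  rows <- sprintf("min+%d%%dif", seq(10, 90, 10))
  expect_lt(max(abs(g[rows, 2:4] - printed[, 2:4])), 0.0101)
  expect_lt(max(abs(g[rows, 1] - printed[, 1])), 0.0101)
})

test_that("grid levels are linear in the range fraction", {
  st <- published_predictor_stats()
  g <- build_grid(st)
  k <- attr(g, "levels")
  for (jp in seq_len(ncol(g))) {
    d <- diff(g[, jp])
    expect_equal(d, diff(k) * st$dif[jp], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(diff(g[, "ankle_rom"]) > 0))
})

test_that("printed-compat mode changes only the boundary rows", {
  st <- published_predictor_stats()
  gf <- build_grid(st)
  gp <- build_grid(st, mode = "printed-compat")
  expect_equal(gp[2:12, ], gf[2:12, ], ignore_attr = TRUE)
  expect_equal(unname(gp[1, ]), 0.9 * st$min)
  expect_equal(unname(gp[13, ]), 2 * st$max)
  expect_equal(unname(round(gp[1, "knee_ic"], 2)), 7.60)
  expect_equal(unname(round(gp[13, "ankle_ic"], 2)), 33.16)
})

test_that("sensitivity curves are linear and centered for a linear model", {
  set.seed(18)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  B <- matrix(c(1, -2, 0.5, 0, 0.3, 1, -1, 2), 4, 2)
  Y <- X %*% B
  colnames(Y) <- c("y1", "y2")
  m <- plsr_fit(X, Y, ncomp = 4)
  st <- predictor_stats(X)
  g <- build_grid(st)
  curves <- sensitivity_curves(m, st, g)
  # slope along predictor 2 for response 1 equals B[2, 1]
  c21 <- curves[curves$predictor == "x2" & curves$response == "y1", ]
  slopes <- diff(c21$prediction) / diff(c21$value)
  expect_equal(slopes, rep(B[2, 1], length(slopes)), tolerance = 1e-8)

  # a degenerate all-average grid predicts the centroid response everywhere
  st0 <- st
  st0$min <- st0$ave
  st0$dif <- rep(0, 4)
  st0$max <- st0$ave
  g0 <- build_grid(st0)
  curves0 <- sensitivity_curves(m, st0, g0)
  expect_equal(curves0$prediction,
               rep(colMeans(Y)[curves0$response], 1),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("direction summary recovers planted coefficient signs", {
  set.seed(9)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
  B <- matrix(c(1.2, -0.8, 0.6, -1.5,
                -0.9, 1.1, -0.4, 0.7,
                0.5, -0.6, 1.3, -0.2,
                -1.1, 0.9, -0.7, 1.4,
                0.8, -1.2, 0.3, -0.5,
                -0.4, 0.6, -1.0, 1.1), 4, 6)
  Y <- X %*% B + matrix(rnorm(600, sd = 0.1), 100, 6)
  colnames(Y) <- paste0("y", 1:6)
  m <- plsr_fit(X, Y, ncomp = 4)
  st <- predictor_stats(X)
  curves <- sensitivity_curves(m, st, build_grid(st))
  dirs <- direction_summary(curves)
  expect_identical(nrow(dirs), 24L)
  for (r in seq_len(nrow(dirs))) {
    jp <- match(dirs$predictor[r], paste0("x", 1:4))
    jr <- match(dirs$response[r], paste0("y", 1:6))
    expect_identical(dirs$direction[r], if (B[jp, jr] > 0) "+" else "-")
  }
  # direction is invariant to the grid-level choice for a linear model
  dirs2 <- direction_summary(
    sensitivity_curves(m, st, build_grid(st, levels = c(0.2, 0.4, 0.6)))
  )
  expect_identical(dirs$direction, dirs2$direction)

  flat <- curves
  flat$prediction <- 1
  expect_true(all(direction_summary(flat)$direction == "0"))
})
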