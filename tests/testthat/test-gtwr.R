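sim_gtwr_data <- function(n = 120, seed = 1, sd = 0.5,
                          slope_surface = FALSE) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  times <- sample(1:30, n, replace = TRUE)
  x1 <- rnorm(n); x2 <- rnorm(n)
  b1 <- if (slope_surface) 1 + coords[, 1] / 500 else 2
  y <- 3 + b1 * x1 - 1.5 * x2 + rnorm(n, 0, sd)
  list(data = data.frame(y = y, x1 = x1, x2 = x2), coords = coords,
       times = times, b1 = b1)
}

test_that("spatio-temporal weights follow the kernel definitions", {
  g <- st_kernel("gaussian", h = 100, lambda = 4)
  expect_equal(st_weight(0, 0, g), 1)
  expect_equal(st_weight(100, 0, g), exp(-1))
  expect_equal(st_weight(0, 50, g), exp(-4 * 2500 / 1e4))
  # lambda = 0 reduces to a pure spatial weight
  g0 <- st_kernel("gaussian", h = 100, lambda = 0)
  expect_equal(st_weight(60, 999, g0), st_weight(60, 0, g0))
  b <- st_kernel("bisquare", h = 100)
  expect_equal(st_weight(50, 0, b), (1 - 0.25)^2)
  expect_equal(st_weight(120, 0, b), 0)
  expect_error(st_kernel("gaussian", h = -1), "bandwidth")
})

test_that("GTWR with an infinite bandwidth reproduces global OLS", {
  d <- sim_gtwr_data(n = 200, seed = 2)
  fit <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times,
              st_kernel("gaussian", h = 1e9, lambda = 0))
  ols <- lm(y ~ x1 + x2, data = d$data)
  for (j in seq_len(ncol(fit$coefficients)))
    expect_lt(max(abs(fit$coefficients[, j] - coef(ols)[j])), 1e-6)
  expect_lt(max(abs(fitted(fit) - fitted(ols))), 1e-6)
  # same holds for the bisquare kernel in its flat limit
  fitb <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times,
               st_kernel("bisquare", h = 1e9, lambda = 0))
  expect_lt(max(abs(coef(fitb)[, 2] - coef(ols)[2])), 1e-6)
})

test_that("AICc matches an independent reimplementation", {
  d <- sim_gtwr_data(n = 80, seed = 3)
  fit <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times,
              st_kernel("gaussian", h = 400))
  n <- 80
  rss <- sum(residuals(fit)^2)
  trS <- fit$trS
  want <- n * log(rss / n) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
  expect_equal(fit$diagnostics$aicc, want, tolerance = 1e-9)
  expect_gt(trS, 0); expect_lt(trS, n)
  # fitted + residual = observed per row
  expect_equal(fitted(fit) + residuals(fit), d$data$y, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("local weighted-residual orthogonality holds at each fit", {
  d <- sim_gtwr_data(n = 60, seed = 4)
  spec <- st_kernel("gaussian", h = 300)
  mf <- model.frame(y ~ x1 + x2, d$data)
  X <- model.matrix(attr(mf, "terms"), mf); y <- d$data$y
  for (i in c(1, 17, 42)) {
    w <- mslur:::gtwr_weights(d$coords, d$times, d$coords[i, ], d$times[i],
                              spec)
    beta <- mslur:::local_wls(X, y, w)$beta
    r <- y - X %*% beta
    expect_lt(max(abs(crossprod(X, w * r))), 1e-8)
  }
})

test_that("parameter recovery: constant and varying coefficient surfaces", {
  # spatially constant truth: local estimates near the true values
  reps <- vapply(1:10, function(s) {
    d <- sim_gtwr_data(n = 200, seed = s)
    fit <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times,
                st_kernel("gaussian", h = 2000))
    colMeans(coef(fit))
  }, numeric(3))
  mc_mean <- rowMeans(reps); mc_se <- apply(reps, 1, sd) / sqrt(10)
  expect_lt(abs(mc_mean[2] - 2), 2 * mc_se[2] + 0.02)
  expect_lt(abs(mc_mean[3] + 1.5), 2 * mc_se[3] + 0.02)
  # linear-in-x slope surface recovered with r > 0.9
  d <- sim_gtwr_data(n = 400, seed = 77, sd = 0.2, slope_surface = TRUE)
  fit <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times,
              st_kernel("gaussian", h = 250))
  expect_gt(cor(coef(fit)[, "x1"], d$b1), 0.9)
})

test_that("bandwidth selection tracks the coefficient structure", {
  h_grid <- c(200, 400, 800, 1600, 1e6)
  # globally linear data: the seed-averaged AICc profile decreases with h,
  # so the largest bandwidth is preferred on average
  profs <- vapply(1:6, function(s) {
    d <- sim_gtwr_data(n = 120, seed = s)
    bw <- select_bandwidth(y ~ x1 + x2, d$data, d$coords, d$times,
                           h_grid = h_grid, refine = FALSE)
    bw$profile$aicc
  }, numeric(length(h_grid)))
  expect_true(all(diff(rowMeans(profs)) < 0))
  d_var <- sim_gtwr_data(n = 300, seed = 6, sd = 0.2, slope_surface = TRUE)
  bw2 <- select_bandwidth(y ~ x1 + x2, d_var$data, d_var$coords,
                          d_var$times, h_grid = h_grid)
  expect_lt(bw2$spec$h, 1e6)       # varying coefficients pull h down
  d_const <- sim_gtwr_data(n = 100, seed = 5)
  single <- select_bandwidth(y ~ x1, d_const$data, d_const$coords,
                             d_const$times, h_grid = 500, lambda_grid = 2)
  expect_equal(single$spec$h, 500)
  expect_equal(single$spec$lambda, 2)
})

test_that("LOOCV behaves like an honest out-of-sample measure", {
  # noiseless linear data with a flat kernel: CV R2 = 1 - eps
  set.seed(7)
  n <- 40
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  dat <- data.frame(x1 = rnorm(n))
  dat$y <- 1 + 2 * dat$x1
  cv <- loocv(y ~ x1, dat, coords, rep(1, n), st_kernel("gaussian", 1e9))
  expect_gt(cv, 1 - 1e-6)
  # CV R2 never beats the in-sample R2
  for (s in 1:5) {
    d <- sim_gtwr_data(n = 60, seed = s)
    spec <- st_kernel("gaussian", h = 400)
    fit <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times, spec)
    cv <- loocv(y ~ x1 + x2, d$data, d$coords, d$times, spec)
    expect_lte(cv, fit$diagnostics$r2 + 1e-9)
  }
  expect_error(loocv(y ~ x1, dat[1:5, ], coords[1:5, ], rep(1, 5),
                     st_kernel("gaussian", 1)), "at least 10")
})

test_that("prediction at a calibration point with its weights matches the fit", {
  d <- sim_gtwr_data(n = 50, seed = 8)
  spec <- st_kernel("gaussian", h = 300)
  fit <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times, spec)
  pred <- predict(fit, d$data[7, ], d$coords[7, , drop = FALSE], d$times[7])
  expect_equal(pred, fitted(fit)[7], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("surface prediction honours grids, nodata and missing predictors", {
  set.seed(9)
  n <- 30
  coords <- cbind(runif(n, 5, 95), runif(n, 5, 95))
  dat <- data.frame(x1 = rnorm(n))
  dat$y <- 2 + 0.5 * dat$x1 + rnorm(n, 0, 0.01)
  fit <- gtwr(y ~ x1, dat, coords, rep(1, n), st_kernel("gaussian", 200))
  g <- raster_grid(matrix(1.5, 10, 10), 0, 0, 10)
  surf <- predict_surface(fit, list(x1 = g), time = 1)
  expect_true(all(abs(grid_values(surf) -
                        (coef(fit)[1, 1] + 1.5 * 0.5)) < 0.2))
  hole <- grid_set_values(g, {
    v <- matrix(1.5, 10, 10); v[3, 3] <- NA; v
  })
  surf2 <- predict_surface(fit, list(x1 = hole), time = 1)
  expect_true(is.na(grid_values(surf2)[3, 3]))
  expect_error(predict_surface(fit, list(zz = g), 1), "missing predictor")
  # constant predictor grids give a near-constant map
  rng <- range(grid_values(surf), na.rm = TRUE)
  expect_lt(diff(rng), 0.05)
})

test_that("gtwr S3 surface behaves", {
  d <- sim_gtwr_data(n = 50, seed = 10)
  fit <- gtwr(y ~ x1 + x2, d$data, d$coords, d$times,
              st_kernel("gaussian", 500))
  expect_output(print(fit), "GTWR fit")
  expect_output(print(summary(fit)), "local coefficients")
  expect_equal(dim(coef(fit)), c(50L, 3L))
  expect_error(gtwr(y ~ x1 + x2, d$data[1:4, ], d$coords[1:4, ],
                    d$times[1:4], st_kernel("gaussian", 10)), "too few")
})
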