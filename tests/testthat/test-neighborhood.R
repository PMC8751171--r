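test_that("the humidity correction follows the growth-factor formula", {
  expect_equal(rh_correction_factor(0), 1)
  expect_equal(rh_correction_factor(0.5), 1.125)
  expect_equal(rh_correction_factor(0.8), 1.8)
  expect_equal(rh_correct(22.5, 0.5), 20)
  expect_equal(rh_correct(10, 0), 10)
  expect_true(all(diff(rh_correction_factor(seq(0, 0.95, 0.05))) > 0))
  expect_error(rh_correct(10, 1), "singular")
  expect_error(rh_correct(10, -0.1), "singular")
})

test_that("synthetic RH inflation is exactly undone by the correction", {
  set.seed(1)
  field <- runif(500, 5, 80)
  RH <- runif(500, 0, 0.9)
  raw <- field * rh_correction_factor(RH)     # generator's inverse model
  expect_equal(rh_correct(raw, RH), field, tolerance = 1e-12)
})

test_that("background adjustment removes drift and keeps the campaign mean", {
  set.seed(2)
  samples <- data.frame(pm = rnorm(200, 30, 5),
                        hour = sample(1:10, 200, replace = TRUE))
  bg <- data.frame(hour = 1:10, pm25 = 20 + rnorm(10, 0, 3))
  adj <- background_adjust(samples, bg)
  expect_equal(mean(adj$pm), mean(samples$pm), tolerance = 1e-9)
  # constant background changes nothing
  bgc <- data.frame(hour = 1:10, pm25 = rep(22, 10))
  expect_equal(background_adjust(samples, bgc)$pm, samples$pm)
  # an hour 5 above the campaign mean is reduced by 5
  bg2 <- data.frame(hour = 1:2, pm25 = c(20, 25))
  s2 <- data.frame(pm = c(10, 10), hour = c(1, 2))
  a2 <- background_adjust(s2, bg2)
  expect_equal(a2$pm, c(10 + 2.5, 10 - 2.5))
  expect_error(background_adjust(data.frame(pm = 1, hour = 99), bg),
               "missing sample hour")
  # ratio mode is available as an option
  ar <- background_adjust(s2, bg2, ratio = TRUE)
  expect_equal(ar$pm, c(10 * 22.5 / 20, 10 * 22.5 / 25))
})

test_that("delta responses are site-relative with zero site means", {
  s <- data.frame(site = rep(c("a", "b"), each = 40),
                  pm = c(rnorm(40, 20), rnorm(40, 35)))
  d <- delta_pm25(s)
  expect_equal(as.numeric(tapply(d$dpm25, d$site, mean)), c(0, 0),
               tolerance = 1e-9)
  two <- data.frame(site = "a", pm = c(10, 20))
  expect_warning(d2 <- delta_pm25(two), "below")
  expect_equal(d2$dpm25, c(-5, 5))
  expect_error(delta_pm25(data.frame(site = "a", pm = 1)), "fewer than 2")
})

test_that("samples snap to the nearest segment within the threshold", {
  roads <- road_graph_from_segments(
    list(rbind(c(0, 0), c(100, 0)), rbind(c(0, 50), c(100, 50))),
    c("trunk", "ordinary"))
  ns <- nearest_segment(roads, c(50, 50, 50), c(2, 48, -30), max_dist = 25)
  expect_equal(ns$segment[1:2], c(1L, 2L))
  expect_true(is.na(ns$segment[3]))   # 30 m away with a 25 m threshold
})

test_that("attached samples inherit segment metrics and local morphology", {
  cfg <- tiny_config(seed = 6)
  scene <- generate_scene(cfg)
  metrics <- suppressWarnings(segment_metrics(scene$roads))
  e <- scene$roads$edges[1, ]
  mid <- colMeans(e$geometry[[1]])
  dirv <- (e$geometry[[1]][2, ] - e$geometry[[1]][1, ])
  dirv <- dirv / sqrt(sum(dirv^2))
  samples <- data.frame(x = c(mid[1], mid[1] + 5 * dirv[1], 1e6),
                        y = c(mid[2], mid[2] + 5 * dirv[2], 1e6),
                        site = 1)
  expect_message(
    out <- attach_neighborhood_predictors(samples, scene, metrics),
    "dropped")
  expect_equal(nrow(out), 2)
  expect_equal(out$segment[1], out$segment[2])
  expect_equal(out$BETWEEN[1], out$BETWEEN[2])
  expect_true(all(is.finite(out$SVF)))
  expect_true(all(out$SVF >= 0 & out$SVF <= 1))
})

test_that("delta MLR recovers planted morphology effects and screens decoys", {
  set.seed(20)
  n <- 600
  tab <- data.frame(SVF = runif(n, 0.3, 1), FAI_POINT = runif(n, 0, 0.4),
                    STRAIGHT = runif(n), BETWEEN = runif(n),
                    CONTROL = runif(n))
  tab$dpm25 <- 3 * tab$FAI_POINT - 12 * tab$SVF + rnorm(n, 0, 0.4)
  tab$dpm25 <- tab$dpm25 - mean(tab$dpm25)
  fit <- fit_delta_mlr(tab, candidates = names(tab)[1:5])
  expect_true(all(c("SVF", "FAI_POINT") %in% fit$selection$selected))
  expect_lt(coef(fit)[["SVF"]], 0)
  expect_gt(coef(fit)[["FAI_POINT"]], 0)
  expect_setequal(fit$selection$selected, c("SVF", "FAI_POINT"))
  # stored ranges bound every training value
  expect_true(all(tab$SVF >= fit$ranges[1, "SVF"] &
                    tab$SVF <= fit$ranges[2, "SVF"]))
})

test_that("permuted responses rarely pass the screen", {
  set.seed(21)
  hits <- 0
  for (s in 1:10) {
    n <- 200
    tab <- data.frame(SVF = runif(n), FAI_POINT = runif(n), X = runif(n))
    tab$dpm25 <- sample(3 * tab$SVF + rnorm(n))
    fit <- fit_delta_mlr(tab, candidates = c("SVF", "FAI_POINT", "X"))
    hits <- hits + (length(fit$selection$selected) > 0)
  }
  expect_lte(hits, 4)
  # all-zero response: intercept-only model with zero R2
  tab0 <- data.frame(SVF = runif(50), dpm25 = rep(0, 50))
  f0 <- fit_delta_mlr(tab0, candidates = "SVF")
  expect_equal(length(f0$selection$selected), 0)
  expect_equal(f0$r2, 0)
})

test_that("within-site centring identifies effects under site confounding", {
  # two sites with opposite between-site offsets that would mask the
  # within-site SVF effect without centring
  set.seed(22)
  n <- 400
  site <- rep(1:2, each = n / 2)
  svf <- runif(n, 0.4, 1) + ifelse(site == 1, 0.5, -0.2)
  pm <- -8 * svf + rnorm(n, 0, 0.5)
  tab <- data.frame(site = site, pm = pm, SVF = svf)
  tab <- delta_pm25(tab)
  fit <- fit_delta_mlr(tab, candidates = "SVF")
  expect_true("SVF" %in% fit$selection$selected)
  expect_lt(abs(coef(fit)[["SVF"]] + 8), 1)
})
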