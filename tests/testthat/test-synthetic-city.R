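test_that("scene generation is deterministic and hits class fractions", {
  cfg <- tiny_config(seed = 7)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$landuse$values, s2$landuse$values)
  expect_identical(s1$stations, s2$stations)
  expect_identical(vapply(s1$buildings, `[[`, 0, "height"),
                   vapply(s2$buildings, `[[`, 0, "height"))
  frac <- tabulate(grid_values(s1$landuse), 5) / prod(dim(s1$landuse))
  want <- c(0.30, 0.10, 0.10, 0.10, 0.40)
  expect_true(all(abs(frac - want) <= 0.02))
})

test_that("scene respects its structural invariants", {
  cfg <- default_city_config(seed = 3)
  s <- generate_scene(cfg)
  # buildings only on built classes (by footprint centroid)
  lu <- grid_values(s$landuse)
  for (b in s$buildings[seq(1, length(s$buildings), by = 25)]) {
    ctr <- polygon_centroid(b$xy)
    rc <- world_to_cell(s$landuse, ctr[1], ctr[2])
    expect_true(lu[rc$row, rc$col] != LANDUSE_CLASSES[["open"]])
    expect_gt(b$height, 0)
  }
  # road classes span all five types
  expect_setequal(unique(s$roads$edges$class),
                  c("trunk", "primary", "secondary", "tertiary", "ordinary"))
  expect_gte(nrow(s$stations), 8)
  # an extent too small for the radius series errors
  expect_error(pipeline_config(buffer_radii = c(50, 2000), extent = 500),
               "too small")
})

test_that("the truth field follows its generative formula", {
  cfg <- tiny_config(seed = 8)
  scene <- generate_scene(cfg)
  # all strengths and gradients zero -> spatially constant field off roads
  p0 <- truth_params(gradient = c(x = 0, y = 0), strengths = c(),
                     svf_coef = 0, fai_coef = 0)
  tr0 <- simulate_truth(scene, p0, cfg)
  f <- grid_values(truth_field(tr0, 3))
  expect_lt(diff(range(f)), 1e-9)
  expect_equal(f[1, 1], max(tr0$background[3], p0$floor), tolerance = 1e-12)
  # doubling a strength doubles that contribution at a probe cell
  p1 <- truth_params(gradient = c(x = 0, y = 0),
                     strengths = c(residential = 10),
                     class_radii = c(residential = 100),
                     svf_coef = 0, fai_coef = 0)
  p2 <- truth_params(gradient = c(x = 0, y = 0),
                     strengths = c(residential = 20),
                     class_radii = c(residential = 100),
                     svf_coef = 0, fai_coef = 0)
  t1 <- simulate_truth(scene, p1, cfg)
  t2 <- simulate_truth(scene, p2, cfg)
  c1 <- grid_values(t1$static) - mean(t1$background) * 0  # static only
  c2 <- grid_values(t2$static)
  probe <- c(20, 31)
  expect_equal(c2[probe[1], probe[2]], 2 * c1[probe[1], probe[2]],
               tolerance = 1e-9)
})

test_that("AR(1)=0 backgrounds are serially uncorrelated", {
  cfg <- pipeline_config(seed = 9, buffer_radii = c(50, 100),
                         extent = 600, aod_cell = 200,
                         days_per_season = 100, seasons = c("a", "b"))
  scene <- generate_scene(cfg, n_stations = 8)
  tr <- simulate_truth(scene, truth_params(ar1 = 0, bg_sd = 3), cfg)
  x <- tr$background[tr$days$season == "a"]
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 2 / sqrt(length(x)) + 0.05)
})

test_that("noise-free observations reproduce the field exactly", {
  cfg <- tiny_config(seed = 10)
  scene <- generate_scene(cfg)
  p <- truth_params(sigma_station = 0, sigma_aod = 0, sigma_mobile = 0,
                    sigma_site = 0, aod_a = 1, aod_b = 0,
                    cloud_fraction = 0, diurnal_amp = 0)
  tr <- simulate_truth(scene, p, cfg)
  obs <- sample_observations(tr, scene, p, cfg, n_sites = 4,
                             samples_per_site = 60)
  # station series equal the field at the station cell
  st <- scene$stations
  day1 <- obs$stations[obs$stations$day == 1, ]
  f1 <- grid_values(truth_field(tr, 1))
  rc <- world_to_cell(scene$landuse, st$x, st$y)
  expect_equal(day1$pm25, f1[cbind(rc$row, rc$col)], tolerance = 1e-9)
  # AOD pixels equal the pixel-mean city-scale field under a unit link
  a1 <- grid_values(obs$aod[[1]]$terra$aod)
  blocks <- as.integer(round(cfg$extent / cfg$aod_cell))
  fac <- as.integer(cfg$aod_cell / cfg$cell_size)
  cm <- grid_values(tr$static_city) + tr$background[1]
  bm <- t(rowsum(t(rowsum(cm, rep(1:blocks, each = fac))),
                 rep(1:blocks, each = fac))) / fac^2
  expect_equal(a1, unname(bm), tolerance = 1e-9, ignore_attr = TRUE)
  # mobile raw data are the field inflated by the RH correction factor
  mob <- obs$mobile
  rcm <- world_to_cell(scene$landuse, mob$x, mob$y)
  fld <- grid_values(tr$static)[cbind(rcm$row, rcm$col)] +
    tr$background[mob$day]
  fld <- pmax(fld, tr$floor)
  expect_equal(mob$pm_raw, fld * rh_correction_factor(mob$RH),
               tolerance = 1e-9)
  # and the correction restores the field exactly
  expect_equal(rh_correct(mob$pm_raw, mob$RH), fld, tolerance = 1e-9)
})

test_that("a fully cloudy sky flags every non-coastal pixel", {
  cfg <- tiny_config(seed = 11)
  scene <- generate_scene(cfg)
  p <- truth_params(cloud_fraction = 1)
  tr <- simulate_truth(scene, p, cfg)
  obs <- sample_observations(tr, scene, p, cfg, n_sites = 3,
                             samples_per_site = 60)
  sc <- obs$aod[[1]]$terra
  expect_true(all(sc$qa_cloud == "Cloudy"))
  filt <- qa_filter(sc)
  kept <- !is.na(grid_values(filt$aod))
  expect_identical(unname(kept), unname(sc$coastline))
})

test_that("mobile tracks stay on the road network at walking pace", {
  cfg <- tiny_config(seed = 12)
  scene <- generate_scene(cfg)
  p <- truth_params()
  tr <- simulate_truth(scene, p, cfg)
  obs <- sample_observations(tr, scene, p, cfg, n_sites = 3,
                             samples_per_site = 120)
  ns <- nearest_segment(scene$roads, obs$mobile$x, obs$mobile$y,
                        max_dist = cfg$snap_distance)
  expect_true(all(!is.na(ns$segment)))
  # 1-s cadence at 0.8 m/s: consecutive same-site steps are 0.8 m apart
  m1 <- obs$mobile[obs$mobile$site == 1, ]
  gap <- sqrt(diff(m1$x)^2 + diff(m1$y)^2)
  expect_lt(median(gap), 0.81)
  expect_gt(median(gap), 0.79)
})
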