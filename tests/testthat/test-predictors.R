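lu_grid <- function(vals, cellsize = 10) raster_grid(vals, 0, 0, cellsize)

test_that("areal fraction counts cell centers inside the circle", {
  n <- 20
  homog <- lu_grid(matrix(LANDUSE_CLASSES[["residential"]], n, n))
  expect_equal(areal_fraction(homog, c(100, 100), 50, "residential"), 1)
  expect_equal(areal_fraction(homog, c(100, 100), 50, "commercial"), 0)
  # raster split in half through the buffer center
  half <- matrix(LANDUSE_CLASSES[["residential"]], n, n)
  half[, 1:(n / 2)] <- LANDUSE_CLASSES[["open"]]
  hg <- lu_grid(half)
  f <- areal_fraction(hg, c(100, 100), 60, "residential")
  expect_lt(abs(f - 0.5), 0.1)   # one cell-row quantisation allowed
  expect_error(areal_fraction(homog, c(1e5, 1e5), 50, "residential"),
               "no raster cells")
  expect_warning(areal_fraction(homog, c(5, 5), 50, "residential"),
                 "beyond the raster")
})

test_that("line density equals clipped length over circle area", {
  r <- 100
  road <- road_graph_from_segments(list(rbind(c(-500, 0), c(500, 0))),
                                   "trunk")
  got <- line_density(road, c(0, 0), r, "trunk")
  expect_equal(got, (2 * r / 1000) / (pi * (r / 1000)^2), tolerance = 1e-9)
  # doubling the radius with one diameter road halves the density
  expect_equal(line_density(road, c(0, 0), 2 * r, "trunk"),
               got / 2, tolerance = 1e-9)
  expect_equal(line_density(road, c(0, 0), r, "ordinary"), 0)
  none <- road_graph_from_segments(list(rbind(c(900, 900), c(950, 900))),
                                   "trunk")
  expect_equal(line_density(none, c(0, 0), 100, "trunk"), 0)
})

test_that("point counts are boundary inclusive", {
  pts <- data.frame(x = c(0, 30, 50, 80), y = c(0, 40, 0, 0))
  expect_equal(point_count(pts[0, ], c(0, 0), 50), 0L)
  expect_equal(point_count(pts, c(0, 0), 50), 3L)  # (30,40) at exactly 50 counts
  expect_equal(point_count(pts, c(0, 0), 79.9), 3L)
})

test_that("buffer point counts are monotone in the radius", {
  set.seed(4)
  pts <- data.frame(x = runif(50, 0, 500), y = runif(50, 0, 500))
  cnt <- vapply(c(50, 100, 200, 300), function(r)
    point_count(pts, c(250, 250), r), 0)
  expect_true(all(diff(cnt) >= 0))
})

test_that("grid evaluators agree with the buffer operations at cell centers", {
  cfg <- tiny_config(seed = 5)
  scene <- generate_scene(cfg)
  st <- scene$stations
  grids <- predictor_grids(scene, cols = c("RES_100", "OPN_200", "BUS_100",
                                           "POP_100", "ROUGH_200"),
                           rose = scene$rose)
  for (i in 1:5) {
    ctr <- c(st$x[i], st$y[i])
    expect_equal(grid_sample(grids$RES_100, ctr[1], ctr[2]),
                 areal_fraction(scene$landuse, ctr, 100, "residential"),
                 tolerance = 1e-8)
    expect_equal(grid_sample(grids$OPN_200, ctr[1], ctr[2]),
                 areal_fraction(scene$landuse, ctr, 200, "open"),
                 tolerance = 1e-8)
    expect_equal(grid_sample(grids$BUS_100, ctr[1], ctr[2]),
                 point_count(scene$bus_stops, ctr, 100), tolerance = 1e-6)
  }
})

test_that("the assembled table has the documented row/column structure", {
  cfg <- tiny_config(seed = 3)
  res <- lur_pipeline(cfg, truth_params(cloud_fraction = 0),
                      through = "predictors")
  tab <- res$table
  # 16 stations x 2 seasons, no gaps under a cloud-free sky
  expect_equal(nrow(tab), 32)
  expect_true(all(!is.na(tab$AOD)))
  sch <- attr(tab, "schema")
  expect_true(all(c("AOD", "LONG", "LAT") %in% sch$col))
  # class fractions partition to 1 at every radius
  for (r in cfg$buffer_radii) {
    tot <- rowSums(tab[, paste0(c("RES", "COM", "IND", "GOV", "OPN"),
                                "_", r)])
    expect_equal(tot, rep(1, nrow(tab)), tolerance = 1e-9)
  }
  expect_true(all(tab$POP_100 >= 0))
  # recomputing the table from the same inputs is bit-identical
  res2 <- lur_pipeline(cfg, truth_params(cloud_fraction = 0),
                       through = "predictors")
  expect_identical(tab, res2$table)
})

test_that("stations without AOD coverage are dropped with a message", {
  # under a fully cloudy sky only the coastal QA band retains AOD, so every
  # station away from the coast loses its rows
  cfg <- tiny_config(seed = 3)
  expect_message(
    res <- lur_pipeline(cfg, truth_params(cloud_fraction = 1),
                        through = "predictors"),
    "dropped")
  scene <- generate_scene(cfg)
  n_coastal <- sum(scene$stations$y <= scene$coast_band +
                     cfg$aod_cell)  # stations whose pixel touches the band
  expect_lte(nrow(res$table), 2 * n_coastal)
  expect_lt(nrow(res$table), 32)
})
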