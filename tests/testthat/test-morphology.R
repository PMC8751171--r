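test_that("frontal area index matches the cube worked example", {
  cube <- list(make_building(50, 50, 10, 10, 10))
  # all wind from one cardinal direction: A_F = 100 m2 over a 1e4 m2 lot
  north <- windrose(c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(frontal_area_index(cube, 100 * 100, north), 0.01)
  # uniform rose: diagonal silhouettes are sqrt(2) wider, oracle value frozen
  expect_equal(frontal_area_index(cube, 1e4, windrose()),
               50 * (1 + sqrt(2)) / 1e4, tolerance = 1e-9)
  expect_equal(frontal_area_index(list(), 1e4, north), 0)
  expect_error(frontal_area_index(cube, 0, north), "lot area")
})

test_that("silhouette occlusion merges overlapping frontal areas", {
  # two cubes in file along the flow: silhouette = one cube, sum = two
  b <- list(make_building(30, 30, 10, 10, 10),
            make_building(30, 60, 10, 10, 10))
  north <- windrose(c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(frontal_area_index(b, 1e4, north, occlusion = TRUE), 0.01)
  expect_equal(frontal_area_index(b, 1e4, north, occlusion = FALSE), 0.02)
  # a taller building behind still shows its top slab
  b2 <- list(make_building(30, 30, 10, 10, 10),
             make_building(30, 60, 10, 10, 25))
  expect_equal(frontal_area_index(b2, 1e4, north), (10 * 25) / 1e4)
})

test_that("buffered FAI uses the circle as lot and is linear in height", {
  cube <- list(make_building(0, 0, 10, 10, 10))
  north <- windrose(c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(buffered_fai(cube, c(0, 0), 250, north),
               100 / (pi * 250^2), tolerance = 1e-12)
  expect_equal(buffered_fai(list(), c(0, 0), 100, north), 0)
  tall <- list(make_building(0, 0, 10, 10, 20))
  expect_equal(buffered_fai(tall, c(0, 0), 250, north),
               2 * buffered_fai(cube, c(0, 0), 250, north))
  # outside the buffer -> excluded
  expect_equal(buffered_fai(cube, c(500, 0), 250, north), 0)
})

test_that("decay weight follows ((R-l)/R)^c", {
  expect_equal(decay_weight(0, 200, 2), 1)
  expect_equal(decay_weight(200, 200, 2), 0)
  expect_equal(decay_weight(100, 200, 2), 0.25)
  expect_equal(decay_weight(250, 200, 2), 0)    # outside the circle
  l <- seq(0, 200, by = 10)
  expect_true(all(diff(decay_weight(l, 200, 2)) < 0))
  expect_error(decay_weight(10, -1, 2), "R and c")
})

test_that("point FAI converges to the fine-grid integral", {
  cube <- list(make_building(100, 0, 12, 12, 30))
  rose <- windrose()
  got <- point_fai(cube, c(0, 0), point_fai_params(R = 200, c = 2, step = 2),
                   rose)
  want <- oracle_point_fai(cube, c(0, 0), 200, 2, 1, rose)
  expect_lt(abs(got - want) / want, 0.01)
  # halving the step moves the value by well under 1%
  # halving the default step moves the value by well under 1%
  got1 <- point_fai(cube, c(0, 0), point_fai_params(R = 200, c = 2, step = 1),
                    rose)
  expect_lt(abs(got - got1) / got1, 0.01)
  expect_equal(point_fai(list(), c(0, 0)), 0)
  expect_error(point_fai_params(R = 200, step = 30), "too coarse")
})

test_that("adding a building strictly increases point FAI", {
  b1 <- list(make_building(60, 40, 10, 10, 15))
  v1 <- point_fai(b1, c(0, 0))
  v2 <- point_fai(c(b1, list(make_building(-50, -30, 10, 10, 20, id = 2))),
                  c(0, 0))
  expect_gt(v2, v1)
})

test_that("point FAI with no decay reduces to the unoccluded buffered density", {
  b <- list(make_building(60, 0, 10, 10, 15),
            make_building(-40, 70, 12, 8, 22, id = 2))
  east <- windrose(c(0, 0, 1, 0, 0, 0, 0, 0))
  flat <- point_fai(b, c(0, 0), point_fai_params(R = 150, c = 1e-9, step = 1),
                    east)
  want <- buffered_fai(b, c(0, 0), 150, east, occlusion = FALSE)
  expect_lt(abs(flat - want) / want, 0.01)
})

test_that("sky view factor handles the canonical horizons", {
  expect_equal(sky_view_factor(flat_dsm(), c(30, 30)), 1)
  # fully enclosed: towering wall all around at the adjacent cells
  g <- flat_dsm(21, 1)
  v <- matrix(1e6, 21, 21); v[11, 11] <- 0
  enc <- grid_set_values(g, v)
  expect_lt(sky_view_factor(enc, c(10.5, 10.5), svf_params(d = 5)), 1e-6)
  # uniform 45-degree horizon -> cos^2(45) = 0.5
  # the discrete ring quantises the 45-degree horizon slightly
  ring <- ring_dsm(45)
  expect_equal(sky_view_factor(ring, c(20.5, 20.5), svf_params(16, d = 18)),
               0.5, tolerance = 0.04)
  expect_error(sky_view_factor(flat_dsm(), c(-5, 3)), "outside")
})

test_that("SVF matches Monte-Carlo hemisphere ray casting on canyons", {
  fixtures <- list(
    ring_dsm(45),
    ring_dsm(30, r = 8),
    {
      g <- flat_dsm(41, 1)
      v <- matrix(0, 41, 41)
      v[, 1:15] <- 12; v[, 27:41] <- 20      # asymmetric street canyon
      grid_set_values(g, v)
    })
  for (g in fixtures) {
    p <- c(20.5, 20.5)
    got <- sky_view_factor(g, p, svf_params(n_azimuths = 256, d = 20))
    mc <- oracle_svf_mc(g, p, n_rays = 1e5, d_max = 20)
    expect_lt(abs(got - mc), 0.01)
  }
})

test_that("SVF is monotone non-increasing as the DSM rises", {
  g <- ring_dsm(30)
  base <- sky_view_factor(g, c(20.5, 20.5), svf_params(16, d = 18))
  v <- grid_values(g); v[25, 25] <- v[25, 25] + 15
  higher <- sky_view_factor(grid_set_values(g, v), c(20.5, 20.5),
                            svf_params(16, d = 18))
  expect_lte(higher, base)
})

test_that("roughness length is a tenth of mean building height", {
  expect_equal(roughness_length(list(), c(0, 0), 100), 0)
  b10 <- list(make_building(10, 0, 8, 8, 10))
  expect_equal(roughness_length(b10, c(0, 0), 100), 1.0)
  mix <- c(b10, list(make_building(-10, 0, 8, 8, 30, id = 2)))
  expect_equal(roughness_length(mix, c(0, 0), 100), 2.0)
  # centroid-in-circle rule
  expect_equal(roughness_length(mix, c(200, 0), 100), 0)
})

test_that("morphology indices are translation invariant", {
  b <- list(make_building(20, -10, 10, 14, 18))
  shift <- function(bb, dx, dy) {
    bb$xy <- bb$xy + matrix(c(dx, dy), 4, 2, byrow = TRUE); bb
  }
  rose <- windrose()
  expect_equal(point_fai(b, c(0, 0), point_fai_params(step = 5), rose),
               point_fai(list(shift(b[[1]], 500, 300)), c(500, 300),
                         point_fai_params(step = 5), rose), tolerance = 1e-12)
  expect_equal(buffered_fai(b, c(0, 0), 100, rose),
               buffered_fai(list(shift(b[[1]], 123, -77)), c(123, -77), 100,
                            rose), tolerance = 1e-12)
})
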