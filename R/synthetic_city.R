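#' Synthetic study area
#'
#' A seeded, fully synthetic compact city with the statistical structure the
#' two-stage analysis assumes: a five-class land-use raster at the working
#' resolution, rectangular buildings with heights on the built classes (and
#' the derived DSM), a jittered grid street network spanning all five road
#' classes, long-term monitoring stations snapped to cell centers, weather
#' stations, bus stops, a population-density raster, and a coastal band along
#' the southern edge. Everything is drawn from one seeded generator, so a
#' given configuration reproduces the scene bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param fractions named land-use target fractions (must sum to 1); the
#'   rasterised fractions land within about 2 % of these targets.
#' @param n_stations number of long-term monitors (>= 8).
#' @param n_weather number of weather stations (>= 4).
#' @param n_bus number of bus stops.
#' @param n_buildings number of buildings.
#' @param rose scene [windrose()] (prevailing wind used for FAI predictors).
#' @param landuse_scale correlation length (m) of the land-use patch pattern.
#' @return an object of class `city_scene`.
#' @export
generate_scene <- function(config,
                           fractions = c(residential = 0.30, commercial = 0.10,
                                         industrial = 0.10, government = 0.10,
                                         open = 0.40),
                           n_stations = 16, n_weather = 8, n_bus = 120,
                           n_buildings = 1200,
                           rose = windrose(c(0.05, 0.10, 0.25, 0.20,
                                             0.10, 0.10, 0.10, 0.10)),
                           landuse_scale = 100) {
  validate_config(config)
  if (abs(sum(fractions) - 1) > 1e-9) stop("land-use fractions must sum to 1")
  if (n_stations < 8) stop("need at least 8 stations")
  set.seed(config$seed)
  cs <- config$cell_size
  n <- as.integer(round(config$extent / cs))
  tpl <- raster_grid(matrix(0, n, n), 0, 0, cs, crs = "LOCAL:metre")

  # -- land use: smoothed noise fields per class, bias-tuned to the targets
  fl <- lapply(seq_along(fractions), function(k)
    smooth_field(n, n, landuse_scale / cs))
  bias <- rep(0, length(fractions))
  lu <- NULL
  for (it in 1:60) {
    sc <- mapply(function(f, b) f + b, fl, bias, SIMPLIFY = FALSE)
    lu <- matrix(max.col(do.call(cbind, lapply(sc, as.vector))), n, n)
    frac <- tabulate(lu, length(fractions)) / (n * n)
    err <- fractions - frac
    if (max(abs(err)) < 0.015) break
    bias <- bias + 1.5 * err
  }
  codes <- LANDUSE_CLASSES[names(fractions)]
  lum <- matrix(codes[lu], n, n)
  landuse <- grid_set_values(tpl, lum)

  # -- road network: jittered grid streets, classes assigned per street
  street_x <- seq(200, config$extent - 200, by = 200)
  street_y <- street_x
  ni <- length(street_x)
  jit <- function(k) stats::runif(k, -15, 15)
  nx <- outer(street_x, rep(1, ni)) + matrix(jit(ni * ni), ni)
  ny <- outer(rep(1, ni), street_y) + matrix(jit(ni * ni), ni)
  cls_of <- function(i) {
    mid <- (ni + 1) / 2
    d <- abs(i - mid)
    c("trunk", "primary", "secondary", "tertiary")[pmin(d + 1, 4)] ->
      cl
    if (d > 3) "ordinary" else cl
  }
  geoms <- list(); cls <- character()
  for (i in seq_len(ni)) for (j in seq_len(ni - 1)) {   # vertical pieces
    geoms[[length(geoms) + 1]] <- rbind(c(nx[i, j], ny[i, j]),
                                        c(nx[i, j + 1], ny[i, j + 1]))
    cls <- c(cls, cls_of(i))
  }
  for (j in seq_len(ni)) for (i in seq_len(ni - 1)) {   # horizontal pieces
    geoms[[length(geoms) + 1]] <- rbind(c(nx[i, j], ny[i, j]),
                                        c(nx[i + 1, j], ny[i + 1, j]))
    cls <- c(cls, cls_of(j))
  }
  roads <- road_graph_from_segments(geoms, cls)

  # -- stations (snapped to cell centers, spread out), weather stations.
  # Ambient monitors are sited off the road corridor, as in routine networks.
  rl <- road_length_raster(roads, tpl)
  corridor <- conv2_same((rl > 0) * 1, matrix(1, 3, 3)) > 0.5
  stations <- scatter_points(tpl, n_stations, min_sep = 0.15 * config$extent,
                             exclude = corridor)
  stations$id <- seq_len(nrow(stations))
  weather <- scatter_points(tpl, n_weather, min_sep = 0.20 * config$extent,
                            exclude = corridor)
  weather$id <- seq_len(nrow(weather))

  # -- bus stops along roads
  seg_pick <- sample.int(nrow(roads$edges), n_bus, replace = TRUE,
                         prob = roads$edges$length)
  tt <- stats::runif(n_bus)
  bus <- do.call(rbind, lapply(seq_len(n_bus), function(k) {
    g <- roads$edges$geometry[[seg_pick[k]]]
    p <- g[1, ] + tt[k] * (g[2, ] - g[1, ])
    data.frame(id = k, x = p[1], y = p[2])
  }))

  # -- buildings on built land, fronting the streets (only the carriageway
  # cells themselves are kept clear) so street canyons form
  built <- lum %in% codes[c("residential", "commercial", "industrial",
                            "government")]
  cand <- which(matrix(built, n, n) & !(rl > 0), arr.ind = TRUE)
  # block-scale density contrast: dense and sparse blocks, so morphology
  # varies strongly between neighbouring streets
  blockf <- smooth_field(n, n, 30)
  wcand <- exp(1.8 * blockf[cand])
  cand <- cand[sample.int(nrow(cand), min(n_buildings, nrow(cand)),
                          prob = wcand), , drop = FALSE]
  hmean <- c(residential = 20, commercial = 38, industrial = 12,
             government = 24)
  cw <- cell_to_world(tpl, cand[, 1], cand[, 2])
  buildings <- lapply(seq_len(nrow(cand)), function(k) {
    w <- stats::runif(1, 10, 18) / 2; d <- stats::runif(1, 10, 18) / 2
    cl <- names(codes)[match(lum[cand[k, 1], cand[k, 2]], codes)]
    h <- stats::rlnorm(1, log(hmean[[cl]]), 0.5)
    list(id = k,
         xy = rbind(c(cw$x[k] - w, cw$y[k] - d), c(cw$x[k] + w, cw$y[k] - d),
                    c(cw$x[k] + w, cw$y[k] + d), c(cw$x[k] - w, cw$y[k] + d)),
         height = h, class = cl)
  })

  br <- rasterize_buildings(buildings, tpl, rose)
  terrain <- grid_set_values(tpl, matrix(0, n, n))
  dsm <- grid_set_values(tpl, br$height)

  # -- population: lognormal field, denser on residential/commercial
  z <- smooth_field(n, n, 12) + 0.8 * (lum %in% codes[c("residential",
                                                        "commercial")])
  pop <- 6700 * exp(0.6 * z) / mean(exp(0.6 * z))
  population <- grid_set_values(tpl, pop)

  structure(list(landuse = landuse, terrain = terrain, dsm = dsm,
                 buildings = buildings, roads = roads, stations = stations,
                 weather_stations = weather, bus_stops = bus,
                 population = population, rose = rose,
                 building_rasters = br, coast_band = 300,
                 cell_size = cs, extent = config$extent,
                 fractions = fractions, seed = config$seed),
            class = "city_scene")
}

#' @export
print.city_scene <- function(x, ...) {
  cat(sprintf("city_scene: %g x %g m @ %g m (seed %d)\n", x$extent, x$extent,
              x$cell_size, x$seed))
  cat(sprintf("  %d buildings, %d road segments, %d stations, %d weather, %d bus stops\n",
              length(x$buildings), nrow(x$roads$edges), nrow(x$stations),
              nrow(x$weather_stations), nrow(x$bus_stops)))
  frac <- tabulate(grid_values(x$landuse), 5) / prod(dim(x$landuse))
  cat("  land use:", paste(sprintf("%s %.2f", names(LANDUSE_CLASSES), frac),
                           collapse = ", "), "\n")
  invisible(x)
}

# smoothed standard-normal field (FFT gaussian smoothing of white noise)
smooth_field <- function(nr, nc, sd_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- as.integer(ceiling(3 * sd_cells))
  off <- (-k):k
  g1 <- exp(-off^2 / (2 * sd_cells^2))
  K <- outer(g1, g1); K <- K / sum(K)
  s <- conv2_same(z, K)
  (s - mean(s)) / stats::sd(s)
}

# n points at cell centers with greedy minimum separation; `exclude` is an
# optional logical matrix of forbidden cells
scatter_points <- function(tpl, n_pts, min_sep, exclude = NULL) {
  nr <- grid_nrow(tpl); nc <- grid_ncol(tpl)
  pool <- cbind(sample.int(nr, 4000, replace = TRUE),
                sample.int(nc, 4000, replace = TRUE))
  if (!is.null(exclude)) pool <- pool[!exclude[pool], , drop = FALSE]
  cw <- cell_to_world(tpl, pool[, 1], pool[, 2])
  xs <- numeric(0); ys <- numeric(0)
  for (k in seq_len(nrow(pool))) {
    if (!length(xs) ||
        min((xs - cw$x[k])^2 + (ys - cw$y[k])^2) >= min_sep^2) {
      xs <- c(xs, cw$x[k]); ys <- c(ys, cw$y[k])
      if (length(xs) == n_pts) break
    }
  }
  if (length(xs) < n_pts)
    stop("could not place ", n_pts, " points at separation ", min_sep)
  data.frame(id = seq_len(n_pts), x = xs, y = ys)
}

#' Parameters of the synthetic data-generating world
#'
#' The generative truth the pipeline is asked to recover: per-season
#' background means with an AR(1) day-to-day component, a linear spatial
#' trend, land-use source strengths acting through the areal fraction at a
#' true buffer radius, morphology effects (sky view factor, point FAI) on
#' road cells, a linear AOD link `AOD = (PM - b)/a`, and observation noise
#' for stations, AOD pixels and the mobile unit.
#'
#' @param bg_mean named per-season background means (ug/m3).
#' @param bg_sd,ar1 day-to-day AR(1) innovation SD and coefficient.
#' @param gradient c(x, y) trend in ug/m3 per km.
#' @param strengths named per-class source strengths (ug/m3 per unit areal
#'   fraction at the true radius).
#' @param class_radii named true buffer radii (m) per active class.
#' @param svf_coef,fai_coef morphology effects on road cells (ug/m3 per unit;
#'   the SVF effect enters as `svf_coef * (SVF - 1)` so open streets are
#'   neutral).
#' @param aod_a,aod_b AOD link slope (ug/m3 per AOD unit) and intercept.
#' @param sigma_station,sigma_aod,sigma_mobile observation noise SDs.
#' @param sigma_site SD of the persistent per-station micro-site offset
#'   (local sources and siting effects the gridded field cannot represent).
#' @param cloud_fraction expected cloudy-pixel fraction per overpass.
#' @param diurnal_amp amplitude of the hourly background cycle (ug/m3).
#' @param floor physical lower bound applied to the truth field (ug/m3).
#' @export
truth_params <- function(bg_mean = c(spring = 22, summer = 15, fall = 28,
                                     winter = 35),
                         bg_sd = 2.5, ar1 = 0.6,
                         gradient = c(x = -2.0, y = 1.5),
                         strengths = c(residential = 20),
                         class_radii = c(residential = 300),
                         svf_coef = -10, fai_coef = 40,
                         aod_a = 50, aod_b = 0,
                         sigma_station = 9.0, sigma_aod = 0.05,
                         sigma_mobile = 1.5, sigma_site = 0,
                         cloud_fraction = 0.25, diurnal_amp = 3,
                         floor = 0.5) {
  if (any(c(sigma_station, sigma_aod, sigma_mobile) < 0))
    stop("noise SDs must be >= 0")
  if (abs(ar1) >= 1) stop("AR(1) coefficient must lie in (-1, 1)")
  structure(list(bg_mean = bg_mean, bg_sd = bg_sd, ar1 = ar1,
                 gradient = gradient, strengths = strengths,
                 class_radii = class_radii, svf_coef = svf_coef,
                 fai_coef = fai_coef, aod_a = aod_a, aod_b = aod_b,
                 sigma_station = sigma_station, sigma_aod = sigma_aod,
                 sigma_mobile = sigma_mobile, sigma_site = sigma_site,
                 cloud_fraction = cloud_fraction, diurnal_amp = diurnal_amp,
                 floor = floor),
            class = "truth_params")
}

#' Road-cell morphology layers of a scene
#'
#' Sky view factor at road-corridor cell centers (NA elsewhere), the
#' point-FAI surface (decay-weighted focal sum of the building frontal-area
#' density), the road corridor mask, and the nearest-segment id per corridor
#' cell. Computed once per scene and cached.
#'
#' @param scene a `city_scene`.
#' @param fai_par [point_fai_params()]; `svf_par` [svf_params()].
#' @param svf_par horizon-scan parameters.
#' @return list with rasters `svf`, `fai_point`, `road_mask`, `segment` .
#' @export
scene_morphology <- function(scene, fai_par = point_fai_params(step = 10),
                             svf_par = svf_params()) {
  if (!is.null(scene$.morph)) return(scene$.morph)
  tpl <- scene$landuse
  rl <- road_length_raster(scene$roads, tpl)
  mask <- conv2_same((rl > 0) * 1, matrix(1, 3, 3)) > 0.5
  # point FAI everywhere via decay-kernel focal sum of the density raster
  R <- fai_par$R; cs <- tpl$cellsize
  k <- floor(R / cs); off <- seq(-k, k) * cs
  dk <- sqrt(outer(off^2, off^2, "+"))
  K <- decay_weight(dk, R, fai_par$c) * cs^2 / (pi * R^2)
  K[dk > R] <- 0
  fai_pt <- conv2_same(scene$building_rasters$dens, K)
  # SVF only where needed (road corridor)
  idx <- which(mask, arr.ind = TRUE)
  cw <- cell_to_world(tpl, idx[, 1], idx[, 2])
  svf_v <- svf_points(scene$dsm, cbind(cw$x, cw$y), svf_par)
  svf <- matrix(NA_real_, grid_nrow(tpl), grid_ncol(tpl))
  svf[idx] <- svf_v
  ns <- nearest_segment(scene$roads, cw$x, cw$y, max_dist = Inf)
  seg <- matrix(NA_real_, grid_nrow(tpl), grid_ncol(tpl))
  seg[idx] <- ns$segment
  list(svf = grid_set_values(tpl, svf),
       fai_point = grid_set_values(tpl, fai_pt),
       road_mask = grid_set_values(tpl, mask * 1),
       segment = grid_set_values(tpl, seg))
}

#' Simulate the true PM2.5 field
#'
#' Builds the static spatial surface (trend + land-use sources at their true
#' radii + road-cell morphology effects) and the per-day background following
#' a seasonal AR(1), then exposes `field(day) = static + background[day]`
#' clipped at the physical floor.
#'
#' @param scene a `city_scene`.
#' @param params a [truth_params()].
#' @param config the [pipeline_config()] (seasons, days per season, seed).
#' @return object of class `pm_truth` with `$static` (raster), `$background`
#'   (per-day), `$days` (data.frame day, season) and `$morph` (the cached
#'   morphology layers).
#' @export
simulate_truth <- function(scene, params, config) {
  set.seed(config$seed + 1L)
  tpl <- scene$landuse
  n_days <- length(config$seasons) * config$days_per_season
  days <- data.frame(day = seq_len(n_days),
                     season = rep(config$seasons,
                                  each = config$days_per_season))
  # seasonal AR(1) backgrounds (season labels outside the named means cycle
  # through them in order)
  bm <- vapply(seq_along(config$seasons), function(i) {
    se <- config$seasons[i]
    if (se %in% names(params$bg_mean)) params$bg_mean[[se]]
    else params$bg_mean[[(i - 1) %% length(params$bg_mean) + 1]]
  }, 0)
  names(bm) <- config$seasons
  bg <- numeric(n_days); e <- 0
  for (d in seq_len(n_days)) {
    innov <- stats::rnorm(1, 0, params$bg_sd * sqrt(1 - params$ar1^2))
    e <- params$ar1 * e + innov
    bg[d] <- bm[[days$season[d]]] + e
  }
  # static surface
  cc <- grid_coords(tpl)
  static <- params$gradient[["x"]] * (cc$x - scene$extent / 2) / 1000 +
    params$gradient[["y"]] * (cc$y - scene$extent / 2) / 1000
  lu <- grid_values(tpl <- scene$landuse)
  ones <- matrix(1, grid_nrow(tpl), grid_ncol(tpl))
  for (cl in names(params$strengths)) {
    r <- params$class_radii[[cl]]
    fs <- focal_circle((lu == LANDUSE_CLASSES[[cl]]) * 1, r, tpl$cellsize)
    nsum <- focal_circle(ones, r, tpl$cellsize)$sum
    static <- static + params$strengths[[cl]] * fs$sum / nsum
  }
  static_city <- static
  morph <- scene_morphology(scene)
  svf <- grid_values(morph$svf); fai <- grid_values(morph$fai_point)
  onroad <- !is.na(svf)
  static[onroad] <- static[onroad] +
    params$svf_coef * (svf[onroad] - 1) +
    params$fai_coef * fai[onroad]
  # clip accounting at the lowest background
  clip_frac <- mean(static + min(bg) < params$floor)
  if (clip_frac > 0.05 && any(unlist(params$strengths) < 0))
    warning(sprintf("negative source strengths clip %.1f%% of cells",
                    100 * clip_frac))
  structure(list(static = grid_set_values(tpl, static),
                 static_city = grid_set_values(tpl, static_city),
                 background = bg,
                 days = days, params = params, morph = morph,
                 floor = params$floor, seasons = config$seasons),
            class = "pm_truth")
}

#' True field for one day / seasonal mean truth
#' @param truth a `pm_truth`.
#' @param day integer day index.
#' @export
truth_field <- function(truth, day) {
  v <- grid_values(truth$static) + truth$background[day]
  grid_set_values(truth$static, pmax(v, truth$floor))
}

#' @rdname truth_field
#' @param season season label.
#' @export
truth_seasonal_mean <- function(truth, season) {
  d <- truth$days$day[truth$days$season == season]
  v <- grid_values(truth$static) + mean(truth$background[d])
  grid_set_values(truth$static, pmax(v, truth$floor))
}

#' Sample synthetic observations from the truth
#'
#' Draws everything the pipeline ingests: daily station PM2.5 (truth at the
#' station cell + station noise), daily weather-station records, daily
#' sounding indices (inactive covariates), two AOD overpasses per day (pixel
#' block means of the truth mapped through the inverse AOD link, with a
#' seeded cloud process and the coastal QA band), and 1 Hz pedestrian tracks
#' at 10 sites walked at 0.8 m/s along the street network during three daily
#' slots, with raw readings inflated by the humidity correction factor so the
#' downstream RH correction is exercised in reverse.
#'
#' @param truth a `pm_truth`; `scene` the `city_scene`; `params`
#'   [truth_params()]; `config` the [pipeline_config()].
#' @param scene,params,config see above.
#' @param n_sites,samples_per_site mobile campaign design (defaults 10 sites,
#'   600 one-second samples each).
#' @return list with data.frames `stations`, `weather`, `sounding`, `mobile`,
#'   `background` and the list `aod` of per-day `list(terra, aqua)` scenes.
#' @export
sample_observations <- function(truth, scene, params, config,
                                n_sites = 10, samples_per_site = 900) {
  set.seed(config$seed + 2L)
  tpl <- scene$landuse
  static <- grid_values(truth$static)
  n_days <- nrow(truth$days)

  # station series
  st <- scene$stations
  rc <- world_to_cell(tpl, st$x, st$y)
  svals <- static[cbind(rc$row, rc$col)] +
    stats::rnorm(nrow(st), 0, params$sigma_site)
  stations <- do.call(rbind, lapply(seq_len(n_days), function(d)
    data.frame(station = st$id, day = d, season = truth$days$season[d],
               pm25 = pmax(svals + truth$background[d] +
                             stats::rnorm(nrow(st), 0, params$sigma_station),
                           0))))

  # weather-station records (independent meteorology, kriged downstream)
  wst <- scene$weather_stations
  t_season <- c(spring = 22, summer = 29, fall = 25, winter = 16)
  woff <- stats::rnorm(nrow(wst), 0, 0.8)
  weather <- do.call(rbind, lapply(seq_len(n_days), function(d) {
    se <- truth$days$season[d]
    data.frame(station = wst$id, day = d, season = se,
               TEMP = (t_season[se] %||% 22) + woff +
                 stats::rnorm(nrow(wst), 0, 1.2),
               RH = pmin(pmax(70 + 8 * stats::rnorm(nrow(wst)), 30), 98),
               WSPD = pmax(2.5 + stats::rnorm(nrow(wst), 0, 0.8), 0),
               RF = pmax(stats::rnorm(nrow(wst), 0.5, 2), 0),
               MSLP = 1012 + stats::rnorm(nrow(wst), 0, 2))
  }))

  # sounding indices: AR(1) decoys
  ar_series <- function(n, mu, sd, rho = 0.5) {
    e <- numeric(n); v <- 0
    for (i in seq_len(n)) {
      v <- rho * v + stats::rnorm(1, 0, sd * sqrt(1 - rho^2)); e[i] <- mu + v
    }
    e
  }
  sounding <- data.frame(day = seq_len(n_days),
                         KINX = ar_series(n_days, 25, 6),
                         PWAT = ar_series(n_days, 45, 8),
                         CINV = ar_series(n_days, 2, 1),
                         LCLP = ar_series(n_days, 950, 15))

  # AOD overpasses: pixel block means of the daily field through the inverse
  # link. The column retrieval responds to the broad aerosol burden, so the
  # block means are taken over the city-scale component (street-canyon
  # morphology deviations are sub-pixel surface effects the column AOD does
  # not resolve).
  nb <- as.integer(round(scene$extent / config$aod_cell))
  fac <- as.integer(round(config$aod_cell / tpl$cellsize))
  bidx <- rep(seq_len(nb), each = fac)
  block_mean <- t(rowsum(t(rowsum(grid_values(truth$static_city), bidx)),
                         bidx)) / fac^2
  coast_rows <- which(cell_to_world(
    raster_grid(matrix(0, nb, nb), 0, 0, config$aod_cell),
    seq_len(nb), rep(1, nb))$y <= scene$coast_band)
  aod_tpl <- raster_grid(matrix(0, nb, nb), 0, 0, config$aod_cell,
                         crs = tpl$crs)
  make_overpass <- function(day, sensor) {
    pm <- block_mean + truth$background[day]
    aod <- pmax((pm - params$aod_b) / params$aod_a +
                  matrix(stats::rnorm(nb * nb, 0, params$sigma_aod), nb), 0)
    z <- smooth_field(nb, nb, 1.5)
    thr <- stats::qnorm(1 - params$cloud_fraction)
    qa <- matrix("Clear", nb, nb)
    qa[z > thr - 0.4] <- "PossiblyCloudy"
    qa[z > thr] <- "Cloudy"
    coast <- matrix(FALSE, nb, nb); coast[coast_rows, ] <- TRUE
    aod_scene(grid_set_values(aod_tpl, aod), qa, coastline = coast,
              sensor = sensor, date = day)
  }
  aod <- lapply(seq_len(n_days), function(d)
    list(terra = make_overpass(d, "Terra"), aqua = make_overpass(d, "Aqua")))

  # mobile campaign: 1 Hz pedestrian tracks on the road network
  summer_days <- truth$days$day[truth$days$season ==
                                  config$seasons[min(2, length(config$seasons))]]
  slots <- c(9, 14, 19)
  # campaign sites: road nodes in locally homogeneous districts (low spatial
  # variability of the land-use-driven field component within ~150 m), spread
  # across the scene — mirroring purposeful representative-site selection
  nodes <- scene$roads$nodes
  sc_city <- grid_values(truth$static_city)
  loc_mean <- focal_circle(sc_city, 150, tpl$cellsize)
  loc_sq <- focal_circle(sc_city^2, 150, tpl$cellsize)
  loc_sd <- sqrt(pmax(loc_sq$sum / loc_sq$n - (loc_mean$sum / loc_mean$n)^2, 0))
  bdens <- focal_circle(scene$building_rasters$cen_n, 200, tpl$cellsize)$sum
  fai_v <- grid_values(truth$morph$fai_point)
  fm <- focal_circle(fai_v, 150, tpl$cellsize)
  fs <- focal_circle(fai_v^2, 150, tpl$cellsize)
  fai_sd <- sqrt(pmax(fs$sum / fs$n - (fm$sum / fm$n)^2, 0))
  rcn <- world_to_cell(tpl, nodes$x, nodes$y)
  hom <- loc_sd[cbind(rcn$row, rcn$col)]
  nb_build <- bdens[cbind(rcn$row, rcn$col)]
  morph_var <- fai_sd[cbind(rcn$row, rcn$col)]
  # campaign design: built-up nodes in districts where the city-scale field
  # is locally flat but the morphology is diverse (contrasting canyons to
  # sample within each site)
  eligible <- nb_build >= stats::quantile(nb_build, 0.5) &
    hom <= stats::quantile(hom, 0.6)
  ord <- c(which(eligible)[order(-morph_var[eligible])],
           which(!eligible)[order(hom[!eligible])])
  n_sites <- min(n_sites, nrow(nodes))
  site_nodes <- NULL
  for (site_sep in scene$extent / c(6, 12, 24, 1e9)) {
    site_nodes <- data.frame(x = numeric(0), y = numeric(0))
    for (k in ord) {
      if (!nrow(site_nodes) ||
          min((site_nodes$x - nodes$x[k])^2 +
              (site_nodes$y - nodes$y[k])^2) >= site_sep^2) {
        site_nodes <- rbind(site_nodes, nodes[k, c("x", "y")])
        if (nrow(site_nodes) == n_sites) break
      }
    }
    if (nrow(site_nodes) == n_sites) break
  }
  if (nrow(site_nodes) < n_sites) stop("could not place campaign sites")
  mobile <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    start <- nearest_node(scene$roads, site_nodes$x[s], site_nodes$y[s])
    pts <- walk_track(scene$roads, start, samples_per_site, step = 0.8)
    day <- sample(summer_days, 1)
    slot <- rep(slots, length.out = 3)
    per <- ceiling(samples_per_site / 3)
    hour <- rep(slot, each = per)[seq_len(samples_per_site)]
    tsec <- seq_len(samples_per_site)
    RH <- pmin(pmax(0.55 + 0.15 * sin(2 * pi * tsec / 900) +
                      ar_series(samples_per_site, 0, 0.05, 0.99), 0.25), 0.92)
    Ta <- 28 + ar_series(samples_per_site, 0, 1, 0.99)
    rcm <- world_to_cell(tpl, pts[, 1], pts[, 2])
    fld <- static[cbind(rcm$row, rcm$col)] + truth$background[day] +
      params$diurnal_amp * sin(2 * pi * (hour - 8) / 24)
    fld <- pmax(fld, truth$floor)
    raw <- fld * rh_correction_factor(RH) +
      stats::rnorm(samples_per_site, 0, params$sigma_mobile)
    mobile[[s]] <- data.frame(site = s, t = tsec, day = day, hour = hour,
                              hour_index = (day - 1) * 24 + hour,
                              x = pts[, 1], y = pts[, 2],
                              pm_raw = pmax(raw, 0), RH = RH, Ta = Ta)
  }
  mobile <- do.call(rbind, mobile)
  ns <- nearest_segment(scene$roads, mobile$x, mobile$y,
                        max_dist = config$snap_distance)
  if (anyNA(ns$segment)) stop("mobile track left the road network")

  hours <- sort(unique(mobile$hour_index))
  background <- data.frame(hour = hours,
                           pm25 = truth$background[(hours - 1) %/% 24 + 1] +
                             params$diurnal_amp *
                             sin(2 * pi * (hours %% 24 - 8) / 24))
  list(stations = stations, weather = weather, sounding = sounding,
       aod = aod, mobile = mobile, background = background)
}

nearest_node <- function(roads, x, y) {
  which.min((roads$nodes$x - x)^2 + (roads$nodes$y - y)^2)
}

# random walk along road edges emitting points every `step` metres
walk_track <- function(roads, start_node, n_pts, step = 0.8) {
  e <- roads$edges
  inc <- lapply(seq_len(nrow(roads$nodes)), function(nd)
    which(e$from == nd | e$to == nd))
  pts <- matrix(NA_real_, n_pts, 2)
  node <- start_node; got <- 0L; prev_edge <- 0L
  while (got < n_pts) {
    cand <- inc[[node]]
    if (length(cand) > 1 && prev_edge %in% cand)
      cand <- cand[cand != prev_edge]
    ei <- if (length(cand) == 1) cand else sample(cand, 1)
    g <- e$geometry[[ei]]
    if (e$to[ei] == node) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
    len <- e$length[ei]
    ss <- seq(step, len, by = step)
    if (length(ss)) {
      take <- min(length(ss), n_pts - got)
      tfrac <- ss[seq_len(take)] / len
      pts[got + seq_len(take), ] <-
        cbind(g[1, 1] + tfrac * (g[nrow(g), 1] - g[1, 1]),
              g[1, 2] + tfrac * (g[nrow(g), 2] - g[1, 2]))
      got <- got + take
    }
    node <- if (e$to[ei] == node) e$from[ei] else e$to[ei]
    prev_edge <- ei
  }
  pts
}
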