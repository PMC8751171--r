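#' Land-use class codes of the five-class scheme
#'
#' residential, commercial, industrial, government, open space / greening —
#' stored in the land-use raster as integer codes 1..5.
#' @export
LANDUSE_CLASSES <- c(residential = 1, commercial = 2, industrial = 3,
                     government = 4, open = 5)

LANDUSE_VARS <- c(residential = "RES", commercial = "COM", industrial = "IND",
                  government = "GOV", open = "OPN")
ROAD_VARS <- c(trunk = "RD0", primary = "RD1", secondary = "RD2",
               tertiary = "RD3", ordinary = "RD4")

col_name <- function(var, radius) paste0(var, "_", radius)

#' Areal fraction of a land-use class within a circular buffer
#'
#' Fraction of raster cells whose center lies within `radius` of `center` that
#' carry the requested class (cell-center-in-circle rule; no area weighting of
#' boundary cells). Warns when the buffer extends beyond the raster.
#'
#' @param landuse `raster_grid` of integer class codes.
#' @param center length-2 numeric (x, y) in m.
#' @param radius buffer radius (m).
#' @param class class name (see [LANDUSE_CLASSES]) or integer code.
#' @return fraction in `[0, 1]`.
#' @export
areal_fraction <- function(landuse, center, radius, class) {
  code <- if (is.character(class)) LANDUSE_CLASSES[[class]] else class
  cells <- cells_in_circle(landuse, center, radius)
  if (!length(cells$row)) stop("no raster cells inside the buffer")
  if (cells$partial)
    warning("buffer extends beyond the raster; fraction uses covered cells only")
  v <- grid_values(landuse)[cbind(cells$row, cells$col)]
  mean(v == code, na.rm = TRUE)
}

cells_in_circle <- function(g, center, radius) {
  cc <- grid_coords(g)
  inside <- (cc$x - center[1])^2 + (cc$y - center[2])^2 <= radius^2 + 1e-9
  partial <- center[1] - radius < g$xmin || center[1] + radius > grid_xmax(g) ||
    center[2] - radius < g$ymin || center[2] + radius > grid_ymax(g)
  idx <- which(inside, arr.ind = TRUE)
  list(row = idx[, 1], col = idx[, 2], partial = partial)
}

#' Road line density within a circular buffer
#'
#' Length of the class-matching road segments clipped to the circle, divided
#' by the circle area: km per km^2. Clipping is exact on each straight
#' polyline piece.
#'
#' @param roads a [road_graph()].
#' @param center length-2 numeric (x, y) in m.
#' @param radius buffer radius (m).
#' @param class road class to match, or NULL for all classes.
#' @export
line_density <- function(roads, center, radius, class = NULL) {
  if (radius <= 0) stop("radius must be > 0")
  e <- roads$edges
  if (!is.null(class)) e <- e[e$class == class, , drop = FALSE]
  tot <- 0
  for (g in e$geometry)
    for (k in seq_len(nrow(g) - 1))
      tot <- tot + chord_length(g[k, ], g[k + 1, ], center, radius)
  (tot / 1000) / (pi * (radius / 1000)^2)
}

# length of the part of segment p0-p1 inside the circle (center, r)
chord_length <- function(p0, p1, center, r) {
  d <- p1 - p0; f <- p0 - center
  a <- sum(d * d); b <- 2 * sum(f * d); cc <- sum(f * f) - r^2
  if (a < 1e-18) return(0)
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(0)
  sq <- sqrt(disc)
  t0 <- max((-b - sq) / (2 * a), 0); t1 <- min((-b + sq) / (2 * a), 1)
  if (t1 <= t0) return(0)
  (t1 - t0) * sqrt(a)
}

#' Count points within a circular buffer (boundary inclusive)
#' @param points data.frame with `x`, `y` columns (or 2-column matrix).
#' @param center length-2 numeric (x, y).
#' @param radius buffer radius (m); a point at exactly `radius` is counted.
#' @export
point_count <- function(points, center, radius) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (!NROW(points)) return(0L)
  sum((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2
      <= radius^2 + 1e-9)
}

# ---- whole-grid buffer evaluators -------------------------------------------
# Each evaluator applies the corresponding buffer operation at every cell
# center (FFT focal sums over the circular kernel; input features are
# rasterised at the working resolution first). The station predictor table
# samples these same grids, so a prediction at a station cell reproduces the
# calibration row exactly.

# accumulate polyline length per cell for one road class
road_length_raster <- function(roads, template, class = NULL) {
  e <- roads$edges
  if (!is.null(class)) e <- e[e$class == class, , drop = FALSE]
  m <- matrix(0, grid_nrow(template), grid_ncol(template))
  ds <- template$cellsize / 4
  for (g in e$geometry) for (k in seq_len(nrow(g) - 1)) {
    p0 <- g[k, ]; p1 <- g[k + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len < 1e-12) next
    np <- max(2L, ceiling(len / ds))
    t0 <- (seq_len(np) - 0.5) / np
    rc <- world_to_cell(template, p0[1] + t0 * (p1[1] - p0[1]),
                        p0[2] + t0 * (p1[2] - p0[2]))
    ok <- !is.na(rc$row)
    if (any(ok)) {
      tab <- table(paste(rc$row[ok], rc$col[ok]))
      ij <- do.call(rbind, strsplit(names(tab), " "))
      idx <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
      m[idx] <- m[idx] + as.numeric(tab) * len / np
    }
  }
  m
}

# exact circular stamp: for every point, add `val` to all cells whose center
# lies within `radius` of the point's true location. Evaluating the result at
# a cell center therefore reproduces the point-geometry buffer ops exactly.
point_stamp_sum <- function(px, py, val, template, radius) {
  nr <- grid_nrow(template); nc <- grid_ncol(template)
  m <- matrix(0, nr, nc)
  cs <- template$cellsize
  if (length(val) == 1) val <- rep(val, length(px))
  for (i in seq_along(px)) {
    rc0 <- world_to_cell(template, px[i] - radius, py[i] + radius)
    rc1 <- world_to_cell(template, px[i] + radius, py[i] - radius)
    rows <- max(1, rc0$row %||% 1):min(nr, rc1$row %||% nr)
    cols <- max(1, rc0$col %||% 1):min(nc, rc1$col %||% nc)
    cw <- cell_to_world(template, rep(rows, times = length(cols)),
                        rep(cols, each = length(rows)))
    hit <- (cw$x - px[i])^2 + (cw$y - py[i])^2 <= radius^2 + 1e-9
    if (any(hit)) {
      idx <- cbind(rep(rows, times = length(cols))[hit],
                   rep(cols, each = length(rows))[hit])
      m[idx] <- m[idx] + val[i]
    }
  }
  m
}

# building rasters: cell-center coverage (fai density, max height) and
# centroid markers (for roughness)
rasterize_buildings <- function(buildings, template, rose = windrose()) {
  nr <- grid_nrow(template); nc <- grid_ncol(template)
  dens <- matrix(0, nr, nc); hgt <- matrix(0, nr, nc)
  cen_h <- matrix(0, nr, nc); cen_n <- matrix(0, nr, nc)
  if (length(buildings)) {
    dvals <- building_fai_density(buildings, rose)
    cc <- grid_coords(template)
    for (i in seq_along(buildings)) {
      b <- buildings[[i]]
      bb <- apply(b$xy, 2, range)
      rc0 <- world_to_cell(template, bb[1, 1], bb[2, 2])
      rc1 <- world_to_cell(template, bb[2, 1], bb[1, 2])
      rows <- max(1, rc0$row %||% 1, na.rm = TRUE):min(nr, rc1$row %||% nr)
      cols <- max(1, rc0$col %||% 1, na.rm = TRUE):min(nc, rc1$col %||% nc)
      sub <- expand.grid(row = rows, col = cols)
      px <- cc$x[cbind(sub$row, sub$col)]; py <- cc$y[cbind(sub$row, sub$col)]
      inb <- point_in_polygon(px, py, b$xy)
      if (any(inb)) {
        idx <- cbind(sub$row[inb], sub$col[inb])
        dens[idx] <- dens[idx] + dvals[i]
        hgt[idx] <- pmax(hgt[idx], b$height)
      }
      ctr <- polygon_centroid(b$xy)
      rcc <- world_to_cell(template, ctr[1], ctr[2])
      if (!is.na(rcc$row)) {
        cen_h[rcc$row, rcc$col] <- cen_h[rcc$row, rcc$col] + b$height
        cen_n[rcc$row, rcc$col] <- cen_n[rcc$row, rcc$col] + 1
      }
    }
  }
  list(dens = dens, height = hgt, cen_h = cen_h, cen_n = cen_n)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Whole-grid spatial predictor surfaces
#'
#' Computes the requested buffer-predictor columns as rasters at the working
#' resolution: land-use fractions (`RES`/`COM`/`IND`/`GOV`/`OPN`), greening
#' cover ratio (`GCR`, derived from the open-space class), road line densities
#' (`RD0`..`RD4`, km/km^2), bus-stop counts (`BUS`), population density
#' (`POP`), buffer-averaged frontal area index (`FAI`), roughness length
#' (`ROUGH`) — each per requested radius — plus the location surfaces `LONG`,
#' `LAT`, `ELEV`.
#'
#' @param scene a `city_scene`.
#' @param cols character vector of column names (e.g. `"RES_300"`); defaults
#'   to every spatial column at every configured radius.
#' @param radii radius series (m) used when `cols` is NULL.
#' @param rose [windrose()] for the FAI surfaces.
#' @return named list of `raster_grid`s.
#' @export
predictor_grids <- function(scene, cols = NULL, radii = NULL,
                            rose = windrose()) {
  tpl <- scene$landuse
  if (is.null(cols)) {
    stopifnot(!is.null(radii))
    fams <- c(unname(LANDUSE_VARS), "GCR", unname(ROAD_VARS), "BUS", "POP",
              "FAI", "ROUGH")
    cols <- c(as.vector(outer(fams, radii, col_name)), "LONG", "LAT", "ELEV")
  }
  parsed <- parse_cols(cols)
  out <- vector("list", length(cols)); names(out) <- cols
  lu <- grid_values(tpl)
  ones <- matrix(1, grid_nrow(tpl), grid_ncol(tpl))
  br <- NULL  # building rasters, built lazily
  need_b <- any(parsed$var %in% c("FAI", "ROUGH"))
  if (need_b) br <- rasterize_buildings(scene$buildings, tpl, rose)
  ncell_cache <- list()
  ncell <- function(r) {
    key <- as.character(r)
    if (is.null(ncell_cache[[key]]))
      ncell_cache[[key]] <<- focal_circle(ones, r, tpl$cellsize)$sum
    ncell_cache[[key]]
  }
  for (i in seq_along(cols)) {
    var <- parsed$var[i]; r <- parsed$radius[i]
    m <- switch(var,
      LONG = grid_coords(tpl)$x,
      LAT = grid_coords(tpl)$y,
      ELEV = if (!is.null(scene$terrain)) grid_values(scene$terrain)
             else matrix(0, grid_nrow(tpl), grid_ncol(tpl)),
      RES = , COM = , IND = , GOV = , OPN = {
        code <- LANDUSE_CLASSES[[names(LANDUSE_VARS)[LANDUSE_VARS == var]]]
        focal_circle((lu == code) * 1, r, tpl$cellsize)$sum / ncell(r)
      },
      GCR = focal_circle((lu == LANDUSE_CLASSES[["open"]]) * 1, r,
                         tpl$cellsize)$sum / ncell(r),
      RD0 = , RD1 = , RD2 = , RD3 = , RD4 = {
        cls <- names(ROAD_VARS)[ROAD_VARS == var]
        lr <- road_length_raster(scene$roads, tpl, cls)
        (focal_circle(lr, r, tpl$cellsize)$sum / 1000) / (pi * (r / 1000)^2)
      },
      BUS = point_stamp_sum(scene$bus_stops$x, scene$bus_stops$y, 1, tpl, r),
      POP = focal_circle(grid_values(scene$population), r,
                         tpl$cellsize)$sum / ncell(r),
      FAI = focal_circle(br$dens * tpl$cellsize^2, r, tpl$cellsize)$sum /
        (pi * r^2),
      ROUGH = {
        cen <- t(vapply(scene$buildings, function(b) polygon_centroid(b$xy),
                        numeric(2)))
        hts <- vapply(scene$buildings, `[[`, 0, "height")
        hs <- point_stamp_sum(cen[, 1], cen[, 2], hts, tpl, r)
        ns <- point_stamp_sum(cen[, 1], cen[, 2], 1, tpl, r)
        z <- 0.1 * hs / pmax(ns, 1)
        z[ns == 0] <- 0
        z
      },
      stop("unknown predictor family: ", var))
    out[[i]] <- grid_set_values(tpl, m)
  }
  out
}

parse_cols <- function(cols) {
  var <- sub("_[0-9]+$", "", cols)
  radius <- suppressWarnings(as.numeric(sub("^.*_", "", cols)))
  radius[!grepl("_[0-9]+$", cols)] <- NA
  list(var = var, radius = radius)
}

#' Assemble the city-scale predictor table
#'
#' One row per (station, season): the seasonal mean PM2.5 response, the
#' mandatory AOD column sampled from the seasonal 10 m AOD surface at the
#' station cell (rows without AOD coverage are dropped with a message), every
#' spatial buffer predictor sampled from [predictor_grids()], and the seasonal
#' means of the temporal variables (kriged meteorology at the station,
#' sounding indices). A schema attribute maps columns to (variable, radius).
#'
#' @param scene a `city_scene`.
#' @param pm_seasonal data.frame `station`, `season`, `pm25`.
#' @param aod_grids named list (per season) of 10 m AOD `raster_grid`s.
#' @param temporal data.frame `station`, `season`, plus one column per
#'   temporal variable (met seasonal means, sounding indices); may be NULL.
#' @param radii buffer radius series (m).
#' @param rose [windrose()] for FAI columns.
#' @return data.frame of class `predictor_table` with attribute `schema`.
#' @export
assemble_table <- function(scene, pm_seasonal, aod_grids, temporal = NULL,
                           radii, rose = windrose()) {
  grids <- predictor_grids(scene, radii = radii, rose = rose)
  st <- scene$stations
  tab <- pm_seasonal
  tab$AOD <- mapply(function(s, season)
    grid_sample(aod_grids[[season]], st$x[st$id == s], st$y[st$id == s]),
    tab$station, tab$season)
  drop <- is.na(tab$AOD)
  if (any(drop)) {
    message(sum(drop), " station-season row(s) dropped for missing AOD: ",
            paste(paste0(tab$station[drop], "/", tab$season[drop]),
                  collapse = ", "))
    tab <- tab[!drop, , drop = FALSE]
  }
  sx <- st$x[match(tab$station, st$id)]; sy <- st$y[match(tab$station, st$id)]
  for (nm in names(grids)) tab[[nm]] <- grid_sample(grids[[nm]], sx, sy)
  if (!is.null(temporal))
    tab <- merge(tab, temporal, by = c("station", "season"), sort = FALSE)
  pc <- parse_cols(setdiff(names(tab), c("station", "season", "pm25")))
  schema <- data.frame(col = setdiff(names(tab), c("station", "season", "pm25")),
                       var = pc$var, radius = pc$radius)
  attr(tab, "schema") <- schema
  class(tab) <- c("predictor_table", "data.frame")
  tab
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("predictor_table: %d rows (station x season), %d predictor columns\n",
              nrow(x), nrow(attr(x, "schema"))))
  invisible(x)
}
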