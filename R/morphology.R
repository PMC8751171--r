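#' Wind direction probability rose (8 principal directions)
#'
#' Probabilities for the eight principal compass directions
#' (N, NE, E, SE, S, SW, W, NW), used to direction-weight frontal-area
#' calculations. Must be non-negative and sum to 1.
#'
#' @param p numeric vector of length 8 (recycled from a scalar); normalised
#'   probabilities.
#' @export
windrose <- function(p = rep(1 / 8, 8)) {
  if (length(p) == 1) p <- rep(p, 8)
  if (length(p) != 8 || any(p < 0)) stop("windrose needs 8 non-negative probabilities")
  if (abs(sum(p) - 1) > 1e-9) stop("windrose probabilities must sum to 1")
  structure(list(p = p, theta = (0:7) * 45), class = "windrose")
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_centroid <- function(xy) c(mean(xy[, 1]), mean(xy[, 2]))

# projected silhouette interval of a footprint perpendicular to flow
# direction theta (compass degrees): [min, max] of vertex projections
proj_interval <- function(xy, theta) {
  th <- theta * pi / 180
  p <- xy[, 1] * cos(th) - xy[, 2] * sin(th)  # axis perpendicular to the flow
  range(p)
}

# union length of a set of intervals (2-column matrix lo, hi)
merge_interval_length <- function(iv) {
  if (!nrow(iv)) return(0)
  o <- order(iv[, 1])
  lo <- iv[o, 1]; hi <- iv[o, 2]
  tot <- 0; cl <- lo[1]; ch <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] > ch) { tot <- tot + ch - cl; cl <- lo[i]; ch <- hi[i] }
    else ch <- max(ch, hi[i])
  }
  tot + ch - cl
}

# frontal (silhouette) area of a building set along flow direction theta.
# Mutual occlusion: at each height slab, overlapping projection intervals are
# merged, so the result is the area of the combined silhouette, not the sum.
frontal_area <- function(buildings, theta, occlusion = TRUE) {
  if (!length(buildings)) return(0)
  iv <- t(vapply(buildings, function(b) proj_interval(b$xy, theta),
                 numeric(2)))
  h <- vapply(buildings, `[[`, 0, "height")
  if (!occlusion) return(sum((iv[, 2] - iv[, 1]) * h))
  hs <- sort(unique(h))
  area <- 0; h0 <- 0
  for (hk in hs) {
    act <- h >= hk
    area <- area + merge_interval_length(iv[act, , drop = FALSE]) * (hk - h0)
    h0 <- hk
  }
  area
}

#' Frontal area index of a lot
#'
#' Direction-probability-weighted ratio of building silhouette area to lot
#' area: `FAI = sum_theta [A_F(theta) / A_T] * P(theta)` over the 8 principal
#' wind directions. `A_F(theta)` is the area of the combined building
#' silhouette perpendicular to the flow (overlapping silhouettes are merged at
#' each height slab, i.e. a building shadowed by a taller one in front does
#' not count twice).
#'
#' @param buildings list of buildings `list(id, xy, height)`; pass the subset
#'   belonging to the lot (buildings are attributed by footprint centroid).
#' @param lot_area lot area `A_T` in m^2; must be > 0.
#' @param rose a [windrose()].
#' @param occlusion merge overlapping silhouettes (default TRUE).
#' @return unitless FAI value.
#' @export
frontal_area_index <- function(buildings, lot_area, rose = windrose(),
                               occlusion = TRUE) {
  if (!is.finite(lot_area) || lot_area <= 0) stop("lot area must be > 0")
  af <- vapply(rose$theta, function(th)
    frontal_area(buildings, th, occlusion), 0)
  sum(af / lot_area * rose$p)
}

#' Buffer-averaged frontal area index
#'
#' [frontal_area_index()] with a circular buffer as the lot: buildings whose
#' footprint centroid lies within `radius` of `center` enter the silhouette,
#' and `A_T` is the circle area.
#'
#' @param buildings full building list.
#' @param center length-2 numeric (x, y) in m.
#' @param radius buffer radius (m).
#' @param rose a [windrose()].
#' @param occlusion merge overlapping silhouettes (default TRUE).
#' @export
buffered_fai <- function(buildings, center, radius, rose = windrose(),
                         occlusion = TRUE) {
  inside <- buildings_in_circle(buildings, center, radius)
  frontal_area_index(inside, pi * radius^2, rose, occlusion)
}

buildings_in_circle <- function(buildings, center, radius) {
  if (!length(buildings)) return(list())
  cen <- t(vapply(buildings, function(b) polygon_centroid(b$xy), numeric(2)))
  keep <- (cen[, 1] - center[1])^2 + (cen[, 2] - center[2])^2 <= radius^2
  buildings[keep]
}

#' Distance-decay weight for point-based FAI
#'
#' `w(l) = ((R - l) / R)^c` for `0 <= l <= R`, and 0 beyond the circle.
#' Strictly decreasing in `l` for `c > 0`; `w(0) = 1`, `w(R) = 0`.
#'
#' @param l distance(s) from the test point (m).
#' @param R decay radius (m), default 200.
#' @param c decay exponent, default 2.
#' @export
decay_weight <- function(l, R = 200, c = 2) {
  if (R <= 0 || c <= 0) stop("R and c must be > 0")
  w <- ((R - l) / R)^c
  w[l > R] <- 0
  w[l < 0] <- NA_real_
  w
}

#' Parameters for point-based FAI
#' @param R decay radius (m), default 200.
#' @param c decay exponent, default 2.
#' @param step integration grid step (m), default `R / 100`; must be
#'   `<= R / 10`.
#' @export
point_fai_params <- function(R = 200, c = 2, step = R / 100) {
  if (R <= 0 || c <= 0) stop("R and c must be > 0")
  if (step > R / 10) stop("integration too coarse: step must be <= R/10")
  structure(list(R = R, c = c, step = step), class = "point_fai_params")
}

# direction-averaged frontal-area density of each building (m^2 of frontal
# area per m^2 of footprint): h * mean projected width / footprint area.
# Integrating this density over a building's footprint recovers its
# direction-averaged frontal area, which makes the decayed area integral of
# point-based FAI consistent with the lot-based index.
building_fai_density <- function(buildings, rose = windrose()) {
  vapply(buildings, function(b) {
    w <- vapply(rose$theta, function(th) diff(proj_interval(b$xy, th)), 0)
    b$height * sum(w * rose$p) / polygon_area(b$xy)
  }, 0)
}

#' Point-based frontal area index
#'
#' Distance-decay-weighted FAI around a test point: the frontal-area density
#' of the surrounding buildings is integrated over the circle of radius `R`,
#' each surface element weighted by [decay_weight()] of its distance to the
#' point, and normalised by the circle area. The integral is discretised on a
#' regular grid of spacing `params$step`; halving the step changes the result
#' by well under 1% on realistic scenes.
#'
#' @param buildings full building list.
#' @param point length-2 numeric (x, y) in m.
#' @param params a [point_fai_params()].
#' @param rose a [windrose()].
#' @return unitless point-based FAI.
#' @export
point_fai <- function(buildings, point, params = point_fai_params(),
                      rose = windrose()) {
  R <- params$R; s <- params$step
  cand <- buildings_in_circle(buildings, point, R + 200)  # generous pre-cut
  if (!length(cand)) return(0)
  dens <- building_fai_density(cand, rose)
  off <- seq(-R + s / 2, R - s / 2, by = s)
  gx <- rep(point[1] + off, times = length(off))
  gy <- rep(point[2] + off, each = length(off))
  l <- sqrt((gx - point[1])^2 + (gy - point[2])^2)
  keep <- l <= R
  gx <- gx[keep]; gy <- gy[keep]; l <- l[keep]
  cell_dens <- numeric(length(gx))
  for (i in seq_along(cand)) {
    inb <- point_in_polygon(gx, gy, cand[[i]]$xy)
    cell_dens[inb] <- dens[i]      # footprints do not overlap in practice
  }
  sum(decay_weight(l, R, params$c) * cell_dens * s^2) / (pi * R^2)
}

#' Parameters for sky-view-factor horizon scanning
#' @param n_azimuths number of horizon-scan directions (>= 8), default 16.
#' @param d maximum scan distance (m), default 100.
#' @export
svf_params <- function(n_azimuths = 16, d = 100) {
  if (n_azimuths < 8) stop("need at least 8 azimuths")
  if (d <= 0) stop("scan distance must be > 0")
  structure(list(n_azimuths = n_azimuths, d = d), class = "svf_params")
}

#' Sky view factor from a digital surface model
#'
#' Horizon-scan estimate of the fraction of the sky hemisphere visible from a
#' point (horizontal viewpoint): along each of `n_azimuths` directions the
#' horizon elevation angle `phi` is the maximum of `atan((z - z0) / l)` over
#' scan distances `l` up to `d`, and `SVF = mean(cos^2 phi)`. 1 over open
#' ground, 0 when fully enclosed. Cells outside the DSM are treated as
#' unobstructed.
#'
#' @param dsm `raster_grid` of surface elevation (ground + buildings, m).
#' @param point length-2 numeric (x, y); must lie inside the DSM.
#' @param params an [svf_params()].
#' @export
sky_view_factor <- function(dsm, point, params = svf_params()) {
  as.vector(svf_points(dsm, matrix(point, 1), params))
}

#' @rdname sky_view_factor
#' @param xy 2-column matrix of points.
#' @export
svf_points <- function(dsm, xy, params = svf_params()) {
  xy <- matrix(xy, ncol = 2)
  z0 <- grid_sample(dsm, xy[, 1], xy[, 2])
  if (anyNA(z0)) stop("point outside DSM")
  az <- (seq_len(params$n_azimuths) - 1) * 2 * pi / params$n_azimuths
  step <- dsm$cellsize / 2
  ls <- seq(step, params$d, by = step)
  svf <- numeric(nrow(xy))
  for (a in az) {
    dx <- sin(a); dy <- cos(a)
    tanmax <- rep(0, nrow(xy))
    for (l in ls) {
      z <- grid_sample(dsm, xy[, 1] + l * dx, xy[, 2] + l * dy)
      z[is.na(z)] <- z0[is.na(z)]
      tanmax <- pmax(tanmax, (z - z0) / l)
    }
    svf <- svf + 1 / (1 + tanmax^2)        # cos^2(atan(t)) = 1/(1+t^2)
  }
  svf / params$n_azimuths
}

#' Surface roughness length within a buffer
#'
#' Rule-of-thumb morphometric estimate: one tenth of the mean height of the
#' buildings whose footprint centroid lies within the buffer; 0 where the
#' buffer holds no building.
#'
#' @param buildings full building list.
#' @param center length-2 numeric (x, y).
#' @param radius buffer radius (m).
#' @return roughness length z0 in m.
#' @export
roughness_length <- function(buildings, center, radius) {
  inside <- buildings_in_circle(buildings, center, radius)
  if (!length(inside)) return(0)
  0.1 * mean(vapply(inside, `[[`, 0, "height"))
}
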