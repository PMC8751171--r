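#' Seasonal PM2.5 surfaces from the fitted GTWR models
#'
#' Calls [predict_surface()] per season with that season's predictor grids
#' and calibration time; cells without AOD coverage propagate to nodata.
#'
#' @param fits named list of [gtwr()] fits, one per season.
#' @param grids_by_season named list (per season) of named predictor-grid
#'   lists.
#' @param times named numeric vector of season midpoint times (days).
#' @return named list of `raster_grid`s.
#' @export
seasonal_maps <- function(fits, grids_by_season, times) {
  out <- lapply(names(fits), function(se) {
    if (is.null(fits[[se]])) stop("no GTWR fit for season: ", se)
    predict_surface(fits[[se]], grids_by_season[[se]], times[[se]])
  })
  names(out) <- names(fits)
  out
}

#' Day-count-weighted annual combination of seasonal maps
#'
#' The annual surface at a cell is the day-count-weighted mean of the seasonal
#' values valid there (weights renormalised over the valid seasons); cells
#' valid in no season stay nodata. Identical seasonal maps combine to
#' themselves.
#'
#' @param maps named list of seasonal `raster_grid`s (aligned).
#' @param day_counts named numeric vector of days per season.
#' @return a `raster_grid`.
#' @export
annual_combine <- function(maps, day_counts) {
  stopifnot(length(maps) >= 1, all(names(maps) %in% names(day_counts)))
  tpl <- maps[[1]]
  acc <- matrix(0, grid_nrow(tpl), grid_ncol(tpl)); wt <- acc
  for (se in names(maps)) {
    v <- grid_values(maps[[se]])
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + day_counts[[se]] * v[ok]
    wt[ok] <- wt[ok] + day_counts[[se]]
  }
  out <- acc / wt
  out[wt == 0] <- NA_real_
  grid_set_values(tpl, out)
}

#' Road-space delta-PM2.5 layer with its validity mask
#'
#' Predicts the neighbourhood model on road-corridor cells only, and only
#' where every retained predictor lies inside its training range (the
#' no-extrapolation rule); all other cells are nodata. Returns the layer plus
#' a small mask report.
#'
#' @param model a `delta_mlr` from [fit_delta_mlr()].
#' @param morph morphology layers from [scene_morphology()].
#' @param metrics per-segment metric table from [segment_metrics()].
#' @return list with `delta` (`raster_grid`) and `report` (cell counts:
#'   road, in_range, out_of_range).
#' @export
delta_layer <- function(model, morph, metrics) {
  tpl <- morph$road_mask
  mask <- grid_values(tpl) > 0
  idx <- which(mask)
  seg <- grid_values(morph$segment)[idx]
  mrow <- match(seg, metrics$id)
  vars <- model$selection$selected
  newdat <- data.frame(row.names = seq_along(idx))
  for (v in vars) {
    newdat[[v]] <- switch(v,
      SVF = grid_values(morph$svf)[idx],
      FAI_POINT = grid_values(morph$fai_point)[idx],
      metrics[[v]][mrow])
  }
  ok <- rep(TRUE, length(idx))
  for (v in vars) {
    rg <- model$ranges[, v]
    ok <- ok & !is.na(newdat[[v]]) & newdat[[v]] >= rg[1] & newdat[[v]] <= rg[2]
  }
  pred <- rep(NA_real_, length(idx))
  cf <- stats::coef(model$fit)
  if (length(vars) == 0) pred[ok] <- cf[["(Intercept)"]]
  else {
    # the layer maps road-space anomalies: each predictor is referenced to
    # its mean over the valid road cells, so the valid-cell mean of the
    # layer equals the (near-zero) intercept of the site-centred fit
    acc <- rep(cf[["(Intercept)"]], sum(ok))
    for (v in vars)
      acc <- acc + cf[[v]] * (newdat[[v]][ok] - mean(newdat[[v]][ok]))
    pred[ok] <- acc
  }
  out <- matrix(NA_real_, grid_nrow(tpl), grid_ncol(tpl))
  out[idx] <- pred
  list(delta = grid_set_values(tpl, out),
       report = c(road = length(idx), in_range = sum(ok),
                  out_of_range = sum(!ok)))
}

#' Overlay the road-space delta layer on the city-scale map
#'
#' `final = city + delta` where the delta layer is valid, `final = city`
#' elsewhere; negative results are floored at 0 and counted.
#'
#' @param city city-scale `raster_grid` (ug/m3).
#' @param delta delta `raster_grid` (same geometry).
#' @return a `raster_grid` with attribute `n_floored`.
#' @export
overlay_maps <- function(city, delta) {
  if (!all(dim(city$values) == dim(delta$values)) ||
      city$cellsize != delta$cellsize || city$xmin != delta$xmin ||
      city$ymin != delta$ymin)
    stop("misaligned grids in overlay")
  cv <- grid_values(city); dv <- grid_values(delta)
  add <- !is.na(dv) & !is.na(cv)
  cv[add] <- cv[add] + dv[add]
  n_floor <- sum(cv < 0, na.rm = TRUE)
  cv[!is.na(cv) & cv < 0] <- 0
  out <- grid_set_values(city, cv)
  attr(out, "n_floored") <- n_floor
  out
}

#' Quicklook plot of a PM2.5 surface
#' @param g a `raster_grid`; `contour` threshold (ug/m3, default 35, the
#'   annual air-quality-objective limit used for map contouring).
#' @param contour contour level.
#' @param ... passed to [graphics::image()].
#' @export
plot_map <- function(g, contour = 35, ...) {
  v <- grid_values(g)
  z <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
  xs <- g$xmin + (seq_len(ncol(v)) - 0.5) * g$cellsize
  ys <- g$ymin + (seq_len(nrow(v)) - 0.5) * g$cellsize
  graphics::image(xs, ys, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  if (is.finite(contour))
    graphics::contour(xs, ys, z, levels = contour, add = TRUE)
  invisible(g)
}
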