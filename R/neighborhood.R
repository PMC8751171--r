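#' Hygroscopic-growth correction of light-scattering PM2.5 readings
#'
#' Laser-scattering monitors over-read at high humidity because droplet growth
#' inflates particle scattering. Raw readings are divided by the correction
#' factor `CF = 1 + 0.25 RH^2 / (1 - RH)` (RH as a fraction in [0, 1)):
#' `pm = pm_raw / CF`. CF is 1 at RH = 0 and increases with RH; the formula is
#' singular at RH = 1, which is rejected.
#'
#' @param pm_raw raw PM2.5 readings (ug/m3).
#' @param RH relative humidity as a fraction in `[0, 1)`.
#' @return corrected PM2.5 (ug/m3).
#' @export
rh_correct <- function(pm_raw, RH) {
  if (any(RH < 0 | RH >= 1)) stop("RH must be in [0, 1): correction factor singular at RH = 1")
  pm_raw / rh_correction_factor(RH)
}

#' @rdname rh_correct
#' @export
rh_correction_factor <- function(RH) 1 + 0.25 * RH^2 / (1 - RH)

#' Background adjustment of mobile samples
#'
#' Removes hour-to-hour and day-to-day drift using the fixed background
#' station: `pm_adj = pm - (background(hour) - mean background over the
#' campaign)`. Additive anomaly removal preserves the campaign-mean level
#' exactly. `ratio = TRUE` switches to multiplicative adjustment
#' (`pm * mean/bg(hour)`), preserving the campaign mean only approximately.
#'
#' @param samples data.frame of mobile samples with columns `pm` and `hour`
#'   (campaign hour index matching `background$hour`).
#' @param background data.frame with `hour` and `pm25` covering every sample
#'   hour.
#' @param ratio use multiplicative instead of additive adjustment.
#' @return `samples` with `pm` adjusted (and the raw values in `pm_unadj`).
#' @export
background_adjust <- function(samples, background, ratio = FALSE) {
  m <- match(samples$hour, background$hour)
  if (anyNA(m))
    stop("background series missing sample hour(s): ",
         paste(utils::head(unique(samples$hour[is.na(m)]), 5), collapse = ", "))
  bg <- background$pm25[m]
  bg_mean <- mean(bg)   # sample-weighted: preserves the campaign mean exactly
  samples$pm_unadj <- samples$pm
  samples$pm <- if (ratio) samples$pm * bg_mean / bg else
    samples$pm - (bg - bg_mean)
  samples
}

#' Site-relative PM2.5 deviations
#'
#' The neighbourhood-scale response: for each sample,
#' `delta = pm - mean(pm over the sample's site)` (the site average pools all
#' time slots after adjustment). Per-site deltas are mean-zero by
#' construction. Sites with fewer than `min_n` samples are an error.
#'
#' @param samples data.frame with `site` and `pm` columns.
#' @param min_n minimum samples per site (default 30).
#' @return `samples` with a `dpm25` column added.
#' @export
delta_pm25 <- function(samples, min_n = 30) {
  cnt <- table(samples$site)
  if (any(cnt < 2)) stop("site(s) with fewer than 2 samples: ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))
  if (any(cnt < min_n))
    warning("site(s) below ", min_n, " samples: ",
            paste(names(cnt)[cnt < min_n], collapse = ", "))
  site_mean <- tapply(samples$pm, samples$site, mean)
  samples$dpm25 <- as.numeric(samples$pm -
                                site_mean[as.character(samples$site)])
  samples
}

# squared distance from points to segment p0-p1 and snap parameter
dist_to_segment <- function(px, py, p0, p1) {
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  L2 <- dx * dx + dy * dy
  t <- if (L2 < 1e-18) rep(0, length(px)) else
    pmin(pmax(((px - p0[1]) * dx + (py - p0[2]) * dy) / L2, 0), 1)
  (px - (p0[1] + t * dx))^2 + (py - (p0[2] + t * dy))^2
}

#' Snap points to their nearest road segment
#'
#' @param roads a [road_graph()].
#' @param px,py point coordinates (m).
#' @param max_dist maximum snap distance (m); farther points get NA.
#' @return list with integer `segment` (edge id, NA if unsnappable) and
#'   `dist` (m).
#' @export
nearest_segment <- function(roads, px, py, max_dist = 25) {
  e <- roads$edges
  best <- rep(Inf, length(px)); seg <- rep(NA_integer_, length(px))
  for (i in seq_len(nrow(e))) {
    g <- e$geometry[[i]]
    for (k in seq_len(nrow(g) - 1)) {
      d2 <- dist_to_segment(px, py, g[k, ], g[k + 1, ])
      upd <- d2 < best
      best[upd] <- d2[upd]; seg[upd] <- e$id[i]
    }
  }
  d <- sqrt(best)
  seg[d > max_dist] <- NA_integer_
  list(segment = seg, dist = d)
}

#' Attach neighbourhood-scale predictors to mobile samples
#'
#' Each sample inherits the 8 network metrics of its nearest road segment
#' (samples farther than `max_dist` from any segment are dropped, with the
#' count reported), and gets point-based morphology computed at its own
#' location: sky view factor from the DSM and point-based FAI from the
#' building set.
#'
#' @param samples data.frame with `x`, `y` (m) sample coordinates.
#' @param scene a `city_scene` (roads, dsm, buildings).
#' @param metrics per-segment metric table from [segment_metrics()].
#' @param max_dist snap threshold (m), default 25.
#' @param svf_par,fai_par morphology parameters ([svf_params()],
#'   [point_fai_params()]).
#' @param rose [windrose()] for point FAI.
#' @param morph optional precomputed list with `svf` and `fai_point` rasters;
#'   when given, morphology is sampled from these surfaces instead of
#'   recomputed per point.
#' @return the snapped samples with columns `segment`, `SVF`, `FAI_POINT` and
#'   the 8 metric columns; attribute `n_dropped` counts unsnappable samples.
#' @export
attach_neighborhood_predictors <- function(samples, scene, metrics,
                                           max_dist = 25,
                                           svf_par = svf_params(),
                                           fai_par = point_fai_params(),
                                           rose = windrose(),
                                           morph = NULL) {
  ns <- nearest_segment(scene$roads, samples$x, samples$y, max_dist)
  drop <- is.na(ns$segment)
  if (any(drop))
    message(sum(drop), " sample(s) beyond ", max_dist, " m of any road: dropped")
  out <- samples[!drop, , drop = FALSE]
  out$segment <- ns$segment[!drop]
  mcols <- c("STRAIGHT", "BETWEEN", "CLOSE", "CONNECT", "CONTROL",
             "MDEPTH", "GINTEG", "LINTEG")
  out[mcols] <- metrics[match(out$segment, metrics$id), mcols]
  if (!is.null(morph)) {
    out$SVF <- grid_sample(morph$svf, out$x, out$y)
    out$FAI_POINT <- grid_sample(morph$fai_point, out$x, out$y)
  } else {
    out$SVF <- svf_points(scene$dsm, cbind(out$x, out$y), svf_par)
    out$FAI_POINT <- vapply(seq_len(nrow(out)), function(i)
      point_fai(scene$buildings, c(out$x[i], out$y[i]), fai_par, rose), 0)
  }
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Neighbourhood-scale delta-PM2.5 regression
#'
#' Ordinary least squares of the site-relative deviations on the
#' neighbourhood predictors, screened with the same rules as the city stage
#' (every retained term p < `alpha`, every VIF < `vif_max`; nothing is
#' forced). Because the response is defined relative to the site mean, the
#' predictors enter the same way (within-site estimator): when the table has
#' a `site` column each candidate is centred on its site mean, so the
#' coefficients are identified from within-site contrasts only — between-site
#' predictor variance carries no response variance by construction and would
#' only attenuate the fit. The campaign-wide mean of each retained predictor
#' is stored as the reference for mapping, and the raw training range of each
#' retained predictor supplies the no-extrapolation validity mask.
#'
#' @param delta_table output of [delta_pm25()] +
#'   [attach_neighborhood_predictors()].
#' @param candidates candidate predictor columns (default: SVF, FAI_POINT and
#'   the 8 network metrics).
#' @param alpha,vif_max screening thresholds (defaults 0.05 and 3).
#' @return object of class `delta_mlr`: the selection result, the final `lm`
#'   (on centred predictors), adjusted R2, per-predictor campaign means
#'   (`centers`) and raw training ranges (`ranges`).
#' @export
fit_delta_mlr <- function(delta_table,
                          candidates = c("SVF", "FAI_POINT", "STRAIGHT",
                                         "BETWEEN", "CLOSE", "CONNECT",
                                         "CONTROL", "MDEPTH", "GINTEG",
                                         "LINTEG"),
                          alpha = 0.05, vif_max = 3) {
  candidates <- intersect(candidates, names(delta_table))
  ok <- stats::complete.cases(delta_table[, candidates, drop = FALSE])
  tab <- delta_table[ok, , drop = FALSE]
  if (nrow(tab) < 10 * length(candidates))
    warning("fewer than 10 rows per candidate predictor")
  raw <- tab
  if (!is.null(tab$site))
    for (cn in candidates) tab[[cn]] <- tab[[cn]] - stats::ave(tab[[cn]],
                                                               tab$site)
  sel <- stepwise_select(tab, tab$dpm25, candidates, forced = character(0),
                         alpha = alpha, vif_max = vif_max)
  ranges <- if (length(sel$selected))
    vapply(sel$selected, function(cn) range(raw[[cn]]), numeric(2))
  else matrix(numeric(0), 2, 0)
  centers <- if (length(sel$selected))
    vapply(sel$selected, function(cn) mean(raw[[cn]]), 0)
  else numeric(0)
  structure(list(selection = sel, fit = sel$fit,
                 adj_r2 = summary(sel$fit)$adj.r.squared,
                 r2 = summary(sel$fit)$r.squared,
                 ranges = ranges, centers = centers, n = nrow(tab)),
            class = "delta_mlr")
}

#' @export
print.delta_mlr <- function(x, ...) {
  cat("delta-PM2.5 MLR:", if (length(x$selection$selected))
    paste(x$selection$selected, collapse = " + ") else "(intercept only)",
    "\n")
  cat(sprintf("  n = %d, R2 = %.3f, adj R2 = %.3f\n", x$n, x$r2, x$adj_r2))
  if (length(x$selection$selected)) {
    cf <- summary(x$fit)$coefficients
    tab <- data.frame(coef = cf[-1, 1], p = cf[-1, 4],
                      vif = x$selection$vif[rownames(cf)[-1]])
    print(signif(tab, 4))
  }
  invisible(x)
}

#' @export
coef.delta_mlr <- function(object, ...) stats::coef(object$fit)

#' @export
predict.delta_mlr <- function(object, newdata, ...) {
  # raw predictor values in; centred on the stored campaign means (the
  # mapping reference standing in for the per-site mean of the training fit)
  for (cn in names(object$centers))
    newdata[[cn]] <- newdata[[cn]] - object$centers[[cn]]
  stats::predict(object$fit, newdata = newdata)
}

#' Model report as a plain list (for JSON export)
#' @param x a `delta_mlr`.
#' @export
delta_report <- function(x) {
  cf <- summary(x$fit)$coefficients
  list(predictors = x$selection$selected,
       coefficients = stats::setNames(cf[, 1], rownames(cf)),
       p = stats::setNames(cf[, 4], rownames(cf)),
       vif = as.list(x$selection$vif),
       adj_r2 = x$adj_r2, n = x$n,
       ranges = apply(x$ranges, 2, identity, simplify = FALSE))
}
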