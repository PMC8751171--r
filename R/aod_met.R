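#' Per-overpass AOD scene with QA flags
#'
#' One satellite overpass of aerosol optical depth (0.55 um, unitless) on a
#' coarse grid, with the QA attributes the filtering rule consumes: a cloud
#' state per pixel (Clear / PossiblyCloudy / Cloudy), an adjacency state
#' (Clear / Adjacent) and a coastline flag marking pixels within the coastal
#' band that are retained regardless of cloud state.
#'
#' @param aod `raster_grid` of AOD values.
#' @param qa_cloud character matrix in {"Clear","PossiblyCloudy","Cloudy"}.
#' @param qa_adjacency character matrix in {"Clear","Adjacent"}.
#' @param coastline logical matrix: pixel lies within the coastal band.
#' @param sensor "Terra" or "Aqua".
#' @param date observation day (integer or Date).
#' @export
aod_scene <- function(aod, qa_cloud, qa_adjacency = NULL, coastline = NULL,
                      sensor = "Terra", date = 1L) {
  stopifnot(inherits(aod, "raster_grid"))
  d <- dim(aod$values)
  if (is.null(qa_adjacency)) qa_adjacency <- matrix("Clear", d[1], d[2])
  if (is.null(coastline)) coastline <- matrix(FALSE, d[1], d[2])
  if (!all(dim(qa_cloud) == d) || !all(dim(coastline) == d))
    stop("QA flag shape must match the AOD grid")
  structure(list(aod = aod, qa_cloud = qa_cloud, qa_adjacency = qa_adjacency,
                 coastline = coastline, sensor = sensor, date = date),
            class = "aod_scene")
}

#' @export
print.aod_scene <- function(x, ...) {
  cat(sprintf("aod_scene: %s day %s, %d x %d px, %.0f%% retained by QA\n",
              x$sensor, format(x$date), nrow(x$aod$values),
              ncol(x$aod$values), 100 * mean(qa_retain_mask(x))))
  invisible(x)
}

qa_retain_mask <- function(scene) {
  scene$qa_cloud %in% c("Clear", "PossiblyCloudy") | scene$coastline
}

#' AOD quality filtering
#'
#' Retains a pixel iff its cloud mask is "Clear" or "PossiblyCloudy"; pixels
#' carrying the coastline flag are additionally retained regardless of cloud
#' state (coastal urban areas would otherwise lose coverage). Everything else
#' becomes nodata. Idempotent.
#'
#' @param scene an [aod_scene()].
#' @return the scene with filtered AOD values and a logical `retained`
#'   attribute matrix.
#' @export
qa_filter <- function(scene) {
  keep <- matrix(qa_retain_mask(scene), nrow(scene$aod$values))
  v <- grid_values(scene$aod)
  v[!keep] <- NA_real_
  if (!any(keep)) warning("QA filter removed every AOD pixel")
  scene$aod <- grid_set_values(scene$aod, v)
  scene$retained <- keep
  scene
}

#' Merge Terra and Aqua overpasses into a daily AOD grid
#'
#' Per-pixel mean of the available (non-nodata) values from the two sensors;
#' nodata only where both are missing.
#'
#' @param terra,aqua [aod_scene()]s on the same grid and date (either may be
#'   NULL if the sensor had no overpass).
#' @return a `raster_grid` of daily mean AOD.
#' @export
daily_merge <- function(terra, aqua) {
  sc <- Filter(Negate(is.null), list(terra, aqua))
  if (!length(sc)) stop("no overpass to merge")
  g0 <- sc[[1]]$aod
  if (length(sc) == 2) {
    a <- sc[[1]]$aod; b <- sc[[2]]$aod
    if (!all(dim(a$values) == dim(b$values)) || a$cellsize != b$cellsize ||
        a$xmin != b$xmin || a$ymin != b$ymin)
      stop("AOD grid geometry mismatch between sensors")
    va <- grid_values(a); vb <- grid_values(b)
    n <- (!is.na(va)) + (!is.na(vb))
    va[is.na(va)] <- 0; vb[is.na(vb)] <- 0
    out <- (va + vb) / n
    out[n == 0] <- NA_real_
  } else out <- grid_values(g0)
  grid_set_values(g0, out)
}

# ---- ordinary kriging of station meteorology --------------------------------

# empirical semivariogram (equal-width bins to the max pair distance)
empirical_variogram <- function(x, y, z, n_bins = 8) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  gsq <- outer(z, z, "-")^2 / 2
  iu <- upper.tri(d)
  dd <- d[iu]; gg <- gsq[iu]
  br <- seq(0, max(dd) * 1.0001, length.out = n_bins + 1)
  bin <- cut(dd, br, include.lowest = TRUE, labels = FALSE)
  data.frame(h = tapply(dd, bin, mean),
             gamma = tapply(gg, bin, mean),
             n = as.vector(table(factor(bin, levels = seq_len(n_bins)))[
               sort(unique(bin))]))
}

# weighted least squares fit of an exponential model gamma(h)=c*(1-exp(-h/a))
# (zero nugget). Weights N(h)/gamma_model^2, the classic variogram WLS scheme.
fit_exponential_variogram <- function(ev) {
  sill0 <- max(ev$gamma); rng0 <- max(ev$h) / 3
  obj <- function(p) {
    c0 <- exp(p[1]); a0 <- exp(p[2])
    m <- c0 * (1 - exp(-ev$h / a0))
    sum(ev$n * (ev$gamma - m)^2 / pmax(m, 1e-12)^2)
  }
  fit <- try(stats::optim(log(c(max(sill0, 1e-9), rng0)), obj), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
  rng <- exp(fit$par[2])
  if (rng > 10 * max(ev$h) || rng < 1e-6 * max(ev$h)) return(NULL)
  list(sill = exp(fit$par[1]), range = rng)
}

exp_cov <- function(d, sill, range) sill * exp(-d / range)

#' Ordinary kriging of station values onto a grid or points
#'
#' Interpolates sparse station measurements (meteorology, here) with ordinary
#' kriging under an exponential variogram fitted by weighted least squares to
#' the empirical semivariogram, zero nugget — so the surface reproduces the
#' station values exactly and prediction weights sum to one. If the variogram
#' fit fails (e.g. a constant field) the function falls back to
#' inverse-distance weighting with a warning; a constant field stays constant
#' under both paths.
#'
#' @param values numeric station observations.
#' @param coords 2-column matrix of station coordinates (m); duplicates are an
#'   error.
#' @param target either a `raster_grid` (predict at every cell center) or a
#'   2-column matrix of points.
#' @param clip_min optional lower physical bound (e.g. 0 for wind speed or
#'   rainfall); clipped cells are counted in the `clipped` attribute.
#' @return a `raster_grid` (grid target) or numeric vector (point target).
#' @export
krige_met <- function(values, coords, target, clip_min = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4) stop("kriging needs at least 4 stations")
  if (anyDuplicated(round(coords, 9))) stop("duplicate station coordinates")
  if (inherits(target, "raster_grid")) {
    cc <- grid_coords(target)
    px <- as.vector(cc$x); py <- as.vector(cc$y)
  } else { px <- target[, 1]; py <- target[, 2] }

  ev <- empirical_variogram(coords[, 1], coords[, 2], values)
  vfit <- if (stats::var(values) < 1e-24) NULL else
    fit_exponential_variogram(ev)
  if (is.null(vfit)) {
    if (stats::var(values) >= 1e-24)
      warning("variogram fit failed; falling back to inverse-distance weighting")
    pred <- idw_predict(values, coords, px, py)
  } else {
    d_ss <- as.matrix(stats::dist(coords))
    K <- exp_cov(d_ss, vfit$sill, vfit$range)
    A <- rbind(cbind(K, 1), c(rep(1, n), 0))
    Ai <- try(solve(A), silent = TRUE)
    if (inherits(Ai, "try-error")) {
      warning("near-singular kriging system; falling back to inverse-distance weighting")
      pred <- idw_predict(values, coords, px, py)
    } else {
      d_ps <- sqrt(outer(px, coords[, 1], "-")^2 +
                     outer(py, coords[, 2], "-")^2)
      C <- cbind(exp_cov(d_ps, vfit$sill, vfit$range), 1)
      W <- C %*% t(Ai)                     # weights + Lagrange column
      pred <- as.vector(W[, seq_len(n), drop = FALSE] %*% values)
    }
  }
  n_clip <- 0L
  if (!is.null(clip_min)) {
    n_clip <- sum(pred < clip_min)
    pred <- pmax(pred, clip_min)
  }
  if (inherits(target, "raster_grid")) {
    out <- grid_set_values(target, matrix(pred, grid_nrow(target)))
    attr(out, "clipped") <- n_clip
    out
  } else structure(pred, clipped = n_clip)
}

idw_predict <- function(values, coords, px, py, power = 2) {
  d <- sqrt(outer(px, coords[, 1], "-")^2 + outer(py, coords[, 2], "-")^2)
  w <- 1 / pmax(d, 1e-12)^power
  hit <- d < 1e-9
  pred <- as.vector((w %*% values) / rowSums(w))
  if (any(hit)) pred[which(rowSums(hit) > 0)] <-
      values[apply(d[rowSums(hit) > 0, , drop = FALSE], 1, which.min)]
  pred
}
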