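#' Spatio-temporal kernel specification for GTWR
#'
#' Weights decay with the combined squared distance
#' `d2 = d_space^2 + lambda * d_time^2` (coordinates in m, times in days;
#' `lambda` is the spatio-temporal scale ratio, m^2/day^2). Gaussian kernel:
#' `w = exp(-d2 / h^2)`; bisquare: `w = (1 - d2/h^2)^2` for `d < h`, else 0.
#'
#' @param kernel "gaussian" or "bisquare".
#' @param h spatial bandwidth (m), > 0.
#' @param lambda spatio-temporal scale ratio, >= 0; 0 reduces GTWR to pure
#'   spatial GWR.
#' @export
st_kernel <- function(kernel = "gaussian", h, lambda = 0) {
  if (!kernel %in% c("gaussian", "bisquare")) stop("unknown kernel: ", kernel)
  if (h <= 0) stop("bandwidth h must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(kernel = kernel, h = h, lambda = lambda),
            class = "st_kernel")
}

#' Spatio-temporal weight between observations
#' @param d_space spatial distance(s) in m.
#' @param d_time temporal distance(s) in days.
#' @param spec an [st_kernel()].
#' @return weights in `[0, 1]`; 1 at zero distance.
#' @export
st_weight <- function(d_space, d_time, spec) {
  d2 <- d_space^2 + spec$lambda * d_time^2
  if (spec$kernel == "gaussian") exp(-d2 / spec$h^2)
  else ifelse(d2 < spec$h^2, (1 - d2 / spec$h^2)^2, 0)
}

gtwr_weights <- function(coords, times, i_xy, i_t, spec, drop_self = NA) {
  ds <- sqrt((coords[, 1] - i_xy[1])^2 + (coords[, 2] - i_xy[2])^2)
  w <- st_weight(ds, times - i_t, spec)
  if (!is.na(drop_self)) w[drop_self] <- 0
  w
}

local_wls <- function(X, y, w, ridge = 1e-8) {
  Xw <- X * w
  A <- crossprod(X, Xw)
  b <- crossprod(Xw, y)
  beta <- tryCatch(solve(A, b), error = function(e) {
    warning("singular local system: applying ridge jitter 1e-8")
    A <<- A + diag(ridge * max(diag(A)), ncol(X))
    solve(A, b)
  })
  list(beta = drop(beta), A = A)
}

#' Geographically and temporally weighted regression
#'
#' Fits the city-scale calibration model: at every observation a weighted
#' least-squares regression of the response on the design (AOD plus the
#' screened predictors), with weights from the spatio-temporal kernel centred
#' on that observation, giving location/time-varying coefficients. Reported
#' diagnostics: R-squared, adjusted R-squared with `tr(S)` effective
#' parameters (S the hat matrix assembled from the local fits), the
#' small-sample-corrected AICc
#' `n ln(RSS/n) + n ln(2 pi) + n (n + tr(S)) / (n - 2 - tr(S))`,
#' and leave-one-out CV R-squared on request.
#'
#' @param formula model formula, e.g. `pm25 ~ AOD + RES_300 + LONG`.
#' @param data data.frame of calibration rows.
#' @param coords 2-column matrix of observation coordinates (m).
#' @param times numeric vector of observation times (days).
#' @param spec an [st_kernel()].
#' @return an object of class `gtwr`: local `coefficients` (one row per
#'   observation), `fitted`, `residuals`, `trS`, `diagnostics`
#'   (r2, adj_r2, aicc), plus the calibration data needed for prediction.
#' @seealso [select_bandwidth()], [loocv()], [predict_surface()]
#' @export
gtwr <- function(formula, data, coords, times, spec) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop("too few observations for the design")
  coords <- as.matrix(coords)
  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  fitted <- numeric(n); lev <- numeric(n)
  for (i in seq_len(n)) {
    w <- gtwr_weights(coords, times, coords[i, ], times[i], spec)
    fit <- local_wls(X, y, w)
    beta[i, ] <- fit$beta
    fitted[i] <- sum(X[i, ] * fit$beta)
    # leverage: s_ii = x_i' A^-1 x_i w_i
    lev[i] <- drop(X[i, ] %*% solve(fit$A, X[i, ])) * w[i]
  }
  res <- y - fitted
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  trS <- sum(lev)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - trS)
  aicc <- gtwr_aicc(rss, n, trS)
  structure(list(call = match.call(), formula = formula,
                 coefficients = beta, fitted = fitted, residuals = res,
                 y = y, X = X, coords = coords, times = times, spec = spec,
                 trS = trS,
                 diagnostics = list(r2 = r2, adj_r2 = adj_r2, aicc = aicc,
                                    rss = rss, n = n, p = p)),
            class = "gtwr")
}

gtwr_aicc <- function(rss, n, trS) {
  if (n - 2 - trS <= 0) return(NA_real_)
  n * log(rss / n) + n * log(2 * pi) + n * (n + trS) / (n - 2 - trS)
}

#' @export
print.gtwr <- function(x, ...) {
  d <- x$diagnostics
  cat("GTWR fit:", deparse(x$formula), "\n")
  cat(sprintf("  kernel %s, h = %g m, lambda = %g\n",
              x$spec$kernel, x$spec$h, x$spec$lambda))
  cat(sprintf("  n = %d, tr(S) = %.2f, R2 = %.3f, adj R2 = %.3f, AICc = %.2f\n",
              d$n, x$trS, d$r2, d$adj_r2, d$aicc))
  invisible(x)
}

#' @export
summary.gtwr <- function(object, ...) {
  qs <- t(apply(object$coefficients, 2, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1)))
  colnames(qs) <- c("Min", "Q1", "Median", "Q3", "Max")
  out <- list(fit = object, coef_quartiles = qs,
              cv_r2 = attr(object, "cv_r2"))
  class(out) <- "summary.gtwr"
  out
}

#' @export
print.summary.gtwr <- function(x, ...) {
  print(x$fit)
  cat("local coefficients:\n")
  print(round(x$coef_quartiles, 4))
  if (!is.null(x$cv_r2)) cat(sprintf("LOOCV R2 = %.3f\n", x$cv_r2))
  invisible(x)
}

#' @export
coef.gtwr <- function(object, ...) object$coefficients

#' @export
fitted.gtwr <- function(object, ...) object$fitted

#' @export
residuals.gtwr <- function(object, ...) object$residuals

#' Predict from a GTWR fit at new locations/times
#'
#' Local coefficients are computed at each new point by weighted least squares
#' against the calibration observations, then applied to the new design row.
#'
#' @param object a [gtwr()] fit.
#' @param newdata data.frame with the model's predictor columns.
#' @param newcoords 2-column matrix of prediction coordinates (m).
#' @param newtimes numeric prediction times (days).
#' @param ... unused.
#' @export
predict.gtwr <- function(object, newdata, newcoords, newtimes, ...) {
  tt <- stats::delete.response(stats::terms(object$formula))
  Xn <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  newcoords <- as.matrix(newcoords)
  if (length(newtimes) == 1) newtimes <- rep(newtimes, nrow(Xn))
  out <- numeric(nrow(Xn))
  for (i in seq_len(nrow(Xn))) {
    w <- gtwr_weights(object$coords, object$times, newcoords[i, ],
                      newtimes[i], object$spec)
    fit <- local_wls(object$X, object$y, w)
    out[i] <- sum(Xn[i, ] * fit$beta)
  }
  out
}

#' @export
plot.gtwr <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "fitted", ylab = "observed",
                 main = "GTWR calibration", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Leave-one-out cross-validation R-squared
#'
#' For each observation the local fit is recomputed with the self-weight set
#' to zero; `CV R2 = 1 - sum (y - yhat_-i)^2 / sum (y - ybar)^2`.
#'
#' @param formula,data,coords,times,spec as in [gtwr()].
#' @export
loocv <- function(formula, data, coords, times, spec) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)
  if (n < 10) stop("LOOCV needs at least 10 observations")
  coords <- as.matrix(coords)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    w <- gtwr_weights(coords, times, coords[i, ], times[i], spec,
                      drop_self = i)
    fit <- local_wls(X, y, w)
    pred[i] <- sum(X[i, ] * fit$beta)
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' AICc-minimising bandwidth selection
#'
#' Evaluates the GTWR AICc over the (h, lambda) candidate grids, skips
#' candidates whose effective parameters leave AICc undefined
#' (`tr(S) >= n - 2`), picks the minimum, and refines h by golden-section
#' search between its grid neighbours within the winning lambda.
#'
#' @param formula,data,coords,times as in [gtwr()].
#' @param kernel kernel family.
#' @param h_grid spatial bandwidth candidates (m).
#' @param lambda_grid scale-ratio candidates.
#' @param refine logical: golden-section refinement of h (default TRUE).
#' @return list with `spec` (the selected [st_kernel()]), `profile`
#'   (data.frame h, lambda, aicc) and `aicc` of the winner.
#' @export
select_bandwidth <- function(formula, data, coords, times,
                             kernel = "gaussian", h_grid, lambda_grid = 0,
                             refine = TRUE) {
  if (!length(h_grid) || !length(lambda_grid)) stop("empty candidate grid")
  prof <- expand.grid(h = h_grid, lambda = lambda_grid)
  prof$aicc <- NA_real_
  for (k in seq_len(nrow(prof))) {
    f <- try(gtwr(formula, data, coords, times,
                  st_kernel(kernel, prof$h[k], prof$lambda[k])), silent = TRUE)
    if (!inherits(f, "try-error")) prof$aicc[k] <- f$diagnostics$aicc
  }
  if (all(is.na(prof$aicc))) stop("AICc undefined for every candidate")
  best <- which.min(prof$aicc)
  h_best <- prof$h[best]; lam <- prof$lambda[best]
  if (refine && length(h_grid) > 1) {
    hs <- sort(h_grid); ib <- match(h_best, hs)
    lo <- hs[max(ib - 1, 1)]; hi <- hs[min(ib + 1, length(hs))]
    if (hi > lo) {
      fobj <- function(h) {
        f <- try(gtwr(formula, data, coords, times, st_kernel(kernel, h, lam)),
                 silent = TRUE)
        if (inherits(f, "try-error") || is.na(f$diagnostics$aicc)) Inf
        else f$diagnostics$aicc
      }
      gr <- (sqrt(5) - 1) / 2
      a <- lo; b <- hi
      c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
      fc <- fobj(c1); fd <- fobj(d1)
      for (it in 1:20) {
        if (fc < fd) { b <- d1; d1 <- c1; fd <- fc
          c1 <- b - gr * (b - a); fc <- fobj(c1)
        } else { a <- c1; c1 <- d1; fc <- fd
          d1 <- a + gr * (b - a); fd <- fobj(d1)
        }
        if (abs(b - a) < 1e-3 * h_best) break
      }
      h_ref <- (a + b) / 2
      if (fobj(h_ref) < min(prof$aicc, na.rm = TRUE)) h_best <- h_ref
    }
  }
  list(spec = st_kernel(kernel, h_best, lam), profile = prof,
       aicc = min(prof$aicc, na.rm = TRUE))
}

#' Predict a PM2.5 surface from a GTWR fit
#'
#' At every cell whose predictor grids are all valid (cells without AOD
#' coverage become nodata), local coefficients are computed against the
#' calibration observations at the cell's location and the requested time,
#' and applied to the cell's predictor vector.
#'
#' @param fit a [gtwr()] fit.
#' @param grids named list of `raster_grid`s, one per predictor in the model
#'   (names must match the model terms; an `AOD` grid is required when AOD is
#'   in the model).
#' @param time prediction time (days), typically the season midpoint used in
#'   calibration.
#' @return a `raster_grid` of predicted PM2.5 (ug/m3).
#' @export
predict_surface <- function(fit, grids, time) {
  vars <- setdiff(colnames(fit$X), "(Intercept)")
  miss <- setdiff(vars, names(grids))
  if (length(miss)) stop("missing predictor grid(s): ",
                         paste(miss, collapse = ", "))
  tpl <- grids[[vars[1]]]
  nr <- grid_nrow(tpl); nc <- grid_ncol(tpl)
  V <- lapply(vars, function(v) as.vector(grid_values(grids[[v]])))
  names(V) <- vars
  Xc <- do.call(cbind, c(list(`(Intercept)` = rep(1, nr * nc)), V))
  valid <- rowSums(is.na(Xc)) == 0
  cc <- grid_coords(tpl)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  out <- rep(NA_real_, nr * nc)
  Xcal <- fit$X; ycal <- fit$y
  idx <- which(valid)
  for (i in idx) {
    w <- gtwr_weights(fit$coords, fit$times, c(px[i], py[i]), time, fit$spec)
    beta <- local_wls(Xcal, ycal, w)$beta
    out[i] <- sum(Xc[i, ] * beta)
  }
  grid_set_values(tpl, matrix(out, nr, nc))
}
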