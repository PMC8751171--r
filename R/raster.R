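#' Gridded raster layer in a projected metric CRS
#'
#' `raster_grid()` builds the package's raster container: a numeric matrix with
#' an affine georeference. Row 1 is the northernmost row, cells are addressed by
#' their centers, and extents are half-open (a point on the east/south edge of
#' the extent falls outside it). All gridded layers — land use, DSM, AOD, kriged
#' meteorology, prediction surfaces — use this one convention, so a world
#' coordinate resolves to the same cell in every module.
#'
#' @param values numeric matrix; row 1 = north.
#' @param xmin,ymin coordinates (m) of the south-west corner of the extent.
#' @param cellsize cell edge length in m; must be > 0.
#' @param crs CRS identifier string; must be projected/metric (geographic CRS
#'   are rejected — buffer areas and lengths in metres are central downstream).
#' @param nodata sentinel for missing cells; stored cells equal to `nodata`
#'   are treated as missing everywhere.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymin, cellsize,
                        crs = "LOCAL:metre", nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cellsize) || cellsize <= 0) stop("cell size must be > 0")
  if (is_geographic_crs(crs)) stop("projected CRS required, got '", crs, "'")
  g <- structure(list(values = values, xmin = xmin, ymin = ymin,
                      cellsize = cellsize, crs = crs, nodata = nodata),
                 class = "raster_grid")
  g
}

is_geographic_crs <- function(crs) {
  grepl("4326|4979|longlat|degree|CRS84|WGS ?84$", crs, ignore.case = TRUE)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)
grid_xmax <- function(g) g$xmin + grid_ncol(g) * g$cellsize
grid_ymax <- function(g) g$ymin + grid_nrow(g) * g$cellsize

#' @export
print.raster_grid <- function(x, ...) {
  v <- grid_values(x)
  cat(sprintf("raster_grid: %d x %d cells @ %g m [%s]\n",
              grid_nrow(x), grid_ncol(x), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n",
              x$xmin, grid_xmax(x), x$ymin, grid_ymax(x)))
  cat(sprintf("  values: min %.4g  max %.4g  (%d nodata)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Raster values with nodata as NA
#' @param g a `raster_grid`.
#' @return numeric matrix with nodata cells set to `NA`.
#' @export
grid_values <- function(g) {
  v <- g$values
  v[v == g$nodata] <- NA_real_
  v
}

#' Replace values, keeping georeference
#' @param g a `raster_grid`; `values` numeric matrix (NA allowed, stored as
#'   the grid's nodata sentinel).
#' @param values numeric matrix conforming to `dim(g)`.
#' @export
grid_set_values <- function(g, values) {
  values <- as.matrix(values)
  if (!all(dim(values) == dim(g$values))) stop("value matrix shape mismatch")
  values[is.na(values)] <- g$nodata
  g$values <- values
  g
}

#' World coordinate to (row, col) cell index
#'
#' Half-open convention: a point on the west/north edge of a cell belongs to
#' that cell. Points outside the extent give NA.
#' @param g a `raster_grid`; `x`,`y` coordinate vectors in m.
#' @param x,y numeric coordinate vectors (m).
#' @return list with integer vectors `row`, `col` (NA outside the extent).
#' @export
world_to_cell <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$cellsize) + 1L
  row <- floor((grid_ymax(g) - y) / g$cellsize) + 1L
  bad <- col < 1L | col > grid_ncol(g) | row < 1L | row > grid_nrow(g)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Cell index to world coordinate of the cell center
#' @param g a `raster_grid`.
#' @param row,col integer vectors of cell indices.
#' @return list with numeric vectors `x`, `y` (cell centers, m).
#' @export
cell_to_world <- function(g, row, col) {
  list(x = g$xmin + (col - 0.5) * g$cellsize,
       y = grid_ymax(g) - (row - 0.5) * g$cellsize)
}

#' Sample raster values at world coordinates (nearest cell)
#' @param g a `raster_grid`.
#' @param x,y coordinate vectors (m).
#' @return numeric vector; NA outside the extent or at nodata cells.
#' @export
grid_sample <- function(g, x, y) {
  rc <- world_to_cell(g, x, y)
  v <- grid_values(g)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- v[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Matrices of cell-center coordinates
#' @param g a `raster_grid`.
#' @return list of matrices `x`, `y` shaped like the grid.
#' @export
grid_coords <- function(g) {
  xs <- g$xmin + (seq_len(grid_ncol(g)) - 0.5) * g$cellsize
  ys <- grid_ymax(g) - (seq_len(grid_nrow(g)) - 0.5) * g$cellsize
  list(x = matrix(xs, grid_nrow(g), grid_ncol(g), byrow = TRUE),
       y = matrix(ys, grid_nrow(g), grid_ncol(g)))
}

# ---- plain-text raster I/O (ESRI ASCII grid + .prj sidecar) -----------------

#' Read / write rasters as ESRI ASCII grids
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by the
#' value matrix north row first — a plain-text, diffable format every GIS
#' reads. The CRS id travels in a `.prj` sidecar next to the file. Round trips
#' are bit-exact: values are written with full double precision.
#'
#' @param path file path (`.asc`).
#' @return `read_raster` returns a `raster_grid`; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% key)) stop("not an ESRI ASCII grid: ", path)
  h <- function(k) val[match(k, key)]
  nodata <- if ("nodata_value" %in% key) h("nodata_value") else -9999
  v <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(v, nrow = h("nrows"), ncol = h("ncols"), byrow = TRUE)
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) trimws(readLines(prj, n = 1L)) else "LOCAL:metre"
  raster_grid(m, h("xllcorner"), h("yllcorner"), h("cellsize"),
              crs = crs, nodata = nodata)
}

#' @rdname read_raster
#' @param g a `raster_grid` to write.
#' @export
write_raster <- function(g, path) {
  stopifnot(inherits(g, "raster_grid"))
  hdr <- c(sprintf("ncols %d", grid_ncol(g)),
           sprintf("nrows %d", grid_nrow(g)),
           sprintf("xllcorner %.17g", g$xmin),
           sprintf("yllcorner %.17g", g$ymin),
           sprintf("cellsize %.17g", g$cellsize),
           sprintf("NODATA_value %.17g", g$nodata))
  rows <- apply(g$values, 1L, function(r) paste(sprintf("%.17g", r),
                                                collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(g$crs, paste0(path, ".prj"))
  invisible(path)
}

# ---- resampling and focal sums ----------------------------------------------

#' Bilinear resampling to a finer cell size
#'
#' Used to smooth the coarse AOD grid down to the 10 m analysis resolution.
#' Interpolation is between the four surrounding source cell centers; outputs
#' therefore stay within their min/max, and a target cell whose center
#' coincides with a source center reproduces the source value exactly. Nodata
#' neighbours are dropped and the remaining bilinear weights renormalised; a
#' fully-nodata neighbourhood yields nodata. Beyond the outermost cell centers
#' values are extended by edge clamping.
#'
#' @param g source `raster_grid`.
#' @param target_cell target cell size (m); must divide the source cell size.
#' @return a `raster_grid` covering the same extent at `target_cell`.
#' @export
resample_bilinear <- function(g, target_cell) {
  ratio <- g$cellsize / target_cell
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target cell size must divide the source cell size")
  nr <- as.integer(grid_nrow(g) * round(ratio))
  nc <- as.integer(grid_ncol(g) * round(ratio))
  tx <- g$xmin + (seq_len(nc) - 0.5) * target_cell
  ty <- grid_ymax(g) - (seq_len(nr) - 0.5) * target_cell
  out <- matrix(bilinear_sample(g, rep(tx, each = nr), rep(ty, times = nc)),
                nr, nc)
  grid_set_values(raster_grid(matrix(g$nodata, nr, nc), g$xmin, g$ymin,
                              target_cell, crs = g$crs, nodata = g$nodata),
                  out)
}

#' @rdname resample_bilinear
#' @param x,y coordinate vectors (m) at which to evaluate the bilinear
#'   interpolant.
#' @export
bilinear_sample <- function(g, x, y) {
  v <- grid_values(g)
  fc <- (x - (g$xmin + g$cellsize / 2)) / g$cellsize + 1
  fr <- ((grid_ymax(g) - g$cellsize / 2) - y) / g$cellsize + 1
  fc <- pmin(pmax(fc, 1), grid_ncol(g))   # edge clamp
  fr <- pmin(pmax(fr, 1), grid_nrow(g))
  c0 <- pmax(pmin(floor(fc), grid_ncol(g) - 1L), 1L)
  r0 <- pmax(pmin(floor(fr), grid_nrow(g) - 1L), 1L)
  wc <- fc - c0; wr <- fr - r0
  val <- numeric(length(x)); wsum <- numeric(length(x))
  for (dr in 0:1) for (dc in 0:1) {
    w <- (if (dr == 0) 1 - wr else wr) * (if (dc == 0) 1 - wc else wc)
    nb <- v[cbind(pmin(r0 + dr, grid_nrow(g)), pmin(c0 + dc, grid_ncol(g)))]
    ok <- !is.na(nb) & w > 0
    val[ok] <- val[ok] + w[ok] * nb[ok]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  out <- val / wsum
  out[wsum == 0] <- NA_real_
  out
}

# Circular focal kernel: offsets whose cell-center distance to the center cell
# is <= radius. Identical to the cell-center-in-circle buffer counting rule.
circle_kernel <- function(radius, cellsize) {
  k <- floor(radius / cellsize)
  off <- seq(-k, k) * cellsize
  d <- sqrt(outer(off^2, off^2, "+"))
  (d <= radius + 1e-9) * 1
}

# 2-D 'same' convolution by FFT (kernel must have odd dimensions). Used for
# buffer focal sums over whole grids; accurate to ~1e-12 relative.
conv2_same <- function(m, k) {
  mr <- nrow(m); mc <- ncol(m); kr <- nrow(k); kc <- ncol(k)
  pr <- mr + kr - 1L; pc <- mc + kc - 1L
  M <- matrix(0, pr, pc); M[1:mr, 1:mc] <- m
  K <- matrix(0, pr, pc); K[1:kr, 1:kc] <- k
  full <- Re(stats::fft(stats::fft(M) * stats::fft(K), inverse = TRUE)) /
    (pr * pc)
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  full[(r0 + 1):(r0 + mr), (c0 + 1):(c0 + mc)]
}

# Focal sum of `m` (NA treated as 0) over the circular buffer; also returns
# the count of non-NA contributing cells for focal means.
focal_circle <- function(m, radius, cellsize) {
  k <- circle_kernel(radius, cellsize)
  ok <- !is.na(m)
  m0 <- m; m0[!ok] <- 0
  list(sum = conv2_same(m0, k), n = round(conv2_same(ok * 1, k)))
}
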