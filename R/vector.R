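#' Road network container
#'
#' An undirected road graph: a node table (id, x, y) and an edge table
#' (id, from, to, class, length) with the polyline geometry of every edge kept
#' in a list column. Road classes follow the five-level scheme used for the
#' line-density predictors: trunk, primary, secondary, tertiary, ordinary.
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (m).
#' @param edges data.frame with columns `id`, `from`, `to`, `class`, `length`
#'   and a list column `geometry` of 2-column coordinate matrices.
#' @export
road_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "road_graph")
}

ROAD_CLASSES <- c("trunk", "primary", "secondary", "tertiary", "ordinary")

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("road_graph: %d nodes, %d edges (%.2f km total)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length) / 1000))
  if (nrow(x$edges)) print(table(x$edges$class))
  invisible(x)
}

polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

#' Build a topologically clean road graph from line segments
#'
#' Endpoints closer than `snap` are merged into a single node so the graph is
#' usable for centrality analysis. Zero-length segments are rejected.
#'
#' @param geoms list of 2-column coordinate matrices (one polyline per road
#'   segment).
#' @param class character vector of road classes, one per segment.
#' @param id optional segment ids (default sequential).
#' @param snap snapping tolerance in m (default 1e-6).
#' @export
road_graph_from_segments <- function(geoms, class, id = seq_along(geoms),
                                     snap = 1e-6) {
  if (length(geoms) == 0L) {
    warning("empty road geometry: returning empty graph")
    return(road_graph(data.frame(id = integer(), x = numeric(), y = numeric()),
                      data.frame(id = integer(), from = integer(),
                                 to = integer(), class = character(),
                                 length = numeric())))
  }
  ends <- do.call(rbind, lapply(geoms, function(g) g[c(1, nrow(g)), ]))
  # snap: cluster endpoint coordinates on a grid of `snap` resolution
  key <- paste(round(ends[, 1] / snap), round(ends[, 2] / snap))
  uid <- match(key, unique(key))
  nodes <- data.frame(id = seq_along(unique(key)),
                      x = tapply(ends[, 1], uid, mean)[order(unique(uid))],
                      y = tapply(ends[, 2], uid, mean)[order(unique(uid))])
  lens <- vapply(geoms, polyline_length, 0)
  if (any(lens <= snap)) stop("zero-length road segment(s): ",
                              paste(id[lens <= snap], collapse = ", "))
  edges <- data.frame(id = id,
                      from = uid[seq(1, length(uid), 2)],
                      to = uid[seq(2, length(uid), 2)],
                      class = as.character(class),
                      length = lens)
  edges$geometry <- geoms
  road_graph(nodes, edges)
}

# ---- GeoJSON I/O (roads, points, buildings) ---------------------------------

read_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

feat_coords <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Read a road network from GeoJSON
#'
#' Expects a FeatureCollection of LineStrings with a `class` property per
#' feature (trunk/primary/secondary/tertiary/ordinary). Shared endpoints are
#' snapped within 1e-6 m into single graph nodes.
#'
#' @param path GeoJSON file.
#' @return a [road_graph()].
#' @export
read_roads <- function(path) {
  gj <- read_geojson(path)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0L)
    return(road_graph_from_segments(list(), character()))
  geoms <- vector("list", length(feats)); cls <- character(length(feats))
  ids <- integer(length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ids[i] <- if (!is.null(f$properties$id)) f$properties$id else i
    if (is.null(f$properties$class))
      stop("road feature ", ids[i], " is missing the road-class attribute")
    cls[i] <- f$properties$class
    geoms[[i]] <- feat_coords(f$geometry$coordinates)
  }
  road_graph_from_segments(geoms, cls, id = ids)
}

#' Write a road network (with optional per-segment properties) to GeoJSON
#' @param roads a [road_graph()].
#' @param path output file.
#' @param extra optional data.frame of per-segment properties (one row per
#'   edge, matched by position) written alongside `id` and `class`.
#' @export
write_roads <- function(roads, path, extra = NULL) {
  feats <- lapply(seq_len(nrow(roads$edges)), function(i) {
    e <- roads$edges[i, ]
    props <- list(id = e$id, class = e$class)
    if (!is.null(extra)) props <- c(props, as.list(extra[i, , drop = FALSE]))
    g <- e$geometry[[1]]
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(k) c(g[k, 1], g[k, 2]))))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a point layer from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Points.
#' @return data.frame with `x`, `y` and all feature properties as columns.
#' @export
read_points <- function(path) {
  gj <- read_geojson(path)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0L) {
    warning("empty point layer: ", path)
    return(data.frame(x = numeric(), y = numeric()))
  }
  rows <- lapply(feats, function(f) {
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      f$properties)
  })
  nm <- unique(unlist(lapply(rows, names)))
  out <- as.data.frame(lapply(nm, function(n)
    unlist(lapply(rows, function(r) if (is.null(r[[n]])) NA else r[[n]]))),
    col.names = nm)
  out
}

#' @rdname read_points
#' @param pts data.frame with `x`, `y` and property columns.
#' @export
write_points <- function(pts, path) {
  props <- setdiff(names(pts), c("x", "y"))
  feats <- lapply(seq_len(nrow(pts)), function(i) {
    list(type = "Feature", properties = as.list(pts[i, props, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(pts$x[i], pts$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write building footprints (polygons with a height property)
#' @param path GeoJSON FeatureCollection of Polygons with `height` (m).
#' @return list of buildings, each `list(id, xy, height)` with `xy` the
#'   exterior-ring coordinate matrix.
#' @export
read_buildings <- function(path) {
  gj <- read_geojson(path)
  lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (is.null(f$properties$height) || f$properties$height <= 0)
      stop("building ", i, " must have height > 0")
    list(id = if (is.null(f$properties$id)) i else f$properties$id,
         xy = feat_coords(f$geometry$coordinates[[1]]),
         height = f$properties$height)
  })
}

#' @rdname read_buildings
#' @param buildings list of `list(id, xy, height)` buildings.
#' @export
write_buildings <- function(buildings, path) {
  feats <- lapply(buildings, function(b) {
    ring <- lapply(seq_len(nrow(b$xy)), function(k) c(b$xy[k, 1], b$xy[k, 2]))
    list(type = "Feature",
         properties = list(id = b$id, height = b$height),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# point-in-polygon (even-odd rule), vectorised over points
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy); inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
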