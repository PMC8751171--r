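# Independent oracles used across the suite. Deliberately written with
# different algorithms from the package internals (path enumeration instead of
# dependency accumulation, ray casting instead of horizon scanning, plain
# loops instead of FFT focal sums).

# ---- graph oracles ----------------------------------------------------------

# all shortest paths between s and t by recursive backtracking on the
# distance matrix (Floyd-Warshall), returning a list of vertex vectors
oracle_shortest_paths <- function(W, s, t) {
  n <- nrow(W)
  D <- W
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  paths <- list()
  recurse <- function(v, acc) {
    if (v == s) { paths[[length(paths) + 1]] <<- rev(c(acc, s)); return() }
    for (u in seq_len(n))
      if (u != v && is.finite(W[u, v]) &&
          abs(D[s, u] + W[u, v] - D[s, v]) < 1e-9)
        recurse(u, c(acc, v))
  }
  if (is.finite(D[s, t]) && s != t) recurse(t, integer(0))
  list(paths = paths, dist = D)
}

# normalized betweenness / closeness / straightness of `targets` vertices by
# explicit enumeration (weights W = adjacency with Inf for non-edges, 0 diag)
oracle_centrality <- function(W, xy, targets) {
  n <- length(targets)
  bt <- stats::setNames(numeric(n), targets)
  D <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- oracle_shortest_paths(W, targets[i], targets[j])
    D <- sp$dist
    np <- length(sp$paths)
    if (!np) next
    for (p in sp$paths) {
      inner <- setdiff(p, c(targets[i], targets[j]))
      hit <- as.character(intersect(inner, targets))
      bt[hit] <- bt[hit] + 1 / np
    }
  }
  if (is.null(D)) D <- oracle_shortest_paths(W, targets[1], targets[1])$dist
  Dt <- D[targets, targets, drop = FALSE]
  close <- (n - 1) / rowSums(Dt)
  eu <- as.matrix(stats::dist(xy[targets, , drop = FALSE]))
  ratio <- eu / Dt; diag(ratio) <- NA
  straight <- rowMeans(ratio, na.rm = TRUE)
  list(betweenness = unname(bt) / ((n - 1) * (n - 2) / 2),
       closeness = unname(close), straightness = unname(straight))
}

# random connected planar-ish road graph with <= n_seg segments
random_road_graph <- function(n_nodes, seed) {
  set.seed(seed)
  xy <- cbind(runif(n_nodes, 0, 1000), runif(n_nodes, 0, 1000))
  # connect each node to its 2 nearest neighbours, keep largest component
  d <- as.matrix(dist(xy))
  geoms <- list(); cls <- character()
  for (i in seq_len(n_nodes)) {
    nb <- order(d[i, ])[2:3]
    for (j in nb) if (i < j) {
      geoms[[length(geoms) + 1]] <- rbind(xy[i, ], xy[j, ])
      cls <- c(cls, sample(c("trunk", "primary", "secondary", "tertiary",
                             "ordinary"), 1))
    }
  }
  road_graph_from_segments(geoms, cls)
}

# weight matrix of the midpoint-augmented primal graph of a road_graph
midpoint_weight_matrix <- function(roads) {
  n0 <- nrow(roads$nodes); m <- nrow(roads$edges)
  n <- n0 + m
  W <- matrix(Inf, n, n); diag(W) <- 0
  xy <- matrix(NA_real_, n, 2)
  xy[seq_len(n0), ] <- cbind(roads$nodes$x, roads$nodes$y)
  for (k in seq_len(m)) {
    e <- roads$edges[k, ]
    g <- e$geometry[[1]]
    mid <- (g[1, ] + g[nrow(g), ]) / 2
    xy[n0 + k, ] <- mid
    w <- e$length / 2
    W[e$from, n0 + k] <- W[n0 + k, e$from] <- w
    W[e$to, n0 + k] <- W[n0 + k, e$to] <- w
  }
  list(W = W, xy = xy, mids = n0 + seq_len(m))
}

# ---- morphology oracles -----------------------------------------------------

# Monte-Carlo sky view factor: cast rays sampled uniformly on the projected
# hemisphere (cosine weighting); a ray is blocked if the DSM surface rises
# above it anywhere along its ground track
oracle_svf_mc <- function(dsm, point, n_rays = 1e5, d_max = 100, seed = 42) {
  set.seed(seed)
  z0 <- grid_sample(dsm, point[1], point[2])
  az <- runif(n_rays, 0, 2 * pi)
  r <- sqrt(runif(n_rays))          # sin of zenith angle, cosine-weighted
  elev <- acos(r)                   # elevation angle above horizon
  step <- dsm$cellsize / 2
  ls <- seq(step, d_max, by = step)
  visible <- rep(TRUE, n_rays)
  for (l in ls) {
    x <- point[1] + l * sin(az); y <- point[2] + l * cos(az)
    z <- grid_sample(dsm, x, y)
    z[is.na(z)] <- z0
    ray_h <- z0 + l * tan(elev)
    visible <- visible & (z <= ray_h + 1e-9)
  }
  mean(visible)
}

# plain-loop fine-grid point-FAI integrator (no vectorised geometry reuse)
oracle_point_fai <- function(buildings, point, R, cexp, step, rose) {
  dens <- vapply(buildings, function(b) {
    wds <- vapply(rose$theta, function(th) {
      thr <- th * pi / 180
      pr <- b$xy[, 1] * cos(thr) - b$xy[, 2] * sin(thr)
      diff(range(pr))
    }, 0)
    b$height * sum(wds * rose$p) / polygon_area(b$xy)
  }, 0)
  total <- 0
  xs <- seq(point[1] - R + step / 2, point[1] + R - step / 2, by = step)
  ys <- seq(point[2] - R + step / 2, point[2] + R - step / 2, by = step)
  for (x in xs) for (y in ys) {
    l <- sqrt((x - point[1])^2 + (y - point[2])^2)
    if (l > R) next
    w <- ((R - l) / R)^cexp
    for (bi in seq_along(buildings))
      if (point_in_polygon(x, y, buildings[[bi]]$xy)) {
        total <- total + w * dens[bi] * step^2
        break
      }
  }
  total / (pi * R^2)
}

# ---- small builders ---------------------------------------------------------

make_building <- function(cx, cy, w, d, h, id = 1) {
  list(id = id,
       xy = rbind(c(cx - w / 2, cy - d / 2), c(cx + w / 2, cy - d / 2),
                  c(cx + w / 2, cy + d / 2), c(cx - w / 2, cy + d / 2)),
       height = h)
}

flat_dsm <- function(n = 60, cellsize = 1, z = 0) {
  raster_grid(matrix(z, n, n), 0, 0, cellsize)
}

# uniform ring wall at distance `r` with height giving elevation angle `ang`
ring_dsm <- function(ang_deg, r = 10, n = 41, cellsize = 1) {
  g <- flat_dsm(n, cellsize)
  cc <- grid_coords(g)
  ctr <- c(n * cellsize / 2, n * cellsize / 2)
  d <- sqrt((cc$x - ctr[1])^2 + (cc$y - ctr[2])^2)
  h <- matrix(0, n, n)
  h[d >= r] <- (d[d >= r]) * tan(ang_deg * pi / 180)
  grid_set_values(g, h)
}

tiny_config <- function(seed = 1, ...) {
  pipeline_config(seed = seed, buffer_radii = c(50, 100, 200),
                  extent = 800, aod_cell = 200, days_per_season = 4,
                  seasons = c("s1", "s2"), ...)
}

# memoised pipeline runs shared by the acceptance blocks
.pipe_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(seed, through = "mapping") {
  key <- paste0(seed, "_", through)
  if (is.null(.pipe_cache[[key]])) {
    cfg <- default_city_config(seed = seed)
    .pipe_cache[[key]] <- suppressWarnings(suppressMessages(
      lur_pipeline(cfg, through = through)))
  }
  .pipe_cache[[key]]
}
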