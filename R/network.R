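#' Segment dual graph for space-syntax metrics
#'
#' Each road segment becomes a node; two nodes are adjacent iff their segments
#' share an endpoint. This segment-based graph approximates an axial map while
#' staying fully determined by the road geometry.
#'
#' @param roads a [road_graph()].
#' @return an igraph object whose vertices are named by segment id.
#' @export
build_dual_graph <- function(roads) {
  e <- roads$edges
  if (!nrow(e)) stop("empty road graph")
  pairs <- NULL
  for (nd in unique(c(e$from, e$to))) {
    segs <- which(e$from == nd | e$to == nd)
    if (length(segs) >= 2) {
      cmb <- utils::combn(segs, 2)
      pairs <- cbind(pairs, cmb)
    }
  }
  g <- igraph::make_empty_graph(n = nrow(e), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(e$id))
  if (!is.null(pairs))
    g <- igraph::add_edges(g, as.vector(pairs))
  igraph::simplify(g)
}

# primal graph with a midpoint vertex inserted on every segment; returns the
# igraph plus the midpoint vertex ids and coordinates
midpoint_graph <- function(roads) {
  nd <- roads$nodes; e <- roads$edges
  n0 <- nrow(nd); m <- nrow(e)
  mid <- t(vapply(e$geometry, function(g) {
    # point at half the polyline length
    seg <- sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)
    cum <- c(0, cumsum(seg)); half <- cum[length(cum)] / 2
    k <- max(which(cum <= half + 1e-12)); k <- min(k, length(seg))
    t0 <- (half - cum[k]) / seg[k]
    g[k, ] + t0 * (g[k + 1, ] - g[k, ])
  }, numeric(2)))
  from <- c(e$from, n0 + seq_len(m))
  to <- c(n0 + seq_len(m), e$to)
  w <- rep(e$length / 2, 2)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  list(graph = g, mid_ids = n0 + seq_len(m), mid_xy = mid)
}

#' Per-segment centrality metrics
#'
#' Normalized straightness, betweenness and closeness for every road segment,
#' computed on the primal network with metric (length-weighted) shortest paths
#' and evaluated at segment midpoints inserted as graph vertices. Within each
#' connected component of size N segments: betweenness counts the fraction of
#' midpoint-pair geodesics passing through a segment, normalised by
#' (N-1)(N-2)/2; closeness is (N-1)/sum of network distances (1/m);
#' straightness is the mean Euclidean-to-network distance ratio, in (0, 1].
#' Components with fewer than 3 segments get betweenness 0.
#'
#' @param roads a [road_graph()].
#' @return data.frame with columns `id`, `STRAIGHT`, `BETWEEN`, `CLOSE`.
#' @export
centrality_metrics <- function(roads) {
  e <- roads$edges
  if (!nrow(e)) stop("empty road graph")
  mg <- midpoint_graph(roads)
  g <- mg$graph; mids <- mg$mid_ids; xy <- mg$mid_xy
  m <- length(mids)
  D <- igraph::distances(g, v = mids, to = mids,
                         weights = igraph::E(g)$weight)
  comp <- igraph::components(g)$membership[mids]
  eu <- as.matrix(stats::dist(xy))
  STRAIGHT <- CLOSE <- numeric(m)
  for (cp in unique(comp)) {
    idx <- which(comp == cp); n <- length(idx)
    if (n == 1) { STRAIGHT[idx] <- 1; CLOSE[idx] <- 0; next }
    Dc <- D[idx, idx, drop = FALSE]; Ec <- eu[idx, idx, drop = FALSE]
    ratio <- Ec / Dc; diag(ratio) <- NA
    STRAIGHT[idx] <- rowMeans(ratio, na.rm = TRUE)
    CLOSE[idx] <- (n - 1) / rowSums(Dc)
  }
  BETWEEN <- midpoint_betweenness(g, mids, comp)
  data.frame(id = e$id, STRAIGHT = STRAIGHT, BETWEEN = BETWEEN, CLOSE = CLOSE)
}

# Betweenness of the midpoint vertices over midpoint pairs, by shortest-path
# counting on the geodesic DAG (handles tied shortest paths exactly without
# enumerating them). Normalised per component by (N-1)(N-2)/2 pairs.
midpoint_betweenness <- function(g, mids, comp, tol = 1e-9) {
  nv <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  # adjacency lists
  nbr <- vector("list", nv); wts <- vector("list", nv)
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1]; b <- el[k, 2]
    nbr[[a]] <- c(nbr[[a]], b); wts[[a]] <- c(wts[[a]], w[k])
    nbr[[b]] <- c(nbr[[b]], a); wts[[b]] <- c(wts[[b]], w[k])
  }
  Dall <- igraph::distances(g, v = mids, weights = w)
  is_target <- rep(FALSE, nv); is_target[mids] <- TRUE
  CB <- numeric(nv)
  for (si in seq_along(mids)) {
    s <- mids[si]; ds <- Dall[si, ]
    reach <- which(is.finite(ds))
    ord <- reach[order(ds[reach])]
    sigma <- numeric(nv); sigma[s] <- 1
    for (v in ord) {
      if (v == s) next
      for (j in seq_along(nbr[[v]])) {
        u <- nbr[[v]][j]
        if (abs(ds[u] + wts[[v]][j] - ds[v]) < tol)
          sigma[v] <- sigma[v] + sigma[u]
      }
    }
    delta <- numeric(nv)
    for (v in rev(ord)) {
      if (v == s) next
      coef <- (if (is_target[v]) 1 else 0) + delta[v]
      for (j in seq_along(nbr[[v]])) {
        u <- nbr[[v]][j]
        if (abs(ds[u] + wts[[v]][j] - ds[v]) < tol)
          delta[u] <- delta[u] + sigma[u] / sigma[v] * coef
      }
    }
    acc <- delta; acc[s] <- 0
    CB[mids] <- CB[mids] + acc[mids]
  }
  bt <- CB[mids] / 2   # each unordered pair counted in both directions
  out <- numeric(length(mids))
  for (cp in unique(comp)) {
    idx <- which(comp == cp); n <- length(idx)
    out[idx] <- if (n >= 3) bt[idx] / ((n - 1) * (n - 2) / 2) else 0
  }
  out
}

# diamond-value normalisation constant used for integration
diamond_dk <- function(k) {
  2 * (k * (log2((k + 2) / 3) - 1) + 1) / ((k - 1) * (k - 2))
}

#' Per-segment space-syntax metrics
#'
#' Connectivity (degree), control value (sum of reciprocal neighbour degrees),
#' mean depth (mean topological distance to the other segments of the
#' component), global integration (reciprocal of the diamond-normalised real
#' relative asymmetry, RRA = RA / D_k with RA = 2(MD-1)/(k-2)), and local
#' integration (the same computed on the subgraph within `local_radius`
#' topological steps). Components with k <= 2, or nodes with RA <= 0, yield NA
#' integration with a warning.
#'
#' @param dual segment dual graph from [build_dual_graph()].
#' @param local_radius topological radius for local integration (default 3).
#' @return data.frame with `id`, `CONNECT`, `CONTROL`, `MDEPTH`, `GINTEG`,
#'   `LINTEG`.
#' @export
syntax_metrics <- function(dual, local_radius = 3) {
  n <- igraph::vcount(dual)
  deg <- igraph::degree(dual)
  adj <- igraph::adjacent_vertices(dual, igraph::V(dual))
  CONTROL <- vapply(adj, function(a)
    sum(1 / deg[as.integer(a)]), 0)
  D <- igraph::distances(dual)
  comp <- igraph::components(dual)$membership
  MDEPTH <- GINTEG <- rep(NA_real_, n)
  integ_of <- function(md, k) {
    if (k <= 2) return(NA_real_)
    ra <- 2 * (md - 1) / (k - 2)
    if (!is.finite(ra) || ra <= 0) return(NA_real_)
    diamond_dk(k) / ra
  }
  warned <- FALSE
  for (cp in unique(comp)) {
    idx <- which(comp == cp); k <- length(idx)
    if (k >= 2)
      MDEPTH[idx] <- rowSums(D[idx, idx, drop = FALSE]) / (k - 1)
    if (k <= 2) { warned <- TRUE; next }
    GINTEG[idx] <- vapply(MDEPTH[idx], integ_of, 0, k = k)
  }
  LINTEG <- vapply(seq_len(n), function(v) {
    nb <- which(D[v, ] <= local_radius & is.finite(D[v, ]))  # includes v
    k <- length(nb)
    if (k <= 2) return(NA_real_)
    sub <- igraph::induced_subgraph(dual, nb)
    dv <- igraph::distances(sub, v = match(v, nb))[1, ]
    integ_of(mean(dv[-match(v, nb)]), k)
  }, 0)
  if (warned || anyNA(GINTEG))
    warning("integration undefined for some segments (component k <= 2 or RA <= 0)")
  data.frame(id = igraph::V(dual)$name, CONNECT = as.integer(deg),
             CONTROL = CONTROL, MDEPTH = MDEPTH, GINTEG = GINTEG,
             LINTEG = LINTEG, stringsAsFactors = FALSE)
}

#' All eight per-segment network metrics
#'
#' Convenience wrapper joining [centrality_metrics()] (primal, length-weighted)
#' and [syntax_metrics()] (dual, topological) by segment id.
#'
#' @param roads a [road_graph()].
#' @param local_radius topological radius for local integration.
#' @return data.frame with segment `id`, `class`, and the 8 metrics.
#' @export
segment_metrics <- function(roads, local_radius = 3) {
  cen <- centrality_metrics(roads)
  syn <- syntax_metrics(build_dual_graph(roads), local_radius)
  syn$id <- type.convert(syn$id, as.is = TRUE)
  out <- merge(cen, syn, by = "id", sort = FALSE)
  out <- out[match(roads$edges$id, out$id), ]
  rownames(out) <- NULL
  cbind(out[, "id", drop = FALSE], class = roads$edges$class,
        out[, setdiff(names(out), "id")])
}
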