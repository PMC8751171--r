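path3 <- function() {
  road_graph_from_segments(list(rbind(c(0, 0), c(100, 0)),
                                rbind(c(100, 0), c(200, 0)),
                                rbind(c(200, 0), c(300, 0))),
                           rep("ordinary", 3))
}

test_that("dual graph encodes segment adjacency", {
  d <- build_dual_graph(path3())
  expect_equal(igraph::vcount(d), 3)
  expect_equal(igraph::degree(d), c(1, 2, 1), ignore_attr = TRUE)
  # 4-segment star -> complete graph K4
  star <- road_graph_from_segments(
    list(rbind(c(0, 0), c(100, 0)), rbind(c(0, 0), c(0, 100)),
         rbind(c(0, 0), c(-100, 0)), rbind(c(0, 0), c(0, -100))),
    rep("ordinary", 4))
  ds <- build_dual_graph(star)
  expect_equal(igraph::ecount(ds), 6)
  expect_true(all(igraph::degree(ds) == 3))
  # disconnected components preserved
  two <- road_graph_from_segments(
    list(rbind(c(0, 0), c(10, 0)), rbind(c(1000, 0), c(1010, 0))),
    rep("trunk", 2))
  expect_equal(igraph::components(build_dual_graph(two))$no, 2)
  expect_error(build_dual_graph(road_graph_from_segments(list(), character())),
               "empty")
})

test_that("three collinear segments give the textbook betweenness pattern", {
  cm <- centrality_metrics(path3())
  expect_equal(cm$BETWEEN, c(0, 1, 0))
  expect_equal(cm$STRAIGHT, c(1, 1, 1))   # straight line network
})

test_that("centrality matches brute-force enumeration on random graphs", {
  for (seed in 1:4) {
    rg <- random_road_graph(10, seed)            # <= 30 midpoint+node vertices
    cm <- centrality_metrics(rg)
    mg <- midpoint_weight_matrix(rg)
    orc <- oracle_centrality(mg$W, mg$xy, mg$mids)
    # oracle normalises over the whole set; restrict to connected graphs
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(is.finite(mg$W) & mg$W > 0,
                                          mode = "undirected"))$no
    if (comp == 1) {
      expect_equal(cm$BETWEEN, orc$betweenness, tolerance = 1e-12)
      expect_equal(cm$CLOSE, orc$closeness, tolerance = 1e-9)
      expect_equal(cm$STRAIGHT, orc$straightness, tolerance = 1e-9)
    }
  }
})

test_that("square-grid closeness equals the direct Dijkstra oracle", {
  sq <- road_graph_from_segments(
    list(rbind(c(0, 0), c(100, 0)), rbind(c(100, 0), c(100, 100)),
         rbind(c(100, 100), c(0, 100)), rbind(c(0, 100), c(0, 0))),
    rep("ordinary", 4))
  cm <- centrality_metrics(sq)
  mg <- midpoint_weight_matrix(sq)
  orc <- oracle_centrality(mg$W, mg$xy, mg$mids)
  expect_equal(cm$CLOSE, orc$closeness, tolerance = 1e-12)
})

test_that("space-syntax metrics follow their definitions", {
  # star dual graph: hub control = k, leaves 1/k
  star <- igraph::make_star(6, mode = "undirected")
  star <- igraph::set_vertex_attr(star, "name", value = as.character(1:6))
  syn <- suppressWarnings(syntax_metrics(star))
  expect_equal(syn$CONTROL[1], 5)
  expect_equal(syn$CONTROL[-1], rep(1 / 5, 5), ignore_attr = TRUE)
  expect_equal(syn$CONNECT, c(5L, rep(1L, 5)))
  # path of 3: end mean depth 1.5, middle 1.0
  p3 <- build_dual_graph(path3())
  s3 <- suppressWarnings(syntax_metrics(p3))
  expect_equal(s3$MDEPTH, c(1.5, 1.0, 1.5))
})

test_that("control values sum to the node count on any graph", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(sample(5:25, 1), 0.3)
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
    deg <- igraph::degree(g)
    g2 <- igraph::induced_subgraph(g, which(deg > 0))
    if (igraph::vcount(g2) < 3) next
    syn <- suppressWarnings(syntax_metrics(g2))
    expect_equal(sum(syn$CONTROL), igraph::vcount(g2), tolerance = 1e-12)
  }
})

test_that("mean depth and integration match enumeration on a known graph", {
  # 5-cycle: every node has depths 1,1,2,2 -> MD = 1.5; symmetric integration
  cyc <- igraph::make_ring(5)
  cyc <- igraph::set_vertex_attr(cyc, "name", value = as.character(1:5))
  syn <- syntax_metrics(cyc)
  expect_equal(syn$MDEPTH, rep(1.5, 5))
  ra <- 2 * (1.5 - 1) / (5 - 2)
  dk <- 2 * (5 * (log2((5 + 2) / 3) - 1) + 1) / ((5 - 1) * (5 - 2))
  expect_equal(syn$GINTEG, rep(dk / ra, 5), tolerance = 1e-12)
  expect_equal(syn$GINTEG, syn$LINTEG, tolerance = 1e-12)  # radius covers all
})

test_that("metrics are invariant under node relabeling", {
  rg <- random_road_graph(8, 99)
  cm1 <- centrality_metrics(rg)
  perm <- sample(nrow(rg$edges))
  rg2 <- rg
  rg2$edges <- rg$edges[perm, ]
  cm2 <- centrality_metrics(rg2)
  m <- match(cm1$id, cm2$id)
  expect_equal(cm1$BETWEEN, cm2$BETWEEN[m], tolerance = 1e-12)
  expect_equal(cm1$CLOSE, cm2$CLOSE[m], tolerance = 1e-12)
})

test_that("segment_metrics joins all eight metrics per segment", {
  rg <- random_road_graph(8, 7)
  sm <- suppressWarnings(segment_metrics(rg))
  expect_equal(nrow(sm), nrow(rg$edges))
  expect_true(all(c("STRAIGHT", "BETWEEN", "CLOSE", "CONNECT", "CONTROL",
                    "MDEPTH", "GINTEG", "LINTEG") %in% names(sm)))
  expect_true(all(sm$BETWEEN >= 0 & sm$BETWEEN <= 1))
  expect_true(all(sm$CONNECT == as.integer(sm$CONNECT)))
})
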