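test_that("network construction enforces the geometric invariants", {
  net <- grid_net(2, 100)
  expect_s3_class(net, "street_network")
  expect_equal(nrow(net$nodes), 9)
  expect_equal(nrow(net$edges), 12)
  ## edge shorter than its chord is rejected
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1000), y = c(0, 0))
  expect_error(street_network(nodes, data.frame(u = "a", v = "b",
                                                length_m = 900)),
               "below straight-line")
  expect_error(street_network(nodes, data.frame(u = "a", v = "b",
                                                length_m = -5)),
               "> 0")
  ## lon/lat-looking input is rejected, metre grids are not
  ll <- data.frame(id = c("a", "b"), x = c(-3.60, -3.61), y = c(37.18, 37.19))
  expect_error(street_network(ll, data.frame(u = "a", v = "b")),
               "lon/lat")
  small <- data.frame(id = c("a", "b"), x = c(0, 100), y = c(0, 0))
  expect_s3_class(street_network(small, data.frame(u = "a", v = "b")),
                  "street_network")
})

test_that("snapping: identity at nodes, midpoint symmetry, brute-force scan", {
  net <- grid_net(3, 100)
  ## a point exactly on a node snaps there with offset 0 or the edge length
  s <- snap_to_network(net, c(0, 0))
  expect_equal(s$snap_dist, 0)
  expect_true(s$offset == 0 || s$offset == net$edges$length[s$edge_id])
  expect_equal(c(s$x, s$y), c(0, 0))
  ## perpendicular from the midpoint of an edge
  s2 <- snap_to_network(net, c(50, 10))  # 10 m above midpoint of a bottom edge
  expect_equal(s2$offset, 50)
  expect_equal(s2$snap_dist, 10)
  ## random points agree with an exhaustive fine-grid scan over all segments
  set.seed(11)
  for (i in 1:25) {
    p <- runif(2, -30, 330)
    s <- snap_to_network(net, p)
    e <- net$edges
    best <- Inf
    for (j in seq_len(nrow(e))) {
      tt <- seq(0, 1, by = 1e-3)
      d <- sqrt((p[1] - (e$ux[j] + tt * (e$vx[j] - e$ux[j])))^2 +
                (p[2] - (e$uy[j] + tt * (e$vy[j] - e$uy[j])))^2)
      best <- min(best, min(d))
    }
    expect_lt(abs(s$snap_dist - best), 0.05)
  }
  expect_error(snap_to_network(net, c(NA, 0)))
})

test_that("network distance: trivial cases and symmetry", {
  net <- grid_net(2, 100)
  ## origin = destination
  expect_equal(shortest_network_distance(net, c(50, 0), c(50, 0)), 0)
  ## opposite corners of a 2x2 grid: Manhattan distance
  expect_equal(shortest_network_distance(net, c(0, 0), c(200, 200)), 400)
  ## symmetric
  a <- c(30, 0); b <- c(170, 200)
  expect_equal(shortest_network_distance(net, a, b),
               shortest_network_distance(net, b, a))
})

test_that("network distance matches the augmented-graph Dijkstra oracle", {
  net <- grid_net(4, 100)
  set.seed(21)
  for (i in 1:50) {
    p1 <- runif(2, 0, 400); p2 <- runif(2, 0, 400)
    s1 <- snap_to_network(net, p1)
    s2 <- snap_to_network(net, p2)
    got <- network_distances(net, s1, s2)
    want <- oracle_snap_distance(net, s1, s2)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("unroutable pairs return NA", {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 100, 5000, 5100), y = 0)
  edges <- data.frame(u = c("a", "c"), v = c("b", "d"))
  net <- street_network(nodes, edges)
  expect_true(is.na(shortest_network_distance(net, c(10, 0), c(5050, 0))))
})

test_that("network distances satisfy the triangle inequality", {
  net <- grid_net(4, 100)
  set.seed(31)
  for (i in 1:15) {
    ps <- lapply(1:3, function(k) snap_to_network(net, runif(2, 0, 400)))
    dab <- network_distances(net, ps[[1]], ps[[2]])
    dbc <- network_distances(net, ps[[2]], ps[[3]])
    dac <- network_distances(net, ps[[1]], ps[[3]])
    expect_lte(dac, dab + dbc + 1e-9)
    ## and dominate the straight line between snapped points
    expect_gte(dac + 1e-9, euclidean_distance(ps[[1]]$x, ps[[1]]$y,
                                              ps[[3]]$x, ps[[3]]$y))
  }
})

test_that("euclidean distance closed forms", {
  expect_equal(euclidean_distance(0, 0, 0, 0), 0)
  expect_equal(euclidean_distance(0, 0, 300, 400), 500)
  expect_equal(euclidean_distance(0, 0, 200, 200), 200 * sqrt(2))
})

test_that("network buffer: single-edge partial reach and saturation", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1000), y = 0)
  net <- street_network(nodes, data.frame(u = "a", v = "b"))
  ## school mid-edge, threshold below the distance to either node
  sa <- network_buffer(net, c(500, 0), threshold = 100)
  expect_equal(nrow(sa$segments), 1)
  expect_equal(sa$segments$from_m, 400)
  expect_equal(sa$segments$to_m, 600)
  expect_length(sa$reached_nodes, 0)
  ## footprint contains the school point
  expect_true(point_in_footprint(sa, 500, 0, method = "exact"))
  expect_gt(sa$area_ha, 0)
  ## saturation: threshold beyond the network diameter reaches every edge
  g4 <- grid_net(4, 100)
  sa2 <- network_buffer(g4, c(200, 200), threshold = 5000)
  expect_setequal(sa2$segments$edge_id, g4$edges$id)
  expect_equal(sum(sa2$segments$to_m - sa2$segments$from_m),
               sum(g4$edges$length))
  expect_setequal(sa2$reached_nodes, g4$nodes$id)
})

test_that("buffer reached set matches a single-source Dijkstra cut", {
  net <- grid_net(6, 250)
  sa <- network_buffer(net, c(750, 750), threshold = 1250)
  e <- net$edges
  d <- oracle_dijkstra(net$nodes$id, e$u, e$v, e$length,
                       grid_id(6, 4, 4))  # node at (750, 750)
  expect_setequal(sa$reached_nodes, names(d)[d <= 1250])
  ## per-node distances agree too
  expect_equal(unname(sa$node_dist[names(d)]), unname(d), tolerance = 1e-9)
})

test_that("buffer reached edges are monotone in the threshold", {
  net <- grid_net(5, 120)
  sa1 <- network_buffer(net, c(300, 300), threshold = 400)
  sa2 <- network_buffer(net, c(300, 300), threshold = 800)
  expect_true(all(sa1$segments$edge_id %in% sa2$segments$edge_id))
  ## covered length per edge grows
  c1 <- tapply(sa1$segments$to_m - sa1$segments$from_m, sa1$segments$edge_id,
               sum)
  c2 <- tapply(sa2$segments$to_m - sa2$segments$from_m, sa2$segments$edge_id,
               sum)
  expect_true(all(c1 <= c2[names(c1)] + 1e-9))
  expect_error(network_buffer(net, c(300, 300), threshold = -5))
})

test_that("intersection counting uses the degree >= 3 convention", {
  ## path graph: all degrees <= 2, no intersections
  nodes <- data.frame(id = as.character(1:4), x = c(0, 100, 200, 300), y = 0)
  edges <- data.frame(u = as.character(1:3), v = as.character(2:4))
  path <- street_network(nodes, edges)
  sa <- network_buffer(path, c(150, 0), threshold = 1000)
  expect_equal(count_intersections(sa, path), 0)
  ## full grid coverage: count equals the exhaustive degree scan
  net <- grid_net(4, 100)
  sa2 <- network_buffer(net, c(200, 200), threshold = 5000)
  deg <- igraph::degree(net$graph)
  expect_equal(count_intersections(sa2, net), sum(deg >= 3))
  ## interior nodes of a grid count, corners do not
  expect_equal(sum(deg >= 3), 25 - 4)  # all but the four corners
})

test_that("footprint area approximates the dilated-edge region", {
  ## one straight 1 km street, margin 25 m: area ~ rectangle + end caps
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1000), y = 0)
  net <- street_network(nodes, data.frame(u = "a", v = "b"))
  sa <- network_buffer(net, c(500, 0), threshold = 2000, margin = 25,
                       grid_res = 5)
  analytic <- (1000 * 50 + pi * 25^2) / 1e4
  expect_lt(abs(sa$area_ha - analytic) / analytic, 0.05)
})

test_that("geojson and csv round-trips preserve the network", {
  net <- grid_net(3, 100)
  gj <- withr::local_tempfile(fileext = ".geojson")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_network_geojson(net, gj)
  write_network_csv(net, cs)
  for (rt in list(read_network_geojson(gj), read_network_csv(cs))) {
    expect_equal(nrow(rt$nodes), nrow(net$nodes))
    expect_equal(nrow(rt$edges), nrow(net$edges))
    expect_equal(sum(rt$edges$length), sum(net$edges$length))
    expect_equal(shortest_network_distance(rt, c(0, 0), c(300, 300)),
                 shortest_network_distance(net, c(0, 0), c(300, 300)))
  }
})
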