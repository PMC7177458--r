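## Fixtures are built in code; oracles here are deliberately independent of
## the package's computation paths (plain-R Dijkstra, grid searches,
## exhaustive enumeration).

## Regular grid street network: nb x nb blocks of `block` metres.
grid_net <- function(nb = 4, block = 100) {
  gs <- nb + 1L
  idx <- function(r, c) (r - 1L) * gs + c
  nodes <- data.frame(id = as.character(seq_len(gs * gs)),
                      x = rep((0:nb) * block, times = gs),
                      y = rep((0:nb) * block, each = gs))
  rc <- expand.grid(r = 1:gs, c = 1:gs)
  h <- rc[rc$c < gs, ]; v <- rc[rc$r < gs, ]
  edges <- data.frame(u = c(idx(h$r, h$c), idx(v$r, v$c)),
                      v = c(idx(h$r, h$c + 1L), idx(v$r + 1L, v$c)))
  street_network(nodes, edges)
}

## Node id of grid position (row, col), 1-based, for grid_net(nb).
grid_id <- function(nb, r, c) as.character((r - 1L) * (nb + 1L) + c)

## Plain-R binary-heap-free Dijkstra over an edge list (u, v, w), undirected.
## Returns named distance vector over all node ids.
oracle_dijkstra <- function(node_ids, eu, ev, w, source) {
  n <- length(node_ids)
  dist <- stats::setNames(rep(Inf, n), node_ids)
  dist[source] <- 0
  visited <- stats::setNames(rep(FALSE, n), node_ids)
  adj <- split(seq_along(eu), eu)
  adj2 <- split(seq_along(ev), ev)
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    i <- cand[which.min(dist[cand])]
    visited[i] <- TRUE
    nm <- node_ids[i]
    for (k in c(adj[[nm]], adj2[[nm]])) {
      other <- if (eu[k] == nm) ev[k] else eu[k]
      nd <- dist[nm] + w[k]
      if (nd < dist[other]) dist[other] <- nd
    }
  }
  dist
}

## Brute-force snapped-point network distance: insert both snap points as
## temporary nodes splitting their edges, then run the plain Dijkstra on the
## augmented edge list.
oracle_snap_distance <- function(net, s1, s2) {
  e <- net$edges
  el <- data.frame(u = e$u, v = e$v, w = e$length, orig = e$id,
                   stringsAsFactors = FALSE)
  ids <- net$nodes$id
  at_node <- function(s) {
    L <- e$length[s$edge_id]
    if (s$offset < 1e-9) e$u[s$edge_id]
    else if (s$offset > L - 1e-9) e$v[s$edge_id]
    else NA_character_
  }
  n1 <- at_node(s1); n2 <- at_node(s2)
  if (is.na(n1) && is.na(n2) && s1$edge_id == s2$edge_id) {
    i <- s1$edge_id
    o <- sort(c(s1$offset, s2$offset))
    el <- el[el$orig != i, ]
    el <- rbind(el, data.frame(u = c(e$u[i], "snapA", "snapB"),
                               v = c("snapA", "snapB", e$v[i]),
                               w = c(o[1], o[2] - o[1], e$length[i] - o[2]),
                               orig = NA))
    n1 <- if (s1$offset <= s2$offset) "snapA" else "snapB"
    n2 <- if (s1$offset <= s2$offset) "snapB" else "snapA"
    ids <- c(ids, "snapA", "snapB")
  } else {
    split_at <- function(el, s, label) {
      i <- s$edge_id
      el <- el[is.na(el$orig) | el$orig != i, ]
      rbind(el, data.frame(u = c(e$u[i], label), v = c(label, e$v[i]),
                           w = c(s$offset, e$length[i] - s$offset),
                           orig = NA))
    }
    if (is.na(n1)) { el <- split_at(el, s1, "snap1"); n1 <- "snap1"
                     ids <- c(ids, "snap1") }
    if (is.na(n2)) { el <- split_at(el, s2, "snap2"); n2 <- "snap2"
                     ids <- c(ids, "snap2") }
  }
  d <- oracle_dijkstra(ids, el$u, el$v, el$w, n1)
  unname(d[n2])
}

## Exhaustive concordant-pair AUC (ties count half).
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

## VIF by explicit normal equations for column j of X.
oracle_vif <- function(X, j) {
  y <- X[, j]
  Z <- cbind(1, X[, -j, drop = FALSE])
  beta <- solve(crossprod(Z), crossprod(Z, y))
  res <- y - Z %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  1 / (1 - r2)
}

## Uniform parcel layer covering a grid city: one square parcel per block.
simple_parcels <- function(nb = 4, block = 100, inset = 10,
                           classes = "residential", residents = 100,
                           floor_area = 1000) {
  n <- nb * nb
  pr <- rep(1:nb, times = nb); pc <- rep(1:nb, each = nb)
  rings <- lapply(seq_len(n), function(i) {
    x0 <- (pc[i] - 1) * block + inset; x1 <- pc[i] * block - inset
    y0 <- (pr[i] - 1) * block + inset; y1 <- pr[i] * block - inset
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  })
  list(table = data.frame(parcel_id = paste0("p", 1:n),
                          use_class = rep_len(classes, n),
                          floor_area_m2 = rep_len(floor_area, n),
                          residents = rep_len(residents, n),
                          stringsAsFactors = FALSE),
       rings = rings)
}

## Small roster on a grid city with homes at nodes.
node_roster <- function(net, school_xy, n = 20, trips = 10, seed = 1) {
  set.seed(seed)
  idx <- sample(nrow(net$nodes), n, replace = TRUE)
  data.frame(pid = sprintf("T%03d", seq_len(n)), age_group = "child",
             gender = "female", home_x = net$nodes$x[idx],
             home_y = net$nodes$y[idx], school_id = "s1",
             trips = rep_len(trips, n), mode = "walk",
             stringsAsFactors = FALSE)
}
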