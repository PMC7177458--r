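## Street network: planar undirected graph with metric edge lengths.
## Shortest paths and connectivity are delegated to igraph; snapping,
## partial-edge arithmetic and network-distance buffers live here.

#' Construct a street network
#'
#' Builds the graph substrate for all route and catchment computation from a
#' node table and an undirected edge list. Coordinates must be in a projected
#' planar CRS in metres; inputs that look like geographic lon/lat degrees are
#' rejected (re-projection is the caller's job).
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (metres).
#' @param edges data.frame with columns `u`, `v` (node ids) and optionally
#'   `length_m`; missing lengths are recomputed as straight-line distances.
#' @return an object of class `street_network`: node and edge tables plus an
#'   igraph graph with edge weights in metres.
#' @details Invariants enforced: positive edge lengths, each length at least
#'   the straight-line distance between its endpoints, finite coordinates,
#'   no self-loops. Edges are stored with integer ids in input order; all
#'   tie-breaks downstream use these ids.
#' @export
street_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  stopifnot(all(c("id", "x", "y") %in% names(nodes)))
  stopifnot(all(c("u", "v") %in% names(edges)))
  if (nrow(nodes) == 0L || nrow(edges) == 0L) {
    stop("street_network: empty node or edge table")
  }
  if (anyDuplicated(nodes$id)) stop("street_network: duplicated node ids")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y))) {
    stop("street_network: non-finite node coordinates")
  }
  nodes <- data.frame(id = as.character(nodes$id), x = as.numeric(nodes$x),
                      y = as.numeric(nodes$y), stringsAsFactors = FALSE)
  u_idx <- match(as.character(edges$u), nodes$id)
  v_idx <- match(as.character(edges$v), nodes$id)
  if (anyNA(u_idx) || anyNA(v_idx)) {
    stop("street_network: edge references unknown node id")
  }
  if (any(u_idx == v_idx)) stop("street_network: self-loop edges not allowed")
  eu <- euclidean_distance(nodes$x[u_idx], nodes$y[u_idx],
                           nodes$x[v_idx], nodes$y[v_idx])
  len <- if ("length_m" %in% names(edges) && !all(is.na(edges$length_m))) {
    l <- as.numeric(edges$length_m)
    l[is.na(l)] <- eu[is.na(l)]
    l
  } else {
    eu
  }
  if (any(len <= 0)) stop("street_network: edge lengths must be > 0")
  if (any(len < eu * (1 - 1e-9) - 1e-9)) {
    stop("street_network: edge length below straight-line distance ",
         "between its endpoints")
  }
  ## Geographic-degree heuristic: coordinates all inside [-180, 180] x
  ## [-90, 90] *and* sub-metre edge spans can only be lon/lat data.
  if (all(abs(nodes$x) <= 180) && all(abs(nodes$y) <= 90) &&
      stats::median(eu) < 1) {
    stop("street_network: coordinates look like geographic lon/lat degrees; ",
         "supply a projected CRS in metres")
  }
  edges_df <- data.frame(
    id = seq_along(u_idx), u = nodes$id[u_idx], v = nodes$id[v_idx],
    u_idx = u_idx, v_idx = v_idx, length = len,
    ux = nodes$x[u_idx], uy = nodes$y[u_idx],
    vx = nodes$x[v_idx], vy = nodes$y[v_idx],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_edgelist(cbind(u_idx, v_idx), directed = FALSE)
  if (igraph::vcount(g) < nrow(nodes)) {
    g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- len
  structure(list(nodes = nodes, edges = edges_df, graph = g),
            class = "street_network")
}

#' @export
print.street_network <- function(x, ...) {
  cat("street_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      igraph::count_components(x$graph), "component(s)\n")
  invisible(x)
}

#' Snap points to the nearest edge of a street network
#'
#' Orthogonal projection of each point onto the nearest edge segment. Ties are
#' broken deterministically towards the lowest edge id, then the lowest offset.
#'
#' @param net a `street_network`.
#' @param x,y point coordinates (metres), vectorised.
#' @return data.frame with one row per point: `edge_id`, `offset` (metres
#'   along the edge's stated length from its `u` endpoint), snapped `x`, `y`,
#'   and `snap_dist` (metres from the input point to the network).
#' @export
snap_points <- function(net, x, y) {
  stopifnot(inherits(net, "street_network"))
  stopifnot(length(x) == length(y), all(is.finite(c(x, y))))
  n <- length(x)
  if (n == 0L) {
    return(data.frame(edge_id = integer(), offset = numeric(),
                      x = numeric(), y = numeric(), snap_dist = numeric()))
  }
  e <- net$edges
  best_d <- rep(Inf, n)
  best_e <- rep(NA_integer_, n)
  best_t <- rep(NA_real_, n)
  best_x <- rep(NA_real_, n)
  best_y <- rep(NA_real_, n)
  ## ascending edge id + strict improvement => lowest-edge-id tie-break
  for (i in seq_len(nrow(e))) {
    ps <- point_segment_distance(x, y, e$ux[i], e$uy[i], e$vx[i], e$vy[i])
    upd <- ps$dist < best_d - 1e-9
    if (any(upd)) {
      best_d[upd] <- ps$dist[upd]
      best_e[upd] <- e$id[i]
      best_t[upd] <- ps$t[upd]
      best_x[upd] <- ps$x[upd]
      best_y[upd] <- ps$y[upd]
    }
  }
  data.frame(edge_id = best_e, offset = best_t * e$length[best_e],
             x = best_x, y = best_y, snap_dist = best_d)
}

#' @rdname snap_points
#' @param p length-2 numeric vector `c(x, y)`.
#' @export
snap_to_network <- function(net, p) {
  snap_points(net, p[1], p[2])
}

## Network distance from a snapped location to every node, as a numeric
## vector aligned with net$nodes (Inf where unroutable).
node_distances_from_snap <- function(net, snap) {
  e <- net$edges[snap$edge_id, ]
  D <- igraph::distances(net$graph, v = c(e$u_idx, e$v_idx),
                         algorithm = "dijkstra")
  pmin(snap$offset + D[1, ], (e$length - snap$offset) + D[2, ])
}

#' Shortest network distance between snapped locations
#'
#' Minimum-cost path length between the snapped origin and each snapped
#' destination, including the partial-edge offsets at both ends; symmetric in
#' origin and destination. Pairs in disconnected components yield `NA`
#' (unroutable; callers exclude such participants with a logged reason).
#'
#' @param net a `street_network`.
#' @param origin_snap one-row snap (from [snap_points()]).
#' @param dest_snaps snap data.frame, any number of rows.
#' @return numeric vector of metres, `NA` where unroutable.
#' @export
network_distances <- function(net, origin_snap, dest_snaps) {
  stopifnot(inherits(net, "street_network"), nrow(origin_snap) == 1L)
  if (nrow(dest_snaps) == 0L) return(numeric())
  nd <- node_distances_from_snap(net, origin_snap)
  ed <- net$edges[dest_snaps$edge_id, ]
  via <- pmin(nd[ed$u_idx] + dest_snaps$offset,
              nd[ed$v_idx] + (ed$length - dest_snaps$offset))
  same <- which(dest_snaps$edge_id == origin_snap$edge_id)
  if (length(same)) {
    direct <- abs(dest_snaps$offset[same] - origin_snap$offset)
    via[same] <- pmin(via[same], direct)
  }
  via[!is.finite(via)] <- NA_real_
  unname(via)
}

#' @rdname network_distances
#' @param origin,dest length-2 numeric vectors `c(x, y)` (unsnapped).
#' @export
shortest_network_distance <- function(net, origin, dest) {
  o <- snap_to_network(net, origin)
  d <- snap_to_network(net, dest)
  network_distances(net, o, d)
}

## Merge a two-column matrix of [a, b] intervals on a line; returns matrix.
merge_intervals <- function(iv) {
  iv <- iv[iv[, 2] > iv[, 1] + 1e-12, , drop = FALSE]
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1] <= out[k, 2] + 1e-12) {
      out[k, 2] <- max(out[k, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Network-distance catchment buffer (service area) around a school
#'
#' All edge portions whose network distance from the (snapped) school point is
#' at most `threshold` metres. An edge reached from one end with residual
#' budget r contributes its first r metres; reaches from both ends merge. The
#' footprint is the set of points within a pedestrian-access margin of any
#' reached portion; its area is measured on a deterministic grid of cell
#' centres (resolution `grid_res`).
#'
#' @param net a `street_network`.
#' @param school length-2 numeric `c(x, y)` of the school (metres).
#' @param threshold network distance threshold in metres (> 0); the study
#'   defaults are 1250 m for children and 1350 m for adolescents.
#' @param margin pedestrian-access margin (metres) by which reached edges are
#'   dilated to form the footprint; default 25.
#' @param grid_res footprint grid resolution in metres; default 10.
#' @param school_id optional identifier carried into outputs.
#' @return object of class `service_area`: snapped school, per-node network
#'   distances, reached node ids, covered edge portions (with coordinates),
#'   footprint grid and `area_ha`.
#' @export
network_buffer <- function(net, school, threshold, margin = 25,
                           grid_res = 10, school_id = NA_character_) {
  stopifnot(inherits(net, "street_network"), threshold > 0, margin > 0)
  snap <- snap_to_network(net, school)
  nd <- node_distances_from_snap(net, snap)
  if (!any(is.finite(nd))) stop("network_buffer: school is unroutable")
  e <- net$edges
  r_u <- pmax(0, threshold - nd[e$u_idx])
  r_v <- pmax(0, threshold - nd[e$v_idx])
  segs <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    iv <- matrix(numeric(), ncol = 2)
    L <- e$length[i]
    if (r_u[i] > 0) iv <- rbind(iv, c(0, min(L, r_u[i])))
    if (r_v[i] > 0) iv <- rbind(iv, c(max(0, L - r_v[i]), L))
    if (e$id[i] == snap$edge_id) {
      iv <- rbind(iv, c(max(0, snap$offset - threshold),
                        min(L, snap$offset + threshold)))
    }
    iv <- merge_intervals(iv)
    if (nrow(iv)) {
      f1 <- iv[, 1] / L
      f2 <- iv[, 2] / L
      segs[[i]] <- data.frame(
        edge_id = e$id[i], from_m = iv[, 1], to_m = iv[, 2],
        x1 = e$ux[i] + f1 * (e$vx[i] - e$ux[i]),
        y1 = e$uy[i] + f1 * (e$vy[i] - e$uy[i]),
        x2 = e$ux[i] + f2 * (e$vx[i] - e$ux[i]),
        y2 = e$uy[i] + f2 * (e$vy[i] - e$uy[i]))
    }
  }
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.null(segs) || nrow(segs) == 0L) {
    stop("network_buffer: threshold reaches no edge portion")
  }
  grid <- footprint_grid(segs, margin, grid_res)
  structure(list(
    school_id = school_id, threshold = threshold, margin = margin,
    snap = snap, node_dist = stats::setNames(nd, net$nodes$id),
    reached_nodes = net$nodes$id[nd <= threshold + 1e-9],
    segments = segs, grid = grid,
    area_ha = sum(grid$covered) * grid$res^2 / 1e4
  ), class = "service_area")
}

## Mark grid cell centres within `margin` of any covered segment.
footprint_grid <- function(segs, margin, res) {
  x0 <- floor((min(segs$x1, segs$x2) - margin) / res) * res
  y0 <- floor((min(segs$y1, segs$y2) - margin) / res) * res
  x1 <- ceiling((max(segs$x1, segs$x2) + margin) / res) * res
  y1 <- ceiling((max(segs$y1, segs$y2) + margin) / res) * res
  nx <- max(1L, as.integer(round((x1 - x0) / res)))
  ny <- max(1L, as.integer(round((y1 - y0) / res)))
  covered <- matrix(FALSE, nrow = ny, ncol = nx)
  cx <- x0 + (seq_len(nx) - 0.5) * res
  cy <- y0 + (seq_len(ny) - 0.5) * res
  for (i in seq_len(nrow(segs))) {
    ix <- which(cx >= min(segs$x1[i], segs$x2[i]) - margin - res &
                cx <= max(segs$x1[i], segs$x2[i]) + margin + res)
    iy <- which(cy >= min(segs$y1[i], segs$y2[i]) - margin - res &
                cy <= max(segs$y1[i], segs$y2[i]) + margin + res)
    if (!length(ix) || !length(iy)) next
    px <- rep(cx[ix], each = length(iy))
    py <- rep(cy[iy], times = length(ix))
    d <- point_segment_distance(px, py, segs$x1[i], segs$y1[i],
                                segs$x2[i], segs$y2[i])$dist
    hit <- matrix(d <= margin, nrow = length(iy))
    covered[iy, ix] <- covered[iy, ix] | hit
  }
  list(x0 = x0, y0 = y0, res = res, nx = nx, ny = ny, covered = covered)
}

#' Test whether points fall inside a service-area footprint
#'
#' A point is in the footprint iff it lies within the pedestrian margin of a
#' reached edge portion. `method = "grid"` looks the point up on the footprint
#' grid (consistent with how `area_ha` is measured); `method = "exact"`
#' computes the distance to the covered segments.
#'
#' @param sa a `service_area`.
#' @param px,py point coordinates (metres), vectorised.
#' @param method "grid" or "exact".
#' @return logical vector.
#' @export
point_in_footprint <- function(sa, px, py, method = c("grid", "exact")) {
  method <- match.arg(method)
  if (method == "exact") {
    best <- rep(Inf, length(px))
    s <- sa$segments
    for (i in seq_len(nrow(s))) {
      d <- point_segment_distance(px, py, s$x1[i], s$y1[i],
                                  s$x2[i], s$y2[i])$dist
      best <- pmin(best, d)
    }
    return(best <= sa$margin)
  }
  g <- sa$grid
  ix <- as.integer(floor((px - g$x0) / g$res)) + 1L
  iy <- as.integer(floor((py - g$y0) / g$res)) + 1L
  ok <- ix >= 1L & ix <= g$nx & iy >= 1L & iy <= g$ny
  out <- rep(FALSE, length(px))
  out[ok] <- g$covered[cbind(iy[ok], ix[ok])]
  out
}

#' Count street intersections inside a service area
#'
#' An intersection is a network node of graph degree >= 3 (the standard GIS
#' convention: dead-ends and mid-block bends are excluded). Counted over the
#' nodes reached within the buffer's network-distance threshold.
#'
#' @param sa a `service_area` computed from `net`.
#' @param net the `street_network` the buffer was computed from.
#' @return integer count.
#' @export
count_intersections <- function(sa, net) {
  stopifnot(inherits(sa, "service_area"), inherits(net, "street_network"))
  deg <- igraph::degree(net$graph)
  idx <- match(sa$reached_nodes, net$nodes$id)
  sum(deg[idx] >= 3)
}

#' @export
print.service_area <- function(x, ...) {
  cat("service_area:", x$threshold, "m threshold,",
      length(x$reached_nodes), "reached nodes,",
      sprintf("%.1f ha footprint\n", x$area_ha))
  invisible(x)
}
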