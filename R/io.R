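## Readers and writers for the pipeline's exchange formats: GeoJSON
## FeatureCollections (street network LineStrings, land-use Polygons,
## service-area footprints) and plain CSV tables. Built on jsonlite; only the
## minimal GeoJSON subset the pipeline emits and consumes is supported.

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

write_feature_collection <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE)
  invisible(path)
}

read_feature_collection <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection: ", path)
  }
  fc$features
}

#' Read a street network from GeoJSON
#'
#' One edge per LineString feature (first to last coordinate); the optional
#' `length_m` property overrides the recomputed geometric length. Nodes are
#' keyed by coordinates rounded to 1e-6 m.
#'
#' @param path GeoJSON file.
#' @return a [street_network()].
#' @export
read_network_geojson <- function(path) {
  feats <- read_feature_collection(path)
  n <- length(feats)
  if (n == 0L) stop("read_network_geojson: no features in ", path)
  ux <- uy <- vx <- vy <- len <- numeric(n)
  for (i in seq_len(n)) {
    g <- feats[[i]]$geometry
    if (!identical(g$type, "LineString")) {
      stop("read_network_geojson: feature ", i, " is not a LineString")
    }
    cc <- g$coordinates
    xs <- vapply(cc, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(cc, function(p) as.numeric(p[[2]]), numeric(1))
    ux[i] <- xs[1]; uy[i] <- ys[1]
    vx[i] <- xs[length(xs)]; vy[i] <- ys[length(ys)]
    lm <- feats[[i]]$properties$length_m
    len[i] <- if (!is.null(lm)) as.numeric(lm) else {
      sum(sqrt(diff(xs)^2 + diff(ys)^2))
    }
  }
  key <- function(x, y) paste(round(x, 6), round(y, 6))
  all_key <- c(key(ux, uy), key(vx, vy))
  all_x <- c(ux, vx); all_y <- c(uy, vy)
  keep <- !duplicated(all_key)
  nodes <- data.frame(id = all_key[keep], x = all_x[keep], y = all_y[keep],
                      stringsAsFactors = FALSE)
  street_network(nodes, data.frame(u = key(ux, uy), v = key(vx, vy),
                                   length_m = len))
}

#' Write a street network to GeoJSON
#'
#' Each edge becomes a two-point LineString feature with a `length_m`
#' property. Deterministic output for a given network.
#'
#' @param net a `street_network`.
#' @param path output file.
#' @export
write_network_geojson <- function(net, path) {
  e <- net$edges
  feats <- lapply(seq_len(nrow(e)), function(i) {
    geojson_feature(
      geometry = list(type = "LineString",
                      coordinates = list(c(e$ux[i], e$uy[i]),
                                         c(e$vx[i], e$vy[i]))),
      properties = list(u = e$u[i], v = e$v[i], length_m = e$length[i]))
  })
  write_feature_collection(feats, path)
}

#' Read/write a street network as a CSV edge list
#'
#' Columns: `u,v,length_m,x_u,y_u,x_v,y_v`.
#'
#' @param path CSV file.
#' @return a [street_network()].
#' @export
read_network_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("u", "v", "length_m", "x_u", "y_u", "x_v", "y_v")
  if (!all(need %in% names(d))) {
    stop("read_network_csv: expected columns ", paste(need, collapse = ","))
  }
  key <- c(d$u, d$v)
  keep <- !duplicated(key)
  nodes <- data.frame(id = key[keep], x = c(d$x_u, d$x_v)[keep],
                      y = c(d$y_u, d$y_v)[keep], stringsAsFactors = FALSE)
  street_network(nodes, data.frame(u = d$u, v = d$v, length_m = d$length_m))
}

#' @rdname read_network_csv
#' @param net a `street_network`.
#' @export
write_network_csv <- function(net, path) {
  e <- net$edges
  utils::write.csv(data.frame(u = e$u, v = e$v, length_m = e$length,
                              x_u = e$ux, y_u = e$uy, x_v = e$vx,
                              y_v = e$vy),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a service area as a GeoJSON MultiPolygon
#'
#' The footprint is emitted as one capsule polygon per reached edge portion
#' (rectangle plus semicircular caps at the pedestrian margin). Properties:
#' `school_id`, `threshold_m`, `area_ha` and, when `net` is supplied,
#' `n_intersections`.
#'
#' @param sa a `service_area`.
#' @param path output file.
#' @param net optionally, the network, to include the intersection count.
#' @export
write_service_area_geojson <- function(sa, path, net = NULL) {
  s <- sa$segments
  m <- sa$margin
  caps <- lapply(seq_len(nrow(s)), function(i) {
    dx <- s$x2[i] - s$x1[i]; dy <- s$y2[i] - s$y1[i]
    L <- sqrt(dx^2 + dy^2)
    if (L < 1e-9) { dx <- 1; dy <- 0; L <- 1 }
    ang <- atan2(dy / L, dx / L)
    th1 <- ang + pi / 2 + seq(0, pi, length.out = 9)
    th2 <- ang - pi / 2 + seq(0, pi, length.out = 9)
    ring <- rbind(cbind(s$x1[i] + m * cos(th1), s$y1[i] + m * sin(th1)),
                  cbind(s$x2[i] + m * cos(th2), s$y2[i] + m * sin(th2)))
    ring <- rbind(ring, ring[1, ])
    lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
  })
  props <- list(school_id = sa$school_id, threshold_m = sa$threshold,
                area_ha = sa$area_ha)
  if (!is.null(net)) props$n_intersections <- count_intersections(sa, net)
  feat <- geojson_feature(
    geometry = list(type = "MultiPolygon",
                    coordinates = lapply(caps, function(r) list(r))),
    properties = props)
  write_feature_collection(list(feat), path)
}

#' Read a land-use parcel layer from GeoJSON
#'
#' Polygon features with properties `use_class` (one of the six classes:
#' residential, industrial, retail, office, public_service, recreational),
#' `floor_area_m2` and optionally `parcel_id` and `residents`.
#'
#' @param path GeoJSON file.
#' @return list with `table` (data.frame of properties) and `rings`
#'   (list of x/y matrices, outer ring of each polygon).
#' @export
read_parcels_geojson <- function(path) {
  feats <- read_feature_collection(path)
  rings <- vector("list", length(feats))
  tab <- data.frame(parcel_id = character(length(feats)),
                    use_class = character(length(feats)),
                    floor_area_m2 = numeric(length(feats)),
                    residents = numeric(length(feats)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    g <- feats[[i]]$geometry
    if (!identical(g$type, "Polygon")) {
      stop("read_parcels_geojson: feature ", i, " is not a Polygon")
    }
    ring <- g$coordinates[[1]]
    rings[[i]] <- cbind(
      vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
      vapply(ring, function(p) as.numeric(p[[2]]), numeric(1)))
    p <- feats[[i]]$properties
    tab$parcel_id[i] <- if (!is.null(p$parcel_id)) as.character(p$parcel_id)
                        else as.character(i)
    tab$use_class[i] <- as.character(p$use_class)
    tab$floor_area_m2[i] <- as.numeric(p$floor_area_m2)
    tab$residents[i] <- if (!is.null(p$residents)) as.numeric(p$residents)
                        else 0
  }
  bad <- setdiff(unique(tab$use_class), use_classes())
  if (length(bad)) {
    stop("read_parcels_geojson: unknown use_class value(s): ",
         paste(bad, collapse = ", "))
  }
  list(table = tab, rings = rings)
}

#' Write a land-use parcel layer to GeoJSON
#'
#' @param parcels list with `table` and `rings` as returned by
#'   [read_parcels_geojson()].
#' @param path output file.
#' @export
write_parcels_geojson <- function(parcels, path) {
  tab <- parcels$table
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    ring <- parcels$rings[[i]]
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
    geojson_feature(
      geometry = list(type = "Polygon", coordinates = list(coords)),
      properties = list(parcel_id = tab$parcel_id[i],
                        use_class = tab$use_class[i],
                        floor_area_m2 = tab$floor_area_m2[i],
                        residents = tab$residents[i]))
  })
  write_feature_collection(feats, path)
}

#' Read a participant roster from CSV
#'
#' UTF-8 CSV with header; empty fields are missing values. Expected columns:
#' `pid, age_group, gender, home_x, home_y, school_id, trips, mode`.
#'
#' @param path CSV file.
#' @return data.frame; `trips` integer (NA when unanswered), `mode` one of
#'   walk/bike/motorised/NA.
#' @export
read_participants_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("pid", "age_group", "home_x", "home_y", "school_id", "trips",
            "mode")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("read_participants_csv: missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!is.na(d$trips) & (d$trips < 0 | d$trips > 10))
  if (length(bad)) {
    stop("read_participants_csv: trips outside 0-10 at line(s) ",
         paste(bad + 1L, collapse = ", "))
  }
  d
}

#' Write an exclusion log as CSV (`pid,reason`)
#'
#' @param log data.frame with columns `pid`, `reason`.
#' @param path output file.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.csv(log[, c("pid", "reason")], path, row.names = FALSE)
  invisible(path)
}
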