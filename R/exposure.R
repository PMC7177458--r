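## Exposure variables: the three school-built-environment measures computed
## on catchment buffers (resident density, intersection density, mixed-use
## entropy as a z-value) and the two route measures (network distance, PRD),
## assembled into one record per routable participant.

#' The six land-use classes of the mixed-use index
#' @return character vector of class names.
#' @export
use_classes <- function() {
  c("residential", "industrial", "retail", "office", "public_service",
    "recreational")
}

#' Pedestrian route directness (PRD)
#'
#' Ratio of the shortest street-network distance to the straight-line
#' (Euclidean) distance between home and school. 1 means a perfectly direct
#' route; values at most 1.5 are conventionally "direct", above 1.5
#' "indirect". Values below 1 are geometrically impossible on a consistent
#' network and are returned with a data-quality warning (they arise from
#' address errors in real data).
#'
#' @param network_dist,euclid_dist distances in metres (vectorised).
#' @return PRD ratio; `NA` where `euclid_dist` is 0 (home at school).
#' @export
prd <- function(network_dist, euclid_dist) {
  out <- ifelse(euclid_dist > 0, network_dist / euclid_dist, NA_real_)
  if (any(euclid_dist == 0)) {
    warning("prd: zero straight-line distance (home at school); NA returned")
  }
  if (any(stats::na.omit(out) < 1 - 1e-9)) {
    warning("prd: values < 1 indicate inconsistent geometry; flag downstream")
  }
  out
}

#' Resident density of a buffer
#' @param residents resident count inside the footprint.
#' @param area_ha footprint area in hectares (> 0).
#' @return residents per hectare.
#' @export
resident_density <- function(residents, area_ha) {
  if (any(area_ha <= 0)) stop("resident_density: area_ha must be > 0")
  residents / area_ha
}

#' Intersection density of a buffer
#' @param n intersection count (nodes of degree >= 3) inside the buffer.
#' @param area_ha footprint area in hectares (> 0).
#' @return intersections per hectare.
#' @export
intersection_density <- function(n, area_ha) {
  if (any(area_ha <= 0)) stop("intersection_density: area_ha must be > 0")
  n / area_ha
}

#' Mixed-use diversity index (normalised land-use entropy)
#'
#' Shannon entropy of floor-area shares across land-use classes, normalised
#' by `ln k` so it lies in \[0, 1\]: 0 for a single use, 1 when the k classes
#' hold equal area. By default k is fixed at 6 (the six named classes), so an
#' absent class lowers the index — the "evenness across the named uses"
#' reading; `k = "present"` normalises by the number of classes with
#' positive area instead (sensitivity analysis).
#'
#' @param areas named numeric vector of class areas (m2); names must be a
#'   subset of [use_classes()] when `k = 6`.
#' @param k 6 (default) or "present".
#' @return entropy in \[0, 1\].
#' @export
mixed_use_index <- function(areas, k = 6) {
  if (any(areas < 0)) stop("mixed_use_index: negative areas")
  tot <- sum(areas)
  if (tot <= 0) stop("mixed_use_index: all areas are zero")
  if (identical(k, "present")) {
    kk <- sum(areas > 0)
    if (kk == 1L) return(0)
  } else {
    stopifnot(k == 6)
    if (!is.null(names(areas)) && !all(names(areas) %in% use_classes())) {
      stop("mixed_use_index: unknown use class names")
    }
    kk <- 6
  }
  p <- areas[areas > 0] / tot
  h <- -sum(p * log(p)) / log(kk)
  min(1, max(0, h))
}

#' z-scores with the population SD convention
#'
#' Used to normalise the per-school mixed-use index across schools. The SD is
#' the population SD (n denominator).
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return z-values with mean 0 and population SD 1.
#' @export
z_scores <- function(values) {
  if (length(values) < 2L) stop("z_scores: need >= 2 values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s < .Machine$double.eps) stop("z_scores: zero SD (constant input)")
  (values - m) / s
}

## Fraction of each parcel's area inside a footprint: share of footprint-grid
## cell centres that fall inside the parcel ring and are covered. Parcels
## wholly outside the grid contribute 0; parcels smaller than a grid cell
## fall back to their centroid.
parcel_footprint_fraction <- function(sa, rings) {
  g <- sa$grid
  cx <- g$x0 + (seq_len(g$nx) - 0.5) * g$res
  cy <- g$y0 + (seq_len(g$ny) - 0.5) * g$res
  vapply(rings, function(ring) {
    ix <- which(cx >= min(ring[, 1]) & cx <= max(ring[, 1]))
    iy <- which(cy >= min(ring[, 2]) & cy <= max(ring[, 2]))
    if (!length(ix) || !length(iy)) {
      px <- mean(range(ring[, 1])); py <- mean(range(ring[, 2]))
      return(as.numeric(point_in_footprint(sa, px, py)))
    }
    px <- rep(cx[ix], each = length(iy))
    py <- rep(cy[iy], times = length(ix))
    inside <- point_in_polygon(px, py, ring)
    if (!any(inside)) {
      px0 <- mean(range(ring[, 1])); py0 <- mean(range(ring[, 2]))
      return(as.numeric(point_in_footprint(sa, px0, py0)))
    }
    cov <- g$covered[cbind(rep(iy, times = length(ix)),
                           rep(ix, each = length(iy)))]
    sum(inside & cov) / sum(inside)
  }, numeric(1))
}

#' School-buffer measures for one service area
#'
#' Computes resident density, intersection density and the raw mixed-use
#' entropy of a school catchment. Parcels partially inside the footprint
#' contribute residents and floor area proportionally to their intersected
#' fraction (areal weighting on the footprint grid).
#'
#' @param net the `street_network`.
#' @param sa a `service_area` for the school.
#' @param parcels parcel layer (list with `table`, `rings`); `table` needs
#'   `use_class`, `floor_area_m2`, `residents`.
#' @param k entropy class-count convention, see [mixed_use_index()].
#' @return one-row data.frame: `school_id`, `threshold`, `area_ha`,
#'   `residents`, `res_density`, `n_intersections`, `int_density`,
#'   `mixed_use_raw`.
#' @export
buffer_measures <- function(net, sa, parcels, k = 6) {
  frac <- parcel_footprint_fraction(sa, parcels$rings)
  tab <- parcels$table
  residents <- sum(tab$residents * frac)
  n_int <- count_intersections(sa, net)
  areas <- tapply(tab$floor_area_m2 * frac, tab$use_class, sum)
  full <- stats::setNames(numeric(length(use_classes())), use_classes())
  full[names(areas)] <- areas
  mix <- if (sum(full) > 0) mixed_use_index(full, k = k) else NA_real_
  data.frame(school_id = sa$school_id, threshold = sa$threshold,
             area_ha = sa$area_ha, residents = residents,
             res_density = resident_density(residents, sa$area_ha),
             n_intersections = n_int,
             int_density = intersection_density(n_int, sa$area_ha),
             mixed_use_raw = mix, stringsAsFactors = FALSE)
}

#' Assemble the per-participant exposure table
#'
#' For each routable participant: home-school network distance (km), PRD, and
#' the three buffer measures of the participant's school at their age group's
#' catchment threshold, plus the dichotomised outcome. Participants whose
#' home and school are in disconnected components, or whose home coincides
#' with the school, are excluded with a logged reason; PRD < 1 records are
#' retained but flagged (dropped when `strict_prd = TRUE`).
#'
#' @param participants data.frame (after [apply_exclusions()]): `pid`,
#'   `age_group` (child|adolescent), `home_x`, `home_y`, `school_id`,
#'   `trips`.
#' @param schools data.frame: `school_id`, `x`, `y`.
#' @param net the `street_network`.
#' @param parcels parcel layer (list with `table`, `rings`).
#' @param thresholds named metres vector, default `c(child = 1250,
#'   adolescent = 1350)`.
#' @param margin,grid_res footprint parameters, see [network_buffer()].
#' @param k entropy convention, see [mixed_use_index()].
#' @param strict_prd drop PRD < 1 records instead of flagging.
#' @return data.frame with columns `pid, age_group, school_id, distance_km,
#'   prd, res_density, int_density, mixed_use_raw, mixed_use_z, acs_trips,
#'   acs_binary, flags`; attributes `exclusions` (data.frame pid/reason) and
#'   `buffer_table` (per school x threshold measures incl. `mixed_use_z`).
#' @export
build_exposure_table <- function(participants, schools, net, parcels,
                                 thresholds = c(child = 1250,
                                                adolescent = 1350),
                                 margin = 25, grid_res = 10, k = 6,
                                 strict_prd = FALSE) {
  stopifnot(all(c("pid", "age_group", "home_x", "home_y", "school_id",
                  "trips") %in% names(participants)))
  stopifnot(all(c("school_id", "x", "y") %in% names(schools)))
  if (nrow(participants) == 0L) {
    out <- empty_exposure_table()
    attr(out, "exclusions") <- data.frame(pid = character(),
                                          reason = character())
    return(out)
  }
  unknown <- setdiff(unique(participants$school_id), schools$school_id)
  if (length(unknown)) {
    stop("build_exposure_table: unknown school id(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!all(participants$age_group %in% names(thresholds))) {
    stop("build_exposure_table: age group without a configured threshold")
  }

  ## --- buffer measures, once per (school, age-group threshold) ------------
  combos <- unique(participants[, c("school_id", "age_group")])
  combos$threshold <- thresholds[combos$age_group]
  buf <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sc <- schools[schools$school_id == combos$school_id[i], ][1, ]
    sa <- network_buffer(net, c(sc$x, sc$y), combos$threshold[i],
                         margin = margin, grid_res = grid_res,
                         school_id = sc$school_id)
    bm <- buffer_measures(net, sa, parcels, k = k)
    bm$age_group <- combos$age_group[i]
    bm
  }))
  ## mixed-use z-value across schools, within each age-group threshold set
  buf$mixed_use_z <- NA_real_
  for (ag in unique(buf$age_group)) {
    sel <- buf$age_group == ag
    buf$mixed_use_z[sel] <- if (sum(sel) >= 2) z_scores(buf$mixed_use_raw[sel])
                            else 0
  }

  ## --- route measures ------------------------------------------------------
  ## Both legs of the PRD ratio are measured between the snapped endpoints,
  ## so network >= straight-line holds by construction on consistent inputs.
  p <- participants
  snaps <- snap_points(net, p$home_x, p$home_y)
  p$net_dist <- NA_real_
  p$euclid <- NA_real_
  for (sid in unique(p$school_id)) {
    sc <- schools[schools$school_id == sid, ][1, ]
    ssnap <- snap_to_network(net, c(sc$x, sc$y))
    sel <- which(p$school_id == sid)
    p$net_dist[sel] <- network_distances(net, ssnap, snaps[sel, ])
    p$euclid[sel] <- euclidean_distance(snaps$x[sel], snaps$y[sel],
                                        ssnap$x, ssnap$y)
  }

  excl <- data.frame(pid = character(), reason = character(),
                     stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(p))
  unroutable <- is.na(p$net_dist)
  if (any(unroutable)) {
    excl <- rbind(excl, data.frame(pid = p$pid[unroutable],
                                   reason = "unroutable"))
    drop <- drop | unroutable
  }
  at_school <- !drop & p$euclid == 0
  if (any(at_school)) {
    excl <- rbind(excl, data.frame(pid = p$pid[at_school],
                                   reason = "home_at_school"))
    drop <- drop | at_school
  }
  p <- p[!drop, , drop = FALSE]

  prd_val <- suppressWarnings(prd(p$net_dist, p$euclid))
  flags <- ifelse(prd_val < 1 - 1e-9, "prd_lt_1", "")
  if (strict_prd && any(flags == "prd_lt_1")) {
    bad <- flags == "prd_lt_1"
    excl <- rbind(excl, data.frame(pid = p$pid[bad], reason = "prd_lt_1"))
    p <- p[!bad, , drop = FALSE]
    prd_val <- prd_val[!bad]
    flags <- flags[!bad]
  }

  bkey <- paste(p$school_id, p$age_group)
  bidx <- match(bkey, paste(buf$school_id, buf$age_group))
  out <- data.frame(
    pid = p$pid, age_group = p$age_group, school_id = p$school_id,
    distance_km = p$net_dist / 1000, prd = prd_val,
    res_density = buf$res_density[bidx],
    int_density = buf$int_density[bidx],
    mixed_use_raw = buf$mixed_use_raw[bidx],
    mixed_use_z = buf$mixed_use_z[bidx],
    acs_trips = p$trips,
    acs_binary = dichotomize_acs(p$trips),
    flags = flags, stringsAsFactors = FALSE)
  attr(out, "exclusions") <- excl
  attr(out, "buffer_table") <- buf
  out
}

empty_exposure_table <- function() {
  data.frame(pid = character(), age_group = character(),
             school_id = character(), distance_km = numeric(),
             prd = numeric(), res_density = numeric(),
             int_density = numeric(), mixed_use_raw = numeric(),
             mixed_use_z = numeric(), acs_trips = integer(),
             acs_binary = integer(), flags = character(),
             stringsAsFactors = FALSE)
}

#' Write the exposure table as CSV
#' @param records exposure table from [build_exposure_table()].
#' @param path output file.
#' @export
write_exposure_table <- function(records, path) {
  cols <- c("pid", "age_group", "school_id", "distance_km", "prd",
            "res_density", "int_density", "mixed_use_z", "acs_trips",
            "acs_binary", "flags")
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}
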