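## Synthetic city: parametric street morphology (grid + cul-de-sacs +
## non-crossable superblocks), land-use parcels, residents, schools, homes,
## and a logistic commuting behaviour model with known coefficients. The
## generator emits exactly the formats the pipeline reads, so every stage is
## testable end to end without external data.

#' Synthetic city configuration
#'
#' Defaults emulate the study conditions: a walkable southern-European urban
#' grid, 826 children and 2142 adolescents across 24 schools (8 primary, 14
#' secondary, 2 serving both age groups), home-school
#' straight-line distances log-normal with median 0.8 km, and small injected
#' fractions of missing outcomes, cyclists and corrupted addresses to
#' exercise the exclusion funnel.
#'
#' @param blocks grid extent in blocks per side.
#' @param block_m block size in metres.
#' @param culdesac_frac fraction of street edges converted to dead ends.
#' @param superblocks number of non-crossable superblock areas.
#' @param superblock_blocks superblock side length in blocks.
#' @param landuse_conc Dirichlet concentration of district land-use shares
#'   (small = specialised districts, large = even mixing).
#' @param residents_mean,residents_disp negative-binomial mean and dispersion
#'   of residents per residential parcel.
#' @param n_schools number of schools.
#' @param school_mix named counts of school levels (`primary`, `secondary`,
#'   `both`); must sum to `n_schools`.
#' @param n_children,n_adolescents participants per age group.
#' @param home_meanlog,home_sdlog log-normal parameters of the home-school
#'   straight-line distance (metres).
#' @param missing_acs_frac,bike_frac,bad_coord_frac injected defect
#'   fractions.
#' @param thresholds per-age-group buffer thresholds (metres).
#' @param seed integer seed; the same seed and config give byte-identical
#'   outputs.
#' @return a `city_config` list.
#' @export
city_config <- function(blocks = 16, block_m = 120, culdesac_frac = 0.12,
                        superblocks = 2, superblock_blocks = 3,
                        landuse_conc = 1.0, residents_mean = 120,
                        residents_disp = 1.5, n_schools = 24,
                        school_mix = c(primary = 8, secondary = 14, both = 2),
                        n_children = 826, n_adolescents = 2142,
                        home_meanlog = log(800), home_sdlog = 0.55,
                        missing_acs_frac = 0.05, bike_frac = 0.02,
                        bad_coord_frac = 0.02,
                        thresholds = c(child = 1250, adolescent = 1350),
                        seed = 1L) {
  stopifnot(blocks >= 4, block_m > 0, culdesac_frac >= 0, culdesac_frac < 1,
            superblocks >= 0, sum(school_mix) == n_schools,
            all(c("primary", "secondary", "both") %in% names(school_mix)),
            missing_acs_frac >= 0, bike_frac >= 0, bad_coord_frac >= 0,
            missing_acs_frac + bike_frac + bad_coord_frac < 1)
  structure(as.list(environment()), class = "city_config")
}

#' Logistic commuting behaviour model
#'
#' Per-age-group coefficient vectors on the logit scale over (intercept,
#' intersection-density dummy, mixed-use dummy, distance in km, PRD). The
#' default slope signs reproduce the qualitative age-group contrast of the
#' study's stratified models (children: -, -, -, +; adolescents: +, +, -, +),
#' with intercepts targeting roughly 68%/71% active shares.
#'
#' @param children,adolescents named coefficient vectors
#'   (`intercept`, `int_d`, `mix_d`, `distance_km`, `prd`).
#' @return a `behaviour_model` list.
#' @export
behaviour_model <- function(
    children = c(intercept = -2.13, int_d = -0.369, mix_d = -0.420,
                 distance_km = -0.18, prd = 2.428),
    adolescents = c(intercept = -1.62, int_d = 0.495, mix_d = 0.711,
                    distance_km = -0.144, prd = 1.257)) {
  nm <- c("intercept", "int_d", "mix_d", "distance_km", "prd")
  stopifnot(identical(names(children), nm),
            identical(names(adolescents), nm),
            all(is.finite(c(children, adolescents))))
  structure(list(child = children, adolescent = adolescents),
            class = "behaviour_model")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate the synthetic city layers
#'
#' Grid street network with cul-de-sac conversion (edge removal, largest
#' component kept) and non-crossable superblocks (interior nodes removed so
#' routes must go around, raising PRD); land-use parcels tiling the blocks
#' with district-level Dirichlet class mixing; residents on residential
#' parcels; schools at well-separated street nodes. Regenerates (up to 5
#' attempts, with a warning) if too much of the grid disconnects.
#'
#' @param cfg a [city_config()].
#' @return list `net` (street_network), `parcels` (table + rings),
#'   `schools` (data.frame `school_id`, `x`, `y`, `level`).
#' @export
generate_city <- function(cfg) {
  stopifnot(inherits(cfg, "city_config"))
  set.seed(cfg$seed)
  for (attempt in 1:5) {
    city <- try(generate_city_once(cfg), silent = TRUE)
    if (!inherits(city, "try-error")) return(city)
    warning("generate_city: attempt ", attempt, " produced a fragmented ",
            "network; regenerating")
  }
  stop("generate_city: could not produce a connected city in 5 attempts")
}

generate_city_once <- function(cfg) {
  b <- cfg$blocks; bm <- cfg$block_m
  gs <- b + 1L                          # grid side in nodes
  idx <- function(r, c) (r - 1L) * gs + c
  nodes <- data.frame(
    id = as.character(seq_len(gs * gs)),
    x = rep((0:b) * bm, times = gs),
    y = rep((0:b) * bm, each = gs))
  ## horizontal + vertical grid edges
  rc <- expand.grid(r = 1:gs, c = 1:gs)
  h <- rc[rc$c < gs, ]; v <- rc[rc$r < gs, ]
  edges <- data.frame(
    u = c(idx(h$r, h$c), idx(v$r, v$c)),
    v = c(idx(h$r, h$c + 1L), idx(v$r + 1L, v$c)))
  ## superblocks: remove interior nodes of s x s block areas
  drop_nodes <- integer()
  if (cfg$superblocks > 0) {
    s <- cfg$superblock_blocks
    ori <- cbind(sample(seq_len(b - s + 1L), cfg$superblocks, replace = TRUE),
                 sample(seq_len(b - s + 1L), cfg$superblocks, replace = TRUE))
    for (k in seq_len(cfg$superblocks)) {
      rr <- (ori[k, 1] + 1L):(ori[k, 1] + s - 1L)
      cc <- (ori[k, 2] + 1L):(ori[k, 2] + s - 1L)
      drop_nodes <- c(drop_nodes, as.vector(outer(rr, cc, idx)))
    }
    drop_nodes <- unique(drop_nodes)
    keep_e <- !(edges$u %in% drop_nodes | edges$v %in% drop_nodes)
    edges <- edges[keep_e, ]
  }
  ## cul-de-sacs: convert a fraction of edges to dead ends by deletion
  if (cfg$culdesac_frac > 0) {
    n_cut <- floor(cfg$culdesac_frac * nrow(edges))
    if (n_cut > 0) edges <- edges[-sample(nrow(edges), n_cut), ]
  }
  ## keep the largest connected component
  g <- igraph::graph_from_edgelist(cbind(edges$u, edges$v), directed = FALSE)
  if (igraph::vcount(g) < gs * gs) {
    g <- igraph::add_vertices(g, gs * gs - igraph::vcount(g))
  }
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  keep_nodes <- as.character(which(comp$membership == main))
  if (length(keep_nodes) < 0.6 * (gs * gs - length(drop_nodes))) {
    stop("fragmented")
  }
  edges <- edges[as.character(edges$u) %in% keep_nodes &
                 as.character(edges$v) %in% keep_nodes, ]
  nodes <- nodes[nodes$id %in% keep_nodes, ]
  net <- street_network(nodes, edges)

  ## parcels: one per block, inset from the street lines
  inset <- 12
  n_par <- b * b
  pr <- rep(1:b, times = b); pc <- rep(1:b, each = b)
  district <- paste0("d", 1L + (pr > b / 2) + 2L * (pc > b / 2))
  dshares <- lapply(unique(district),
                    function(d) rdirichlet1(rep(cfg$landuse_conc, 6)))
  names(dshares) <- unique(district)
  cls <- character(n_par)
  for (i in seq_len(n_par)) {
    cls[i] <- sample(use_classes(), 1, prob = dshares[[district[i]]])
  }
  floor_area <- stats::rlnorm(n_par, meanlog = log(8000), sdlog = 0.4)
  residents <- ifelse(
    cls == "residential",
    stats::rnbinom(n_par, mu = cfg$residents_mean, size = cfg$residents_disp),
    0)
  rings <- lapply(seq_len(n_par), function(i) {
    x0 <- (pc[i] - 1) * bm + inset; x1 <- pc[i] * bm - inset
    y0 <- (pr[i] - 1) * bm + inset; y1 <- pr[i] * bm - inset
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  })
  parcels <- list(
    table = data.frame(parcel_id = paste0("p", seq_len(n_par)),
                       use_class = cls, floor_area_m2 = floor_area,
                       residents = residents, district = district,
                       stringsAsFactors = FALSE),
    rings = rings)

  ## schools: well-separated street nodes
  min_sep <- 2.5 * bm
  ord <- sample(nrow(net$nodes))
  chosen <- integer()
  for (i in ord) {
    if (!length(chosen)) { chosen <- i; next }
    d <- euclidean_distance(net$nodes$x[i], net$nodes$y[i],
                            net$nodes$x[chosen], net$nodes$y[chosen])
    if (all(d >= min_sep)) chosen <- c(chosen, i)
    if (length(chosen) == cfg$n_schools) break
  }
  if (length(chosen) < cfg$n_schools) stop("fragmented")
  levels <- rep(names(cfg$school_mix), times = cfg$school_mix)
  schools <- data.frame(
    school_id = paste0("s", seq_len(cfg$n_schools)),
    x = net$nodes$x[chosen], y = net$nodes$y[chosen],
    level = levels, stringsAsFactors = FALSE)
  list(net = net, parcels = parcels, schools = schools)
}

school_serves <- function(level, age_group) {
  level == "both" | level == switch(age_group, child = "primary",
                                    adolescent = "secondary")
}

#' Generate participants with outcomes from the behaviour model
#'
#' Homes are placed around each participant's school at a log-normal
#' straight-line distance and uniform bearing. True exposures (distance, PRD,
#' buffer dummies) are computed with the pipeline's own exposure operations;
#' the active indicator is Bernoulli(logit^-1(beta x)), and the weekly trip
#' count is drawn uniformly from 4..10 if active, else 0..3, so active is
#' exactly trips >= 4. Configurable fractions of missing outcomes, bike mode
#' and corrupted home coordinates are then injected.
#'
#' @param cfg a [city_config()].
#' @param city output of [generate_city()].
#' @param model a [behaviour_model()].
#' @return list `participants` (roster data.frame), `truth` (generating
#'   coefficients, dummy medians, seed, realised active rates).
#' @export
generate_participants <- function(cfg, city, model = behaviour_model()) {
  stopifnot(inherits(cfg, "city_config"), inherits(model, "behaviour_model"))
  set.seed(as.integer(cfg$seed + 1000003L))
  groups <- c(rep("child", cfg$n_children),
              rep("adolescent", cfg$n_adolescents))
  n <- length(groups)
  sch <- city$schools
  school_id <- character(n)
  for (ag in c("child", "adolescent")) {
    sel <- groups == ag
    eligible <- sch$school_id[school_serves(sch$level, ag)]
    if (!length(eligible)) stop("generate_participants: no school serves ", ag)
    school_id[sel] <- sample(eligible, sum(sel), replace = TRUE)
  }
  si <- match(school_id, sch$school_id)
  r <- stats::rlnorm(n, cfg$home_meanlog, cfg$home_sdlog)
  theta <- stats::runif(n, 0, 2 * pi)
  home_x <- sch$x[si] + r * cos(theta)
  home_y <- sch$y[si] + r * sin(theta)
  roster <- data.frame(
    pid = sprintf("P%05d", seq_len(n)), age_group = groups,
    gender = sample(c("male", "female"), n, replace = TRUE),
    home_x = home_x, home_y = home_y, school_id = school_id,
    trips = 0L, mode = "walk", stringsAsFactors = FALSE)

  ## exposures via the pipeline's own operations
  exp_tab <- build_exposure_table(roster, sch, city$net, city$parcels,
                                  thresholds = cfg$thresholds)
  med_int <- stats::median(exp_tab$int_density)
  med_mix <- stats::median(exp_tab$mixed_use_z)
  x_int <- as.numeric(exp_tab$int_density > med_int)
  x_mix <- as.numeric(exp_tab$mixed_use_z > med_mix)
  eta <- numeric(nrow(exp_tab))
  for (ag in c("child", "adolescent")) {
    be <- model[[ag]]
    sel <- exp_tab$age_group == ag
    eta[sel] <- be["intercept"] + be["int_d"] * x_int[sel] +
      be["mix_d"] * x_mix[sel] +
      be["distance_km"] * exp_tab$distance_km[sel] +
      be["prd"] * exp_tab$prd[sel]
  }
  p_active <- stats::plogis(eta)
  active <- stats::rbinom(length(eta), 1, p_active)
  trips <- ifelse(active == 1, sample(4:10, length(eta), replace = TRUE),
                  sample(0:3, length(eta), replace = TRUE))
  m <- match(roster$pid, exp_tab$pid)
  roster$trips <- ifelse(is.na(m), stats::rbinom(n, 1, 0.5) * 7L, trips[m])
  roster$mode <- ifelse(roster$trips >= 4, "walk", "motorised")

  ## injected defects, disjoint sets
  n_def <- floor(n * c(cfg$missing_acs_frac, cfg$bike_frac,
                       cfg$bad_coord_frac))
  pool <- sample(n)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  i_miss <- take(n_def[1]); i_bike <- take(n_def[2]); i_bad <- take(n_def[3])
  roster$trips[i_miss] <- NA_integer_
  roster$mode[i_bike] <- "bike"
  roster$home_x[i_bad] <- NA_real_
  roster$home_y[i_bad] <- NA_real_

  truth <- list(
    seed = cfg$seed,
    coefficients = list(child = as.list(model$child),
                        adolescent = as.list(model$adolescent)),
    dummy_medians = list(int_density = med_int, mixed_use_z = med_mix),
    active_rate = stats::setNames(
      vapply(c("child", "adolescent"),
             function(ag) mean(active[exp_tab$age_group == ag]), numeric(1)),
      c("child", "adolescent")),
    injected = list(missing_acs = n_def[1], bike = n_def[2],
                    bad_coords = n_def[3]))
  list(participants = roster, truth = truth)
}

#' Simulate a full study: city plus participant roster
#'
#' @param cfg a [city_config()].
#' @param model a [behaviour_model()].
#' @return list `city`, `participants`, `truth`.
#' @export
simulate_study <- function(cfg, model = behaviour_model()) {
  city <- generate_city(cfg)
  gp <- generate_participants(cfg, city, model)
  list(city = city, participants = gp$participants, truth = gp$truth)
}

#' Write all simulated layers to a directory
#'
#' Emits `network.geojson`, `parcels.geojson`, `schools.csv`,
#' `participants.csv` and `truth.json` — exactly the formats the pipeline
#' reads. Output is byte-identical for identical config and seed.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_city <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_geojson(sim$city$net, file.path(dir, "network.geojson"))
  write_parcels_geojson(sim$city$parcels, file.path(dir, "parcels.geojson"))
  utils::write.csv(sim$city$schools, file.path(dir, "schools.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}
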