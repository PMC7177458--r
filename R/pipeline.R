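## End-to-end orchestration: exposure -> outcome coding -> association ->
## ROC thresholds -> cross-table, with per-stage artifacts and a single JSON
## report. Inputs come either from files (the generic GeoJSON/CSV formats)
## or from an in-memory simulated study.

#' Pipeline run configuration
#'
#' Declarative configuration with the study defaults: catchment thresholds
#' 1250 m (children) / 1350 m (adolescents), classification cutoff p = 0.50,
#' PRD bin edges combining the ROC cutoff 1.212 with the 1.5
#' direct/indirect convention, VIF drop threshold 2.0.
#'
#' @param network,parcels,schools,participants input file paths (GeoJSON /
#'   CSV); all four `NULL` means the pipeline simulates its inputs from
#'   `city_cfg`.
#' @param city_cfg a [city_config()] used when simulating.
#' @param thresholds named buffer thresholds in metres.
#' @param prd_edges interior PRD bin edges.
#' @param cutoff classification probability cutoff in (0, 1).
#' @param vif_threshold VIF drop threshold.
#' @param ci_method "wald" or "profile".
#' @param strict_prd drop (rather than flag) PRD < 1 records.
#' @param seed integer seed for any simulation randomness.
#' @param output_dir where stage artifacts are written; `NULL` disables
#'   writing.
#' @return a `run_config` list.
#' @export
run_config <- function(network = NULL, parcels = NULL, schools = NULL,
                       participants = NULL, city_cfg = city_config(),
                       thresholds = c(child = 1250, adolescent = 1350),
                       prd_edges = default_prd_edges(), cutoff = 0.5,
                       vif_threshold = 2, ci_method = "wald",
                       strict_prd = FALSE, seed = 1L, output_dir = NULL) {
  stopifnot(all(thresholds > 0), !is.unsorted(prd_edges, strictly = TRUE),
            cutoff > 0, cutoff < 1)
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulation-or-load, exclusion coding, exposure assembly, the
#' two-model logistic sequence, the four ROC threshold analyses and the PRD
#' cross-table, writing per-stage artifacts plus `report.json` when
#' `cfg$output_dir` is set. Identical seed and config give identical
#' artifacts.
#'
#' @param cfg a [run_config()].
#' @return the report list, invisibly: one element per stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  inputs <- stage("inputs", {
    if (is.null(cfg$network)) {
      ccfg <- cfg$city_cfg
      ccfg$seed <- cfg$seed
      ccfg$thresholds <- cfg$thresholds
      sim <- simulate_study(ccfg)
      if (!is.null(out)) write_city(sim, file.path(out, "city"))
      list(net = sim$city$net, parcels = sim$city$parcels,
           schools = sim$city$schools, roster = sim$participants,
           truth = sim$truth)
    } else {
      list(net = read_network_geojson(cfg$network),
           parcels = read_parcels_geojson(cfg$parcels),
           schools = utils::read.csv(cfg$schools, stringsAsFactors = FALSE),
           roster = read_participants_csv(cfg$participants),
           truth = NULL)
    }
  })

  coding <- stage("coding", apply_exclusions(inputs$roster))
  records <- stage("exposure", build_exposure_table(
    coding$retained, inputs$schools, inputs$net, inputs$parcels,
    thresholds = cfg$thresholds, strict_prd = cfg$strict_prd))
  exclusions <- rbind(coding$log, attr(records, "exclusions"))

  models <- stage("association", run_model_sequence(
    records, vif_threshold = cfg$vif_threshold, cutoff = cfg$cutoff))
  thresholds <- stage("thresholds", threshold_report(records))
  crosstab <- stage("crosstab", build_crosstab(records, cfg$prd_edges))

  report <- list(
    config = list(thresholds = as.list(cfg$thresholds),
                  prd_edges = cfg$prd_edges, cutoff = cfg$cutoff,
                  vif_threshold = cfg$vif_threshold, seed = cfg$seed,
                  strict_prd = cfg$strict_prd),
    exclusions = list(counts = as.list(table(exclusions$reason)),
                      n_input = nrow(inputs$roster),
                      n_analysed = nrow(records)),
    exposure = list(
      n = nrow(records),
      active_share_pct = 100 * mean(records$acs_binary),
      by_age = lapply(split(records, records$age_group), function(d) {
        list(n = nrow(d), active_share_pct = 100 * mean(d$acs_binary),
             median_distance_km = stats::median(d$distance_km),
             median_prd = stats::median(d$prd))
      })),
    association = list(
      dropped = models$dropped,
      model1_accuracy = models$model1$accuracy,
      model2 = lapply(models$model2, function(m) {
        list(n = m$n, accuracy = m$accuracy, coefficients = m$coefficients)
      })),
    thresholds = lapply(thresholds, function(r) {
      list(auc = r$auc, ci = r$ci, cutoff = r$cutoff, j_max = r$j_max,
           validity = r$validity)
    }),
    crosstab = list(counts = crosstab$counts, row_pct = crosstab$row_pct,
                    chi_square = crosstab$chi_square))

  if (!is.null(out)) {
    write_exposure_table(records, file.path(out, "exposure.csv"))
    write_exclusion_log(exclusions, file.path(out, "exclusions.csv"))
    write_model_report(models, file.path(out, "models.json"),
                       file.path(out, "models_table.csv"))
    write_roc_summary(thresholds, file.path(out, "roc_summary.json"),
                      points_dir = file.path(out, "roc_points"))
    write_crosstab(crosstab, file.path(out, "crosstab.csv"),
                   file.path(out, "crosstab.json"))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = 10,
                         matrix = "rowmajor")
  }
  invisible(c(report, list(
    records = records, models = models, roc = thresholds,
    crosstab_obj = crosstab, truth = inputs$truth)))
}
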