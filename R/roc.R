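## Empirical ROC analysis with Youden-index cut-points. The conventions are
## fixed and deterministic: thresholds midway between consecutive distinct
## scores, trapezoidal AUC (equal to the Mann-Whitney concordance statistic
## with half-credit for ties), Hanley-McNeil AUC variance for the 95% CI, and
## J ties broken towards the cutoff that classifies more participants active.

#' ROC curve analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC of a score against a 0/1 label over all distinct
#' score thresholds, computes the trapezoidal AUC with a Hanley-McNeil 95%
#' CI, and returns the cutoff maximising the Youden index J = sensitivity +
#' specificity - 1. A model is `valid` when AUC >= 0.5 and 0.5 lies outside
#' the CI; a valid model with AUC < 0.75 is classed `valid-exploratory`;
#' otherwise `invalid`.
#'
#' @param scores numeric scores (e.g. PRD or distance in km).
#' @param labels 0/1 outcome (1 = active).
#' @param orientation `"higher"` (higher score predicts active),
#'   `"lower"`, or `"auto"` (by comparing class means).
#' @return object of class `roc_result`: `points` (fpr, tpr, threshold, j,
#'   from (0,0) to (1,1)), `auc`, `ci`, `cutoff` (score units), `j_max`,
#'   `orientation`, `validity`, `n_pos`, `n_neg`, `degenerate`.
#' @export
roc_analysis <- function(scores, labels,
                         orientation = c("auto", "higher", "lower")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok])
  if (!all(labels %in% c(0L, 1L))) stop("roc_analysis: labels must be 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_analysis: both outcome classes must be present")
  }
  degenerate <- length(unique(scores)) == 1L
  if (orientation == "auto") {
    orientation <- if (mean(scores[labels == 1L]) >=
                       mean(scores[labels == 0L])) "higher" else "lower"
  }
  s <- if (orientation == "higher") scores else -scores
  us <- sort(unique(s))
  thr <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  sp <- s[labels == 1L]; sn <- s[labels == 0L]
  tpr <- vapply(thr, function(t) mean(sp > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sn > t), numeric(1))
  j <- tpr - fpr
  ord <- order(fpr, tpr)
  pts <- data.frame(fpr = fpr[ord], tpr = tpr[ord], threshold = thr[ord],
                    j = j[ord])
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  ## Hanley & McNeil (1982) variance of the empirical AUC
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
        (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * sqrt(max(0, v))))
  j_max <- max(j)
  ## ties -> lowest internal threshold = the more inclusive active class
  best <- min(thr[j >= j_max - 1e-12])
  cutoff <- if (orientation == "higher") best else -best
  validity <- if (degenerate || !(auc >= 0.5 && (ci[1] > 0.5 || ci[2] < 0.5))) {
    "invalid"
  } else if (auc < 0.75) "valid-exploratory" else "valid"
  structure(list(points = pts, auc = auc, ci = ci, cutoff = cutoff,
                 j_max = j_max, orientation = orientation,
                 validity = validity, n_pos = n_pos, n_neg = n_neg,
                 degenerate = degenerate), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "roc_result: AUC = %.3f (95%% CI %.3f-%.3f), J_max = %.3f at %s %.4g (%s)\n",
    x$auc, x$ci[1], x$ci[2], x$j_max,
    if (x$orientation == "higher") "score >" else "score <", x$cutoff,
    x$validity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, main = "ROC", ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity", main = main, ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Route-measure threshold report
#'
#' The four ROC/Youden analyses of the study protocol: PRD for all
#' participants and separately for children and adolescents (active above
#' the cutoff), and home-school distance for all participants (active below
#' the cutoff). Each carries its validity class.
#'
#' @param records exposure table with `prd`, `distance_km`, `acs_binary`,
#'   `age_group`.
#' @return named list of `roc_result`: `prd_all`, `prd_children`,
#'   `prd_adolescents`, `distance_all`.
#' @export
threshold_report <- function(records) {
  stratum <- function(sel, scores, orientation) {
    if (!sum(sel)) stop("threshold_report: empty stratum")
    roc_analysis(scores[sel], records$acs_binary[sel],
                 orientation = orientation)
  }
  list(
    prd_all = stratum(rep(TRUE, nrow(records)), records$prd, "higher"),
    prd_children = stratum(records$age_group == "child", records$prd,
                           "higher"),
    prd_adolescents = stratum(records$age_group == "adolescent",
                              records$prd, "higher"),
    distance_all = stratum(rep(TRUE, nrow(records)), records$distance_km,
                           "lower"))
}

#' Write ROC results: JSON summary plus per-analysis curve-point CSVs
#'
#' @param report list from [threshold_report()].
#' @param json_path summary JSON file.
#' @param points_dir optional directory for per-analysis curve CSVs.
#' @export
write_roc_summary <- function(report, json_path, points_dir = NULL) {
  jsonlite::write_json(lapply(report, function(r) {
    list(auc = r$auc, ci = r$ci, cutoff = r$cutoff, j_max = r$j_max,
         orientation = r$orientation, validity = r$validity,
         n_pos = r$n_pos, n_neg = r$n_neg)
  }), json_path, auto_unbox = TRUE, digits = 10)
  if (!is.null(points_dir)) {
    dir.create(points_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(report)) {
      utils::write.csv(report[[nm]]$points,
                       file.path(points_dir, paste0("roc_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(json_path)
}
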