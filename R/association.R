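## Binary logistic regression protocol: a pooled model with age-group
## adjustment and a confounding check, collinearity diagnostics, and
## age-stratified refits. Model fitting is delegated to stats::glm (IRLS);
## this layer owns the Wald/OR reporting conventions, the classification
## accuracy at a probability cutoff, and the diagnostic rules.

#' Fit a binary logistic regression with Wald/OR reporting
#'
#' Maximum-likelihood logit fit entering all predictors in a single step
#' ("Intro" style: no stepwise selection). Reports per-predictor log-odds
#' coefficients B, SE, Wald p, OR = exp(B) with 95 percent Wald CI
#' exp(B +- 1.96 SE), and the fraction of cases correctly classified at the
#' stated probability cutoff.
#'
#' @param data data.frame holding predictors and outcome.
#' @param predictors character vector of predictor column names.
#' @param outcome name of the 0/1 outcome column.
#' @param cutoff classification probability cutoff, default 0.50.
#' @param ci one of "wald" (default) or "profile" (profile-likelihood CI).
#' @return object of class `blr_fit`: `coefficients` data.frame (`term`,
#'   `B`, `SE`, `p`, `OR`, `ci_lo`, `ci_hi`), `accuracy`, `n`, `converged`,
#'   `loglik`, and the underlying `glm` fit.
#' @export
fit_blr <- function(data, predictors, outcome, cutoff = 0.5,
                    ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  stopifnot(cutoff > 0, cutoff < 1)
  y <- data[[outcome]]
  if (length(unique(y)) < 2L) {
    stop("fit_blr: outcome has a single class")
  }
  for (v in predictors) {
    if (length(unique(data[[v]])) < 2L) {
      stop("fit_blr: constant predictor: ", v)
    }
  }
  form <- stats::reformulate(if (length(predictors)) predictors else "1",
                             response = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  ## |log-odds| beyond ~15 (OR > 3e6) only arises when a predictor separates
  ## the classes; the IRLS estimate then diverges with the iteration budget
  if (sep_warn || any(abs(cf[, "Estimate"]) > 15)) {
    worst <- rownames(cf)[which.max(abs(cf[, "Estimate"]))]
    stop("fit_blr: (quasi-)perfect separation; offending predictor: ", worst)
  }
  if (!fit$converged) {
    stop("fit_blr: IRLS did not converge in ", fit$iter, " iterations")
  }
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  if (ci == "profile") {
    ci_mat <- suppressMessages(stats::confint(fit))
    if (is.null(dim(ci_mat))) ci_mat <- matrix(ci_mat, nrow = 1)
    lo <- exp(ci_mat[, 1]); hi <- exp(ci_mat[, 2])
  } else {
    lo <- exp(est - 1.96 * se); hi <- exp(est + 1.96 * se)
  }
  pred <- as.integer(stats::fitted(fit) > cutoff)
  structure(list(
    coefficients = data.frame(
      term = rownames(cf), B = est, SE = se, p = cf[, "Pr(>|z|)"],
      OR = exp(est), ci_lo = lo, ci_hi = hi,
      row.names = NULL, stringsAsFactors = FALSE),
    accuracy = mean(pred == y), n = length(y),
    converged = fit$converged, loglik = as.numeric(stats::logLik(fit)),
    cutoff = cutoff, fit = fit), class = "blr_fit")
}

#' @export
print.blr_fit <- function(x, ...) {
  cat(sprintf("blr_fit: n = %d, accuracy at p = %.2f: %.1f%%\n",
              x$n, x$cutoff, 100 * x$accuracy))
  print(transform(x$coefficients, OR = round(OR, 3), B = round(B, 3),
                  SE = round(SE, 3), p = signif(p, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3)))
  invisible(x)
}

#' Confounding check: OR change between crude and adjusted models
#'
#' Percent change of each predictor's OR when the adjustment variable enters
#' the model: `100 |OR_adj - OR_crude| / OR_crude`. Changes of 10 percent or
#' more flag the adjustment variable as a confounder worth keeping.
#'
#' @param crude,adjusted `blr_fit` objects on the same predictors apart from
#'   the adjustment term.
#' @param flag_at flag threshold in percent, default 10.
#' @return data.frame `term`, `OR_crude`, `OR_adj`, `change_pct`, `flagged`.
#' @export
confounding_check <- function(crude, adjusted, flag_at = 10) {
  ct <- crude$coefficients
  at <- adjusted$coefficients
  shared <- setdiff(intersect(ct$term, at$term), "(Intercept)")
  if (!length(shared)) stop("confounding_check: no shared predictors")
  extra <- setdiff(at$term, ct$term)
  if (!length(extra)) {
    message("confounding_check: models share all terms (no adjustment term)")
  }
  orc <- ct$OR[match(shared, ct$term)]
  ora <- at$OR[match(shared, at$term)]
  change <- 100 * abs(ora - orc) / orc
  data.frame(term = shared, OR_crude = orc, OR_adj = ora,
             change_pct = change, flagged = change >= flag_at,
             stringsAsFactors = FALSE)
}

#' Multicollinearity diagnostics for a predictor set
#'
#' Pearson correlation matrix, per-predictor VIF (1 / (1 - R2_j) from
#' regressing predictor j on the others), condition indices of the scaled,
#' intercept-included cross-product matrix, and (when an outcome is given)
#' the logistic-fit coefficient SEs. Conventional screens: pairwise |r| <
#' 0.80 and SE < 2.0 are acceptable; VIF near 1 is ideal; condition index
#' < 20 raises no concern.
#'
#' @param data data.frame of predictors.
#' @param predictors character vector of (numeric) predictor columns, >= 2.
#' @param outcome optional 0/1 outcome column name; adds logistic SEs.
#' @return object of class `collinearity_report`: `cor_matrix`, `max_abs_r`,
#'   `vif` (named), `condition_index` (named by eigen rank), optional `se`.
#' @export
collinearity_diagnostics <- function(data, predictors, outcome = NULL) {
  if (length(predictors) < 2L) {
    stop("collinearity_diagnostics: need >= 2 predictors")
  }
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("collinearity_diagnostics: constant predictor")
  }
  cm <- stats::cor(X)
  vif <- vapply(seq_along(predictors), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-12) {
      stop("collinearity_diagnostics: perfect collinearity involving ",
           predictors[j])
    }
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- predictors
  ## SPSS-style condition indices: scale design columns (incl. intercept) to
  ## unit length, eigen-decompose X'X.
  Xi <- cbind(`(Intercept)` = 1, X)
  Xs <- sweep(Xi, 2, sqrt(colSums(Xi^2)), "/")
  ev <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, .Machine$double.eps)
  cond <- sqrt(max(ev) / ev)
  se <- NULL
  if (!is.null(outcome)) {
    se <- stats::setNames(
      fit_blr(data, predictors, outcome)$coefficients$SE[-1], predictors)
  }
  structure(list(cor_matrix = cm,
                 max_abs_r = max(abs(cm[upper.tri(cm)])),
                 vif = vif, condition_index = cond, se = se),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("collinearity_report: max |r| =", round(x$max_abs_r, 3), "\n")
  cat("VIF:", paste(names(x$vif), round(x$vif, 3), sep = "=",
                    collapse = ", "), "\n")
  cat("condition indices:", paste(round(x$condition_index, 2),
                                  collapse = ", "), "\n")
  invisible(x)
}

## Analysis frame: dummy-code the three school-level measures at the
## participant-level median, keep the route measures numeric, add the
## age-group indicator (adolescent = 1).
association_frame <- function(records) {
  data.frame(
    acs = records$acs_binary,
    res_d = median_dummy(records$res_density),
    int_d = median_dummy(records$int_density),
    mix_d = median_dummy(records$mixed_use_z),
    distance_km = records$distance_km,
    prd = records$prd,
    age_adolescent = as.integer(records$age_group == "adolescent"),
    age_group = records$age_group,
    stringsAsFactors = FALSE)
}

#' Run the two-model logistic analysis sequence
#'
#' Step 1: pooled model (model 1) with the five predictors (three median
#' dummies + distance + PRD) plus the age-group adjustment; its crude
#' counterpart without the age term feeds the confounding check. Step 2:
#' collinearity diagnostics on the five predictors. Step 3: predictors that
#' are both non-significant in model 1 (p > `p_drop`) and collinearity-
#' flagged (VIF > `vif_threshold`) are dropped; model 2 is refit separately
#' for children and adolescents on the remaining predictors.
#'
#' @param records exposure table (see [build_exposure_table()]).
#' @param vif_threshold VIF drop threshold, default 2.0.
#' @param p_drop significance drop threshold, default 0.05.
#' @param cutoff classification probability cutoff, default 0.50.
#' @param min_events minimum events per stratum, default 10.
#' @return list: `model1`, `model1_crude`, `confounding`, `collinearity`,
#'   `dropped` (character), `model2` (named list `child`, `adolescent`),
#'   `predictors_model2`.
#' @export
run_model_sequence <- function(records, vif_threshold = 2, p_drop = 0.05,
                               cutoff = 0.5, min_events = 10) {
  af <- association_frame(records)
  preds <- c("res_d", "int_d", "mix_d", "distance_km", "prd")
  if (length(unique(af$age_group)) < 2L) {
    stop("run_model_sequence: need both age groups for the pooled model")
  }
  m1 <- fit_blr(af, c(preds, "age_adolescent"), "acs", cutoff = cutoff)
  m1_crude <- fit_blr(af, preds, "acs", cutoff = cutoff)
  conf <- confounding_check(m1_crude, m1)
  coll <- collinearity_diagnostics(af, preds, outcome = "acs")
  p1 <- stats::setNames(m1$coefficients$p, m1$coefficients$term)[preds]
  dropped <- preds[p1 > p_drop & coll$vif[preds] > vif_threshold]
  keep <- setdiff(preds, dropped)
  m2 <- lapply(c(child = "child", adolescent = "adolescent"), function(ag) {
    sub <- af[af$age_group == ag, , drop = FALSE]
    if (nrow(sub) == 0L || sum(sub$acs) < min_events ||
        sum(1 - sub$acs) < min_events) {
      stop("run_model_sequence: stratum '", ag, "' has fewer than ",
           min_events, " events per class")
    }
    fit_blr(sub, keep, "acs", cutoff = cutoff)
  })
  list(model1 = m1, model1_crude = m1_crude, confounding = conf,
       collinearity = coll, dropped = dropped, model2 = m2,
       predictors_model2 = keep)
}

#' Write model results as JSON plus a flat CSV table
#'
#' The CSV mirrors the customary per-age-group layout (B, SE, p, OR, CI per
#' predictor); the JSON carries the full per-model detail.
#'
#' @param seq result of [run_model_sequence()].
#' @param json_path,csv_path output files.
#' @export
write_model_report <- function(seq, json_path, csv_path) {
  as_list <- function(m) {
    list(n = m$n, accuracy = m$accuracy, loglik = m$loglik,
         converged = m$converged, coefficients = m$coefficients)
  }
  jsonlite::write_json(list(
    model1 = as_list(seq$model1),
    model1_crude = as_list(seq$model1_crude),
    confounding = seq$confounding,
    collinearity = list(max_abs_r = seq$collinearity$max_abs_r,
                        vif = as.list(seq$collinearity$vif),
                        condition_index = seq$collinearity$condition_index),
    dropped = seq$dropped,
    model2 = lapply(seq$model2, as_list)
  ), json_path, auto_unbox = TRUE, digits = 10)
  flat <- do.call(rbind, lapply(names(seq$model2), function(ag) {
    cf <- seq$model2[[ag]]$coefficients
    cf <- cf[cf$term != "(Intercept)", ]
    data.frame(age_group = ag, term = cf$term, B = cf$B, SE = cf$SE,
               p = cf$p, OR = cf$OR,
               ci95 = sprintf("%.3f-%.3f", cf$ci_lo, cf$ci_hi),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(flat, csv_path, row.names = FALSE)
  invisible(json_path)
}
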