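## Cross-tabulation of commuting status by PRD ranges, with row percentages
## and Pearson's chi-square. Default bin edges combine the ROC-derived PRD
## cutoff (1.212) with the conventional direct/indirect boundary (1.5).

default_prd_edges <- function() c(1.212, 1.30, 1.40, 1.50)

prd_bin_labels <- function(edges) {
  k <- length(edges)
  c(sprintf("[Min-%.3g]", edges[1]),
    sprintf("(%.3g-%.3g]", edges[-k], edges[-1]),
    sprintf("(%.3g-Max]", edges[k]))
}

## (a, b] bin assignment with the first bin closed at the minimum.
assign_prd_bin <- function(prd, edges) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("PRD bin edges must be strictly increasing")
  }
  rowSums(outer(prd, edges, ">")) + 1L
}

new_crosstab <- function(counts, edges) {
  row_tot <- rowSums(counts)
  ## the independence test needs positive margins; degenerate tables keep
  ## their counts but carry an NA test
  chi <- if (any(row_tot == 0) || any(colSums(counts) == 0)) {
    list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
  } else {
    chi_square(counts)
  }
  structure(list(counts = counts, edges = edges,
                 labels = colnames(counts), row_totals = row_tot,
                 row_pct = sweep(counts, 1, row_tot, "/") * 100,
                 chi_square = chi), class = "acs_crosstab")
}

#' Cross-tabulate ACS status by PRD ranges
#'
#' Bins PRD into left-open right-closed intervals at the given edges (the
#' first bin is closed at the minimum), counts active and non-active
#' participants per bin, and tests independence with Pearson's chi-square.
#' Row percentages are kept at full precision internally; rounding to one
#' decimal happens only in the print/write layer.
#'
#' @param records exposure table with `prd` and `acs_binary`.
#' @param edges strictly increasing interior bin edges; default
#'   `c(1.212, 1.30, 1.40, 1.50)`.
#' @return object of class `acs_crosstab`: `counts` (status x bin), `row_pct`,
#'   `row_totals`, `edges`, `labels`, `chi_square` (statistic, df, p).
#' @export
build_crosstab <- function(records, edges = default_prd_edges()) {
  if (nrow(records) == 0L) stop("build_crosstab: empty records")
  ok <- !is.na(records$prd) & !is.na(records$acs_binary)
  bin <- assign_prd_bin(records$prd[ok], edges)
  status <- factor(ifelse(records$acs_binary[ok] == 1, "active",
                          "non_active"), levels = c("active", "non_active"))
  counts <- table(status, factor(bin, levels = seq_len(length(edges) + 1L)))
  counts <- matrix(as.integer(counts), nrow = 2,
                   dimnames = list(c("active", "non_active"),
                                   prd_bin_labels(edges)))
  new_crosstab(counts, edges)
}

#' Build a cross-table object from printed counts
#'
#' Reporting-layer constructor: takes an already-tabulated status x bin count
#' matrix (e.g. a published cross-table) and computes row totals, row
#' percentages and the chi-square test from it.
#'
#' @param counts integer matrix, rows = status, columns = bins.
#' @param edges optional bin edges (metadata only).
#' @return an `acs_crosstab`.
#' @export
crosstab_from_counts <- function(counts, edges = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) && !is.null(edges)) {
    colnames(counts) <- prd_bin_labels(edges)
  }
  new_crosstab(counts, edges)
}

#' Share of a cross-table row falling in selected bins
#'
#' Row percentage aggregated over one or more bins, e.g. the share of active
#' participants with PRD above 1.5.
#'
#' @param ct an `acs_crosstab`.
#' @param row row name or index.
#' @param bins column names or indices to aggregate.
#' @return percentage in \[0, 100\] (full precision).
#' @export
bin_share <- function(ct, row, bins) {
  stopifnot(inherits(ct, "acs_crosstab"))
  100 * sum(ct$counts[row, bins]) / ct$row_totals[[row]]
}

#' Pearson's chi-square test of independence on a count table
#'
#' Classic Pearson statistic with margin-based expected counts and no
#' continuity correction; p-value from the chi-square distribution with
#' (rows - 1)(cols - 1) degrees of freedom.
#'
#' @param counts count matrix.
#' @return list `statistic`, `df`, `p`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi_square: zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' @export
print.acs_crosstab <- function(x, ...) {
  shown <- matrix(sprintf("%d (%.1f%%)", x$counts, x$row_pct),
                  nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(shown, quote = FALSE)
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.3g\n",
              x$chi_square$statistic, x$chi_square$df, x$chi_square$p))
  invisible(x)
}

#' Write a cross-table: CSV layout plus JSON with raw counts and the test
#'
#' The CSV shows counts with one-decimal row percentages; the JSON carries
#' full-precision counts, percentages and the chi-square triple.
#'
#' @param ct an `acs_crosstab`.
#' @param csv_path,json_path output files.
#' @export
write_crosstab <- function(ct, csv_path, json_path) {
  df <- data.frame(status = rownames(ct$counts),
                   total = ct$row_totals,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ct$counts))) {
    df[[ct$labels[j]]] <- sprintf("%d (%.1f%%)", ct$counts[, j],
                                  ct$row_pct[, j])
  }
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(list(counts = ct$counts, row_pct = ct$row_pct,
                            edges = ct$edges, chi_square = ct$chi_square),
                       json_path, auto_unbox = TRUE, digits = 10,
                       matrix = "rowmajor")
  invisible(csv_path)
}
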