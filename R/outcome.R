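## Outcome coding: dichotomisation of the weekly active-trip count, the
## participant exclusion funnel, and median dummy-coding of school-level
## predictors.

#' Dichotomise weekly active commuting counts
#'
#' Participants reporting 4-10 active trips per week are coded active (1);
#' 0-3 non-active (0). The boundary is inclusive: exactly the set 4..10 maps
#' to 1.
#'
#' @param trips integer vector in 0..10 (no missing values; exclude upstream).
#' @return integer 0/1 vector.
#' @export
dichotomize_acs <- function(trips) {
  if (anyNA(trips)) stop("dichotomize_acs: missing trip counts; exclude first")
  if (any(trips < 0 | trips > 10)) {
    stop("dichotomize_acs: trips must be in 0..10")
  }
  as.integer(trips >= 4)
}

#' Apply the participant exclusion rules
#'
#' Removes, with one logged reason per participant: (i) missing weekly trip
#' count (`missing_acs`), (ii) reported bike commuting (`bike`; cyclists are
#' excluded, not recoded to active), (iii) missing or non-finite home
#' coordinates (`ungeocodable`). Unroutable homes are excluded later by the
#' exposure stage, which is the first point where routability is known.
#' Idempotent: retained + excluded = input count.
#'
#' @param participants raw roster (see [read_participants_csv()]).
#' @return list with `retained` (data.frame) and `log` (data.frame
#'   `pid`, `reason`) plus a `counts` summary (named integer vector).
#' @export
apply_exclusions <- function(participants) {
  p <- participants
  reason <- rep(NA_character_, nrow(p))
  reason[is.na(p$trips)] <- "missing_acs"
  bike <- is.na(reason) & !is.na(p$mode) & p$mode == "bike"
  reason[bike] <- "bike"
  badxy <- is.na(reason) & (!is.finite(p$home_x) | !is.finite(p$home_y))
  reason[badxy] <- "ungeocodable"
  keep <- is.na(reason)
  log <- data.frame(pid = p$pid[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  counts <- c(retained = sum(keep),
              missing_acs = sum(log$reason == "missing_acs"),
              bike = sum(log$reason == "bike"),
              ungeocodable = sum(log$reason == "ungeocodable"))
  list(retained = p[keep, , drop = FALSE], log = log, counts = counts)
}

#' Median dummy-coding of a school-level measure
#'
#' Recodes a continuous school-built-environment measure to 0/1 at the median
#' of the participant-level column (each participant carries their school's
#' value), matching the regression's unit of analysis. Values strictly above
#' the median code to 1; values at the median code to 0.
#'
#' @param values numeric vector (one value per participant).
#' @return integer 0/1 vector.
#' @export
median_dummy <- function(values) {
  if (!length(values)) stop("median_dummy: empty input")
  as.integer(values > stats::median(values))
}
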