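#' Phase labels of the remote monitoring calendar
#' @return Character vector of the three phases in order.
#' @export
monitoring_phases <- function() c("baseline", "monitoring1", "monitoring2")

#' Summarize one participant-phase of daily drinking records
#'
#' Aggregates daily reports into the trial's phase-level outcomes.
#' Drinks/day divides total drinks by the *total calendar days* in the
#' phase (missing reports count in the denominator but contribute no
#' drinks), matching the trial's figure convention; because that
#' denominator absorbs missingness, the missingness-robust variant
#' `drinks_per_reported_day` (total drinks over days with a report) is
#' also returned, and the two are never mixed. Drinks/drinking day
#' divides total drinks by the number of days with at least one reported
#' drink and is `NA` (undefined, not zero) when there are no drinking
#' days.
#'
#' @param records Data frame for a single participant and phase with
#'   columns `participant`, `phase` and `reported_drinks` (`NA` = missing
#'   report).
#' @return A one-row data frame: `participant`, `phase`, `total_days`,
#'   `reported_days`, `drinking_days`, `total_drinks`, `drinks_per_day`,
#'   `drinks_per_reported_day`, `drinks_per_drinking_day`.
#' @examples
#' summarize_phase(data.frame(participant = "p1", phase = "baseline",
#'                            reported_drinks = c(4, 0, 5, 6, 0, 4, 4)))
#' @export
summarize_phase <- function(records) {
  if (nrow(records) == 0L) stop("no records supplied")
  if (length(unique(records$phase)) != 1L)
    stop("records must come from a single phase")
  if (length(unique(records$participant)) != 1L)
    stop("records must come from a single participant")
  d <- records$reported_drinks
  if (any(d < 0, na.rm = TRUE)) stop("reported drinks must be non-negative")
  total_days <- nrow(records)
  reported_days <- sum(!is.na(d))
  drinking_days <- sum(d >= 1, na.rm = TRUE)
  total_drinks <- sum(d, na.rm = TRUE)
  data.frame(
    participant = records$participant[1L],
    phase = records$phase[1L],
    total_days = total_days,
    reported_days = reported_days,
    drinking_days = drinking_days,
    total_drinks = total_drinks,
    drinks_per_day = total_drinks / total_days,
    drinks_per_reported_day =
      if (reported_days >= 1L) total_drinks / reported_days else NA_real_,
    drinks_per_drinking_day =
      if (drinking_days >= 1L) total_drinks / drinking_days else NA_real_)
}

#' Phase summaries for a whole daily table
#'
#' Applies [summarize_phase()] to every participant-phase in a daily
#' records table.
#'
#' @param daily Daily records with columns `participant`, `phase`,
#'   `reported_drinks`.
#' @return A data frame with one row per participant-phase.
#' @export
summarize_phases <- function(daily) {
  pieces <- split(daily,
                  list(daily$participant, daily$phase), drop = TRUE)
  out <- do.call(rbind, lapply(pieces, summarize_phase))
  out <- out[order(out$participant, match(out$phase, monitoring_phases())), ]
  rownames(out) <- NULL
  out
}

#' Baseline eligibility from the 7-day monitoring phase
#'
#' Applies the enrollment rules to the seven-day baseline window: the
#' participant must have reported drinks on at least 5 of the 7 days, have
#' at least 4 drinking days, and meet the harmful-drinking clause — at
#' least 4 days of 4+ drinks, and/or an average of more than 4
#' drinks/drinking day.
#'
#' @param drinks Length-7 vector of daily drink counts (`NA` = missing
#'   report).
#' @return A list with `eligible` (logical) and `reasons` (character
#'   vector naming every failed clause; empty when eligible).
#' @examples
#' baseline_eligibility(c(5, 5, 5, 5, 0, 0, 0))
#' @export
baseline_eligibility <- function(drinks) {
  if (length(drinks) != 7L)
    stop("baseline eligibility requires exactly 7 days of records")
  if (any(drinks < 0, na.rm = TRUE)) stop("drink counts must be non-negative")
  reported_days <- sum(!is.na(drinks))
  drinking_days <- sum(drinks >= 1, na.rm = TRUE)
  heavy_days <- sum(drinks >= 4, na.rm = TRUE)
  dpdd <- if (drinking_days >= 1L)
    sum(drinks, na.rm = TRUE) / drinking_days else 0
  reasons <- character(0)
  if (reported_days < 5L)
    reasons <- c(reasons, "fewer than 5 of 7 days reported")
  if (drinking_days < 4L)
    reasons <- c(reasons, "fewer than 4 drinking days")
  if (heavy_days < 4L && dpdd <= 4)
    reasons <- c(reasons,
                 "neither 4+ days of 4+ drinks nor >4 drinks/drinking day")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Analysis-ready long-format daily table
#'
#' One row per participant-day with the daily outcome, phase, group and
#' participant covariates, suitable for external mixed-model fitting.
#' Missing reports stay missing (`NA`); rows are never dropped.
#'
#' @param daily Daily records (`participant`, `day_index`, `phase`,
#'   `reported_drinks`).
#' @param profiles Participant table with `id`, `group` and covariate
#'   columns (`age`, `sex`, `ethnicity`, `race`, `education`, `income`,
#'   `audit_score` where present).
#' @return A data frame with one row per participant-day.
#' @export
long_format_export <- function(daily, profiles) {
  if (anyDuplicated(daily[c("participant", "day_index")]))
    stop("duplicate participant-day rows in the daily table")
  covs <- intersect(c("group", "age", "sex", "ethnicity", "race",
                      "education", "income", "audit_score"),
                    names(profiles))
  m <- match(daily$participant, profiles$id)
  if (anyNA(m)) stop("daily records reference unknown participants")
  out <- data.frame(participant = daily$participant,
                    day_index = daily$day_index,
                    phase = daily$phase,
                    drinks = daily$reported_drinks)
  for (v in covs) out[[v]] <- profiles[[v]][m]
  out[order(out$participant, out$day_index), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
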