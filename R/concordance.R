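#' Classify one monitored day from breath samples and the drink report
#'
#' The day's breath status is `positive` when the peak (highest) breath
#' alcohol concentration reaches the threshold (default 0.02% BrAC),
#' `negative` below it, and `missing` when no samples were submitted. The
#' report status is `none` for a reported zero, `one_or_more` for a
#' positive count, and `missing` for no report.
#'
#' @param samples Numeric vector of BrAC readings (%) for the day;
#'   `length 0` means no submissions.
#' @param reported Reported drink count for the day, or `NA` if missing.
#' @param threshold Positive-sample threshold in % BrAC.
#' @return A list with `breath_status`, `report_status`, `peak_brac`.
#' @examples
#' classify_day(c(0.00, 0.02), reported = 3)
#' @export
classify_day <- function(samples, reported, threshold = 0.02) {
  samples <- samples[!is.na(samples)]
  if (any(samples < 0)) stop("BrAC values must be non-negative")
  peak <- if (length(samples)) max(samples) else NA_real_
  breath <- if (is.na(peak)) "missing"
            else if (peak >= threshold) "positive" else "negative"
  report <- if (is.na(reported)) "missing"
            else if (reported == 0) "none" else "one_or_more"
  list(breath_status = breath, report_status = report, peak_brac = peak)
}

#' Breath-by-self-report concordance matrix
#'
#' Cross-tabulates every monitored participant-day's breath status
#' (Negative / Positive / Missing) against its self-report status
#' (None / One or more / Missing). The grand total equals the number of
#' classified days.
#'
#' @param daily Daily records with `reported_drinks` and BrAC sample
#'   columns `brac_1`, `brac_2`, `brac_3` (any subset; `NA` = not
#'   submitted).
#' @param threshold Positive-sample threshold in % BrAC.
#' @return A 3x3 integer matrix with dimnames
#'   `Negative/Positive/Missing` x `None/One or more/Missing`.
#' @export
concordance_matrix <- function(daily, threshold = 0.02) {
  brac_cols <- grep("^brac_", names(daily), value = TRUE)
  breath <- character(nrow(daily))
  report <- character(nrow(daily))
  peaks <- numeric(nrow(daily))
  for (i in seq_len(nrow(daily))) {
    cl <- classify_day(as.numeric(daily[i, brac_cols]),
                       daily$reported_drinks[i], threshold)
    breath[i] <- cl$breath_status
    report[i] <- cl$report_status
    peaks[i] <- cl$peak_brac
  }
  breath <- factor(breath, levels = c("negative", "positive", "missing"),
                   labels = c("Negative", "Positive", "Missing"))
  report <- factor(report, levels = c("none", "one_or_more", "missing"),
                   labels = c("None", "One or more", "Missing"))
  m <- table(breath, report)
  out <- matrix(as.integer(m), 3, 3,
                dimnames = list(`Breath` = rownames(m),
                                `Self-report` = colnames(m)))
  attr(out, "peaks") <- peaks
  out
}

#' Extract the non-missing 2x2 from a concordance matrix
#'
#' Drops the Missing row and column, leaving the paired
#' breath-status-by-report-status table used for the exact test.
#'
#' @param m A 3x3 matrix from [concordance_matrix()].
#' @return A 2x2 integer matrix.
#' @export
concordance_2x2 <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  m[1:2, 1:2]
}

#' Fisher exact test on a 2x2 concordance table
#'
#' Conditional maximum-likelihood odds ratio under the noncentral
#' hypergeometric model and the two-sided exact p-value summing the
#' probabilities of tables as or less probable than the observed one at
#' OR = 1 (via [stats::fisher.test()]). A table with a zero margin has no
#' defined odds ratio and raises a degenerate-table error.
#'
#' @param counts A 2x2 matrix of non-negative integer counts.
#' @return A list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_or(matrix(c(184, 519, 18, 844), 2, byrow = TRUE))
#' @export
fisher_exact_or <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop(errorCondition(
      "degenerate table: a zero margin leaves the odds ratio undefined",
      class = c("eftrial_degenerate_table", "error", "condition")))
  ft <- stats::fisher.test(counts)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Rank-based ROC area under the curve
#'
#' Discrimination of peak daily BrAC for drinking days:
#' `AUC = P(peak on a drinking day > peak on a non-drinking day)
#' + 0.5 * P(tie)`, computed from the Mann-Whitney rank statistic (exactly
#' equivalent to counting ordered pairs).
#'
#' @param peaks Numeric scores (peak BrAC per day).
#' @param labels Binary indicators (1 = drinking day), aligned to `peaks`.
#' @return The AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.00, 0.00, 0.08, 0.09), c(0, 0, 1, 1))
#' @export
roc_auc <- function(peaks, labels) {
  keep <- !is.na(peaks) & !is.na(labels)
  peaks <- peaks[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop(errorCondition(
      "AUC undefined: both drinking and non-drinking days are required",
      class = c("eftrial_undefined_value", "error", "condition")))
  r <- rank(peaks)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance statistics for a daily table
#'
#' Builds the 3x3 matrix, runs the exact test on its non-missing 2x2
#' (association between a positive breath sample and reporting at least
#' one drink), and computes the AUC of peak BrAC for predicting a
#' drinking day over days with both measurements.
#'
#' @inheritParams concordance_matrix
#' @return A list with `matrix`, `odds_ratio`, `p_value`, `auc`,
#'   `threshold`.
#' @export
concordance_stats <- function(daily, threshold = 0.02) {
  m <- concordance_matrix(daily, threshold)
  peaks <- attr(m, "peaks")
  # exact test orientation: positive breath vs one-or-more report
  t22 <- concordance_2x2(m)[2:1, 2:1]
  ft <- fisher_exact_or(t22)
  ok <- !is.na(peaks) & !is.na(daily$reported_drinks)
  auc <- roc_auc(peaks[ok], as.integer(daily$reported_drinks[ok] >= 1))
  list(matrix = m, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       auc = auc, threshold = threshold)
}
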