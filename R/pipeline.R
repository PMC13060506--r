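#' Reconstruct an indifference curve from recorded titration trials
#'
#' Replays the adjusting-amount update rule over recorded trial rows
#' (`delay_days`, `trial_index`, `ss_amount`, `choice`) for one session
#' and returns the implied indifference curve. The recorded `ss_amount`
#' is checked against the replay at every trial.
#'
#' @param trials Trial rows for one participant-session.
#' @param schedule The [titration_schedule()] in force.
#' @return An [indifference_curve()].
#' @export
curve_from_trials <- function(trials, schedule = titration_schedule()) {
  A <- schedule$A
  delays <- sort(unique(trials$delay_days))
  ip <- vapply(delays, function(d) {
    tr <- trials[trials$delay_days == d, , drop = FALSE]
    tr <- tr[order(tr$trial_index), , drop = FALSE]
    if (nrow(tr) != schedule$trials_per_delay)
      stop(sprintf("delay %g has %d trials, expected %d", d, nrow(tr),
                   schedule$trials_per_delay))
    ss <- A / 2
    for (t in seq_len(nrow(tr))) {
      if (abs(tr$ss_amount[t] - ss) > 1e-6)
        stop(sprintf(
          "recorded SS amount %.4f at delay %g trial %d; replay expected %.4f",
          tr$ss_amount[t], d, t, ss))
      step <- A / 2^(t + 1)
      ss <- ss + if (tr$choice[t] == "SS") -step else step
    }
    ss
  }, numeric(1))
  indifference_curve(delays, ip)
}

#' Discounting results table
#'
#' Fits the hyperbolic model to every participant-session in a long-format
#' choice table and returns one row per session with the rate estimate and
#' screening flags.
#'
#' @param choices Choice records (`participant`, `session`, `delay_days`,
#'   `trial_index`, `ss_amount`, `choice`).
#' @param schedule The [titration_schedule()] in force.
#' @return Data frame: `participant`, `session`, `k`, `ln_k`, `sse`,
#'   `criterion1_ok`, `criterion2_ok`, `boundary_flag`.
#' @export
discounting_table <- function(choices, schedule = titration_schedule()) {
  pieces <- split(choices, list(choices$participant, choices$session),
                  drop = TRUE)
  rows <- lapply(pieces, function(tr) {
    fit <- fit_hyperbolic(curve_from_trials(tr, schedule), schedule)
    data.frame(participant = tr$participant[1L], session = tr$session[1L],
               k = fit$k, ln_k = fit$ln_k, sse = fit$sse,
               criterion1_ok = fit$systematic$criterion1_ok,
               criterion2_ok = fit$systematic$criterion2_ok,
               boundary_flag = fit$boundary_flag)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant, out$session), ]
  rownames(out) <- NULL
  out
}

#' Demand results table
#'
#' Caps responses, derives the dataset-wide span via [shared_k_span()],
#' fits the exponentiated demand equation to every participant-session,
#' and appends the fitted unit-elasticity price.
#'
#' @param purchase Purchase records (`participant`, `session`, `price`,
#'   `quantity`).
#' @param cap Overconsumption cap.
#' @param k_span Span constant; derived from the pooled capped data when
#'   `NULL`.
#' @return Data frame: `participant`, `session`, `intensity_obs`,
#'   `omax_obs`, `pmax_obs`, `Q0`, `alpha`, `ln_alpha`, `k_span`,
#'   `converged`, `fitted_pmax`.
#' @export
demand_table <- function(purchase, cap = 50, k_span = NULL) {
  capped_all <- cap_overconsumption(purchase$quantity, cap)$quantity
  if (is.null(k_span)) k_span <- shared_k_span(capped_all)
  pieces <- split(purchase, list(purchase$participant, purchase$session),
                  drop = TRUE)
  rows <- lapply(pieces, function(pp) {
    pp <- pp[order(pp$price), , drop = FALSE]
    obs <- demand_observations(pp$price, pp$quantity, cap)
    fit <- fit_exponentiated(obs, k_span, cap)
    data.frame(participant = pp$participant[1L], session = pp$session[1L],
               intensity_obs = fit$intensity_obs, omax_obs = fit$omax_obs,
               pmax_obs = fit$pmax_obs, Q0 = fit$Q0, alpha = fit$alpha,
               ln_alpha = fit$ln_alpha, k_span = fit$k_span,
               converged = fit$converged,
               fitted_pmax = if (fit$converged) fitted_pmax(fit)
                             else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant, out$session), ]
  rownames(out) <- NULL
  out
}

#' Filter a trial dataset by analysis population
#'
#' `complete_case` keeps only participants with all scheduled sessions
#' present in both the choice and purchase tables. `intention_to_treat`
#' keeps every participant who initiated the intervention (session 2
#' present), treats sessions after the last completed one as missing
#' (rows after a discontinuation are absent), and truncates each
#' participant's daily records at their last submitted drink report or
#' breath sample.
#'
#' @param trial A `trial_data` list (see [simulate_cohort()]).
#' @param mode `"complete_case"` or `"intention_to_treat"`.
#' @param n_sessions Number of scheduled sessions.
#' @return The filtered `trial_data`.
#' @export
complete_case_filter <- function(trial,
                                 mode = c("complete_case",
                                          "intention_to_treat"),
                                 n_sessions = 5) {
  mode <- match.arg(mode)
  sess <- unique(rbind(trial$choices[c("participant", "session")],
                       trial$purchase[c("participant", "session")]))
  n_sess <- tapply(sess$session, sess$participant,
                   function(s) length(unique(s)))
  if (mode == "complete_case") {
    keep <- names(n_sess)[n_sess == n_sessions]
  } else {
    started <- tapply(sess$session, sess$participant,
                      function(s) 2 %in% s)
    keep <- names(started)[started]
  }
  out <- trial
  for (tb in c("profiles", "choices", "purchase", "daily")) {
    idcol <- if (tb == "profiles") "id" else "participant"
    out[[tb]] <- trial[[tb]][trial[[tb]][[idcol]] %in% keep, ,
                             drop = FALSE]
    rownames(out[[tb]]) <- NULL
  }
  if (mode == "intention_to_treat" && nrow(out$daily)) {
    brac_cols <- grep("^brac_", names(out$daily), value = TRUE)
    submitted <- !is.na(out$daily$reported_drinks)
    for (bc in brac_cols) submitted <- submitted | !is.na(out$daily[[bc]])
    keep_rows <- rep(FALSE, nrow(out$daily))
    for (p in unique(out$daily$participant)) {
      rows <- which(out$daily$participant == p)
      sub <- rows[submitted[rows]]
      if (length(sub))
        keep_rows[rows[out$daily$day_index[rows] <=
                         max(out$daily$day_index[sub])]] <- TRUE
    }
    out$daily <- out$daily[keep_rows, , drop = FALSE]
    rownames(out$daily) <- NULL
  }
  attr(out, "mode") <- mode
  out
}

#' Write a trial dataset to delimited files
#'
#' Writes `profiles.csv`, `choices.csv`, `purchase.csv` and `daily.csv`
#' (headered UTF-8 CSV, missing values as empty fields).
#'
#' @param trial A `trial_data` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_data <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in c("profiles", "choices", "purchase", "daily"))
    utils::write.csv(trial[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a trial dataset from delimited files
#'
#' @param dir Directory containing `profiles.csv`, `choices.csv`,
#'   `purchase.csv`, `daily.csv`.
#' @return A `trial_data` list (without generator config).
#' @export
read_trial_data <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), na.strings = "")
  out <- list(profiles = rd("profiles.csv"), choices = rd("choices.csv"),
              purchase = rd("purchase.csv"), daily = rd("daily.csv"),
              config = NULL, schedule = titration_schedule())
  class(out) <- "trial_data"
  out
}

#' Read a trial configuration from YAML
#'
#' Reads a YAML document of [cohort_config()] fields; absent fields take
#' the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A [cohort_config()].
#' @export
read_trial_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$missingness_log_odds))
    raw$missingness_log_odds <- unlist(raw$missingness_log_odds)
  if (!is.null(raw$phase_effects))
    raw$phase_effects <- lapply(raw$phase_effects, unlist)
  do.call(cohort_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

group_session_means <- function(tab, profiles, value) {
  g <- profiles$group[match(tab$participant, profiles$id)]
  agg <- stats::aggregate(tab[[value]],
                          by = list(group = g, session = tab$session),
                          FUN = function(x) mean(x, na.rm = TRUE))
  names(agg)[3] <- paste0("mean_", value)
  agg[order(agg$group, agg$session), ]
}

#' Run the full trial pipeline
#'
#' Simulates (or loads) a trial, then runs every analysis stage in order:
#' discounting estimation, demand estimation, phase-level consumption
#' summaries, breath/self-report concordance, and the BIC adherence model
#' search for missing drink reports. Every interface file and a single
#' JSON report are written; exclusions (nonsystematic discounting flags,
#' nonconverged demand fits, missing days) are counted in the report.
#'
#' @param config A [cohort_config()] (used when simulating, and for
#'   provenance).
#' @param input_dir Directory of existing trial CSVs; when `NULL` the
#'   cohort is simulated from `config`.
#' @param out_dir Output directory.
#' @param mode Analysis population passed to [complete_case_filter()].
#' @return An object of class `trial_report` (also written as
#'   `report.json` in `out_dir`).
#' @examples
#' \donttest{
#' rep <- run_pipeline(cohort_config(n_per_group = 4, seed = 7),
#'                     out_dir = tempfile())
#' print(rep)
#' }
#' @export
run_pipeline <- function(config = cohort_config(), input_dir = NULL,
                         out_dir = tempfile("eftrial_"),
                         mode = c("intention_to_treat", "complete_case")) {
  mode <- match.arg(mode)
  validate_cohort_config(config)
  trial <- if (is.null(input_dir)) simulate_cohort(config)
           else read_trial_data(input_dir)
  trial <- complete_case_filter(trial, mode,
                                n_sessions = config$n_sessions)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_data(trial, out_dir)

  disc <- discounting_table(trial$choices, trial$schedule)
  utils::write.csv(disc, file.path(out_dir, "discounting.csv"),
                   row.names = FALSE, na = "")
  dem <- demand_table(trial$purchase, cap = config$cap)
  utils::write.csv(dem, file.path(out_dir, "demand.csv"),
                   row.names = FALSE, na = "")
  phase_sum <- summarize_phases(trial$daily)
  utils::write.csv(phase_sum, file.path(out_dir, "phase_summaries.csv"),
                   row.names = FALSE, na = "")
  frame <- long_format_export(trial$daily, trial$profiles)
  utils::write.csv(frame, file.path(out_dir, "model_frame.csv"),
                   row.names = FALSE, na = "")
  conc <- concordance_stats(trial$daily)
  utils::write.csv(as.data.frame.matrix(conc$matrix),
                   file.path(out_dir, "concordance_matrix.csv"), na = "")
  jsonlite::write_json(conc[c("odds_ratio", "p_value", "auc", "threshold")],
                       file.path(out_dir, "concordance_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  frame$missing_drinks <- as.integer(is.na(frame$drinks))
  mains <- c("group", "phase", "age", "sex", "ethnicity", "race",
             "education", "income")
  mains <- mains[vapply(mains, function(v)
    length(unique(frame[[v]])) >= 2L, logical(1))]
  sel <- select_by_bic(frame, "missing_drinks", mains = mains,
                       interactions =
                         if (all(c("group", "phase") %in% mains))
                           "group:phase" else character(0))
  jsonlite::write_json(
    list(best = sel$best, n = sel$n, excluded = sel$excluded,
         ranked = utils::head(sel$table, 25)),
    file.path(out_dir, "selection_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  grp <- trial$profiles$group[match(phase_sum$participant,
                                    trial$profiles$id)]
  cons <- stats::aggregate(
    cbind(drinks_per_day, drinks_per_reported_day,
          drinks_per_drinking_day) ~ grp + phase,
    data = cbind(phase_sum, grp = grp),
    FUN = function(x) mean(x, na.rm = TRUE), na.action = stats::na.pass)
  names(cons)[1] <- "group"
  cons <- cons[order(cons$group, match(cons$phase, monitoring_phases())), ]
  rownames(cons) <- NULL

  report <- list(
    discounting = list(
      group_session_ln_k = group_session_means(disc, trial$profiles,
                                               "ln_k"),
      n_sessions = nrow(disc),
      n_nonsystematic = sum(!disc$criterion1_ok | !disc$criterion2_ok),
      n_boundary = sum(disc$boundary_flag)),
    demand = list(
      group_session_ln_alpha = group_session_means(
        dem[dem$converged, ], trial$profiles, "ln_alpha"),
      group_session_intensity = group_session_means(
        dem, trial$profiles, "intensity_obs"),
      n_fits = nrow(dem),
      n_nonconverged = sum(!dem$converged)),
    consumption = list(
      group_phase = cons,
      n_participant_phases = nrow(phase_sum),
      n_missing_days = sum(is.na(trial$daily$reported_drinks))),
    concordance = conc[c("odds_ratio", "p_value", "auc", "threshold")],
    adherence = list(
      best_model = if (length(sel$best)) sel$best else "intercept-only",
      n_models = nrow(sel$table),
      n_nonconverged = length(sel$excluded)),
    provenance = list(
      seed = config$seed, mode = mode, config_hash = config_hash(config),
      n_participants = nrow(trial$profiles),
      package_version = as.character(utils::packageVersion("eftrial"))))
  class(report) <- "trial_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  attr(report, "out_dir") <- out_dir
  report
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Trial analysis report (", x$provenance$mode, ", seed ",
      x$provenance$seed, ", n = ", x$provenance$n_participants, ")\n",
      sep = "")
  cat("\nDrinks/day by group x phase:\n")
  print(x$consumption$group_phase, digits = 4)
  cat("\nConcordance: OR = ", format(x$concordance$odds_ratio, digits = 5),
      ", p = ", format(x$concordance$p_value, digits = 3),
      ", AUC = ", format(x$concordance$auc, digits = 4), "\n", sep = "")
  cat("Adherence best model: ~ ",
      paste(x$adherence$best_model, collapse = " + "), "\n", sep = "")
  cat("Discounting sessions fit: ", x$discounting$n_sessions,
      " (", x$discounting$n_nonsystematic, " flagged nonsystematic)\n",
      sep = "")
  cat("Demand fits: ", x$demand$n_fits, " (", x$demand$n_nonconverged,
      " nonconverged, excluded)\n", sep = "")
  invisible(x)
}
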