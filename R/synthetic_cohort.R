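#' Synthetic trial configuration
#'
#' Generative parameters for a synthetic two-arm remote-monitoring trial.
#' Defaults describe a cohort like the study population: latent hyperbolic
#' discount rates with ln(k) ~ Normal(-5, 2.5^2); baseline drinking around
#' 5.5 drinks/day with between-person spread (Gamma participant rates,
#' SD about 2.2); purchase-task intensity near 10 drinks and demand
#' elasticity near 0.003; an active-arm-only consumption reduction across
#' monitoring phases; and submission missingness that rises in the final
#' monitoring phase.
#'
#' @param n_per_group Participants per arm.
#' @param mean_ln_k,sd_ln_k Population mean and SD of latent ln(k)
#'   (log 1/days).
#' @param mean_baseline_drinks Mean baseline drinking rate (drinks/day).
#' @param baseline_shape Gamma shape for between-person rate heterogeneity
#'   (mean fixed at `mean_baseline_drinks`).
#' @param phase_effects Named list `EFT`/`CET` of length-3 multiplicative
#'   rate factors for phases baseline / monitoring1 / monitoring2.
#' @param demand_Q0_mean,demand_alpha_mean Median latent intensity and
#'   elasticity of the purchase-task population (lognormal).
#' @param sd_ln_Q0,sd_ln_alpha Log-scale SDs of the demand latents.
#' @param demand_gen_k Span constant used when generating purchase
#'   responses (log10 units).
#' @param noise_sd_choice Softmax temperature for discounting choices, in
#'   dollars (0 = deterministic value maximizer).
#' @param noise_sd_demand Multiplicative purchase-task noise SD, log10
#'   units.
#' @param missingness_log_odds Length-3 per-phase log-odds that a daily
#'   submission (drink report; each breath sample) is missing; `-Inf`
#'   disables missingness.
#' @param brac_per_drink Peak % BrAC contributed per drink consumed.
#' @param brac_noise_sd Additive BrAC noise SD (%, truncated at 0).
#' @param phase_days Length-3 calendar days per phase.
#' @param n_sessions Laboratory sessions per participant.
#' @param cap Purchase-task overconsumption cap.
#' @param seed Master seed; per-participant substreams are derived from it
#'   so growing the cohort does not reshuffle earlier participants.
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n_per_group = 4, seed = 1)
#' @export
cohort_config <- function(n_per_group = 32,
                          mean_ln_k = -5.0,
                          sd_ln_k = 2.5,
                          mean_baseline_drinks = 5.5,
                          baseline_shape = 6.25,
                          phase_effects = list(EFT = c(1, 0.8, 0.6),
                                               CET = c(1, 1, 1)),
                          demand_Q0_mean = 10,
                          demand_alpha_mean = 0.003,
                          sd_ln_Q0 = 0.3,
                          sd_ln_alpha = 0.5,
                          demand_gen_k = 2,
                          noise_sd_choice = 20,
                          noise_sd_demand = 0.12,
                          missingness_log_odds = c(baseline = -2,
                                                   monitoring1 = -2,
                                                   monitoring2 = -0.5),
                          brac_per_drink = 0.02,
                          brac_noise_sd = 0.005,
                          phase_days = c(7, 14, 14),
                          n_sessions = 5,
                          cap = 50,
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid configuration: '%s' %s", field, why))
  chk(length(cfg$n_per_group) == 1L && cfg$n_per_group >= 1 &&
        cfg$n_per_group == round(cfg$n_per_group),
      "n_per_group", "must be a positive integer")
  chk(is.finite(cfg$mean_ln_k), "mean_ln_k", "must be finite")
  chk(cfg$sd_ln_k >= 0, "sd_ln_k", "must be >= 0")
  chk(cfg$mean_baseline_drinks >= 0, "mean_baseline_drinks",
      "must be >= 0")
  chk(is.list(cfg$phase_effects) &&
        all(c("EFT", "CET") %in% names(cfg$phase_effects)),
      "phase_effects", "must name EFT and CET")
  for (g in c("EFT", "CET"))
    chk(length(cfg$phase_effects[[g]]) == 3L &&
          all(cfg$phase_effects[[g]] > 0),
        "phase_effects", paste0("for ", g,
                                " must be 3 positive rate factors"))
  chk(cfg$demand_Q0_mean > 0, "demand_Q0_mean", "must be > 0")
  chk(cfg$demand_alpha_mean > 0, "demand_alpha_mean", "must be > 0")
  chk(cfg$noise_sd_choice >= 0, "noise_sd_choice", "must be >= 0")
  chk(cfg$noise_sd_demand >= 0, "noise_sd_demand", "must be >= 0")
  chk(length(cfg$missingness_log_odds) == 3L &&
        !anyNA(cfg$missingness_log_odds),
      "missingness_log_odds", "must be 3 per-phase log-odds")
  chk(cfg$brac_per_drink >= 0, "brac_per_drink", "must be >= 0")
  chk(length(cfg$phase_days) == 3L && all(cfg$phase_days >= 1),
      "phase_days", "must be 3 positive day counts")
  chk(cfg$n_sessions >= 1, "n_sessions", "must be >= 1")
  chk(length(cfg$seed) == 1L && is.finite(cfg$seed), "seed",
      "must be a single integer")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic trial configuration:", 2 * x$n_per_group,
      "participants (", x$n_per_group, "per arm ), seed", x$seed, "\n")
  cat("  ln(k) ~ N(", x$mean_ln_k, ",", x$sd_ln_k, "^2 );",
      "baseline", x$mean_baseline_drinks, "drinks/day\n")
  cat("  phase factors EFT:", paste(x$phase_effects$EFT, collapse = "/"),
      " CET:", paste(x$phase_effects$CET, collapse = "/"), "\n")
  cat("  missingness log-odds:",
      paste(signif(x$missingness_log_odds, 3), collapse = "/"), "\n")
  invisible(x)
}

#' Simulated discounting chooser
#'
#' A choice function for the adjusting-amount task. Each option is valued
#' hyperbolically (`value = amount / (1 + k * delay)`; the smaller-sooner
#' amount is immediate, so its value is its amount) and the smaller-sooner
#' option is chosen with logistic probability
#' `plogis((ss - value_LL) / temperature)`. Temperature 0 gives the
#' deterministic value maximizer (SS chosen when its amount is at least
#' the delayed value).
#'
#' @param latent_ln_k Natural log of the hyperbolic discount rate
#'   (1/days).
#' @param temperature Softmax temperature in dollars (>= 0).
#' @return A function `(ss, ll, delay)` returning `"SS"` or `"LL"`;
#'   stochastic choosers draw from the session RNG stream.
#' @examples
#' ch <- simulated_chooser(log(0.01), temperature = 0)
#' ch(600, 1000, 100)  # "SS": $600 now beats $500 of present value
#' @export
simulated_chooser <- function(latent_ln_k, temperature = 0) {
  if (temperature < 0) stop("'temperature' must be >= 0")
  k <- exp(latent_ln_k)
  function(ss, ll, delay) {
    if (ss < 0 || ll < 0) stop("amounts must be non-negative")
    v <- ll / (1 + k * delay)
    if (temperature == 0) {
      if (ss >= v) "SS" else "LL"
    } else {
      if (stats::runif(1) < stats::plogis((ss - v) / temperature))
        "SS" else "LL"
    }
  }
}

# Derive a reproducible substream seed for participant i from the master
# seed; fixed multiplier keeps streams stable when the cohort grows.
participant_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * i) %% 2147483563)
}

#' Simulate a complete synthetic trial
#'
#' Generates participant profiles with latent truths, session-level
#' discounting choice records and purchase-task responses, and daily
#' drinking/breath records across the three monitoring phases. Daily drink
#' counts are Poisson with rate `participant rate x group-phase factor`;
#' each day schedules three breath samples whose readings scale with the
#' day's drinks (with a decay toward later samples and additive noise
#' truncated at zero); the drink report and each breath sample are
#' independently set missing by the per-phase log-odds mechanism. One
#' master seed fans out to per-participant substreams.
#'
#' @param config A [cohort_config()].
#' @return An object of class `trial_data`: a list of data frames
#'   `profiles`, `choices`, `purchase`, `daily`, plus the `config` and
#'   the titration `schedule` used.
#' @examples
#' trial <- simulate_cohort(cohort_config(n_per_group = 2, seed = 42))
#' names(trial)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  schedule <- titration_schedule()
  prices <- apt_prices()
  phases <- monitoring_phases()
  n_total <- 2L * config$n_per_group
  p_miss <- stats::plogis(as.numeric(config$missingness_log_odds))
  decay <- c(1, 0.75, 0.5)

  profiles <- vector("list", n_total)
  choices <- vector("list", n_total)
  purchase <- vector("list", n_total)
  daily <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    set.seed(participant_seed(config$seed, i))
    id <- sprintf("P%03d", i)
    group <- if (i %% 2L == 1L) "EFT" else "CET"
    ln_k <- stats::rnorm(1, config$mean_ln_k, config$sd_ln_k)
    Q0 <- stats::rlnorm(1, log(config$demand_Q0_mean), config$sd_ln_Q0)
    alpha <- stats::rlnorm(1, log(config$demand_alpha_mean),
                           config$sd_ln_alpha)
    rate <- if (config$baseline_shape > 0)
      stats::rgamma(1, shape = config$baseline_shape,
                    rate = config$baseline_shape /
                      max(config$mean_baseline_drinks, 1e-12))
      else config$mean_baseline_drinks
    profiles[[i]] <- data.frame(
      id = id, group = group, latent_ln_k = ln_k, latent_Q0 = Q0,
      latent_alpha = alpha, baseline_rate = rate, missing_propensity = 0,
      age = round(min(max(stats::rnorm(1, 39, 13), 21), 65)),
      sex = sample(c("Male", "Female"), 1, prob = c(0.64, 0.36)),
      ethnicity = sample(c("Not Hispanic or Latino", "Hispanic or Latino"),
                         1, prob = c(0.94, 0.06)),
      race = sample(c("White", "Black or African American", "Other"), 1,
                    prob = c(0.78, 0.13, 0.09)),
      education = sample(c("High School", "College", "Graduate School"),
                         1, prob = c(0.19, 0.61, 0.20)),
      income = sample(c("<$25k", "$25-50k", "$50-100k", ">$100k"), 1,
                      prob = c(0.28, 0.29, 0.27, 0.16)),
      audit_score = round(min(max(stats::rnorm(1, 23, 4.5), 16), 40)))

    # session-level tasks
    chooser <- simulated_chooser(ln_k, config$noise_sd_choice)
    ch_rows <- vector("list", config$n_sessions)
    pu_rows <- vector("list", config$n_sessions)
    for (s in seq_len(config$n_sessions)) {
      curve <- run_titration(chooser, schedule, session = s)
      tr <- attr(curve, "trials")
      tr <- cbind(participant = id, session = s, tr)
      ch_rows[[s]] <- tr
      q_latent <- exponentiated_demand(prices, Q0, alpha,
                                       config$demand_gen_k)
      q <- round(q_latent *
                   10^stats::rnorm(length(prices), 0,
                                   config$noise_sd_demand))
      pu_rows[[s]] <- data.frame(participant = id, session = s,
                                 price = prices,
                                 quantity = pmin(pmax(q, 0), config$cap))
    }
    choices[[i]] <- do.call(rbind, ch_rows)
    purchase[[i]] <- do.call(rbind, pu_rows)

    # daily monitoring
    phase_vec <- rep(phases, times = config$phase_days)
    n_days <- length(phase_vec)
    factor_g <- config$phase_effects[[group]]
    lam <- rate * factor_g[match(phase_vec, phases)]
    drinks <- stats::rpois(n_days, lam)
    pm <- p_miss[match(phase_vec, phases)]
    reported <- ifelse(stats::runif(n_days) < pm, NA_integer_, drinks)
    brac <- matrix(NA_real_, n_days, 3)
    for (j in 1:3) {
      raw <- pmax(0, drinks * config$brac_per_drink * decay[j] +
                    stats::rnorm(n_days, 0, config$brac_noise_sd))
      submitted <- stats::runif(n_days) >= pm
      brac[, j] <- ifelse(submitted, raw, NA_real_)
    }
    daily[[i]] <- data.frame(participant = id,
                             day_index = seq_len(n_days),
                             phase = phase_vec,
                             reported_drinks = reported,
                             brac_1 = brac[, 1], brac_2 = brac[, 2],
                             brac_3 = brac[, 3])
  }

  out <- list(profiles = do.call(rbind, profiles),
              choices = do.call(rbind, choices),
              purchase = do.call(rbind, purchase),
              daily = do.call(rbind, daily),
              config = config, schedule = schedule)
  rownames(out$profiles) <- rownames(out$choices) <- NULL
  rownames(out$purchase) <- rownames(out$daily) <- NULL
  class(out) <- "trial_data"
  out
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Synthetic trial dataset:", nrow(x$profiles), "participants\n")
  cat("  choices:", nrow(x$choices), "rows; purchase:", nrow(x$purchase),
      "rows; daily:", nrow(x$daily), "rows\n")
  invisible(x)
}
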