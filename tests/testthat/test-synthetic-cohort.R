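test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- cohort_config(n_per_group = 3, seed = 21)
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1$profiles, t2$profiles)
  expect_identical(t1$choices, t2$choices)
  expect_identical(t1$purchase, t2$purchase)
  expect_identical(t1$daily, t2$daily)
})

test_that("growing the cohort does not reshuffle earlier participants", {
  small <- simulate_cohort(cohort_config(n_per_group = 3, seed = 8))
  big <- simulate_cohort(cohort_config(n_per_group = 5, seed = 8))
  expect_identical(small$profiles,
                   big$profiles[seq_len(nrow(small$profiles)), ])
  expect_identical(small$daily,
                   big$daily[big$daily$participant %in%
                               small$profiles$id, ])
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
  expect_error(cohort_config(sd_ln_k = -1), "sd_ln_k")
  expect_error(cohort_config(phase_effects = list(EFT = c(1, 1, -1),
                                                  CET = c(1, 1, 1))),
               "phase_effects")
  expect_error(cohort_config(missingness_log_odds = c(0, 0)),
               "missingness_log_odds")
})

test_that("every participant carries 5 sessions and 35 monitored days", {
  trial <- simulate_cohort(cohort_config(n_per_group = 2, seed = 12))
  sch <- trial$schedule
  per_session <- length(sch$delays) * sch$trials_per_delay
  counts <- table(trial$choices$participant, trial$choices$session)
  expect_true(all(counts == per_session))
  expect_equal(ncol(counts), 5)
  expect_true(all(table(trial$purchase$participant) == 5 * 13))
  expect_true(all(table(trial$daily$participant) == 35))
  expect_equal(as.vector(tapply(trial$daily$phase, trial$daily$participant,
                                function(p) sum(p == "baseline"))),
               rep(7, 4))
})

test_that("neutral phase factors reproduce the configured drinking rate", {
  cfg <- cohort_config(n_per_group = 100, seed = 33,
                       baseline_shape = 0,  # no between-person spread
                       phase_effects = list(EFT = c(1, 1, 1),
                                            CET = c(1, 1, 1)),
                       missingness_log_odds = c(-Inf, -Inf, -Inf))
  trial <- simulate_cohort(cfg)
  expect_false(anyNA(trial$daily$reported_drinks))
  by_phase <- tapply(trial$daily$reported_drinks, trial$daily$phase, mean)
  n_days <- tapply(trial$daily$reported_drinks, trial$daily$phase, length)
  # Poisson mean 5.5: each phase mean within 4 SE of the generator mean
  se <- sqrt(5.5 / n_days)
  expect_true(all(abs(by_phase - 5.5) < 4 * se))
})

test_that("a group-by-phase rate factor shifts only the targeted arm", {
  cfg <- cohort_config(n_per_group = 80, seed = 14,
                       phase_effects = list(EFT = c(1, 1, 0.6),
                                            CET = c(1, 1, 1)),
                       missingness_log_odds = c(-Inf, -Inf, -Inf))
  trial <- simulate_cohort(cfg)
  g <- trial$profiles$group[match(trial$daily$participant,
                                  trial$profiles$id)]
  m <- tapply(trial$daily$reported_drinks, list(g, trial$daily$phase),
              mean)
  expect_equal(m["EFT", "monitoring2"] / m["EFT", "baseline"], 0.6,
               tolerance = 0.1)
  expect_equal(m["CET", "monitoring2"] / m["CET", "baseline"], 1,
               tolerance = 0.1)
})

test_that("missingness tracks the logistic transform of the log-odds", {
  lo <- c(baseline = -2, monitoring1 = -1, monitoring2 = 0.5)
  cfg <- cohort_config(n_per_group = 60, seed = 9,
                       missingness_log_odds = lo)
  trial <- simulate_cohort(cfg)
  for (ph in monitoring_phases()) {
    d <- trial$daily$reported_drinks[trial$daily$phase == ph]
    p_hat <- mean(is.na(d))
    p <- plogis(lo[[ph]])
    expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / length(d)))
  }
})

test_that("breath readings rise with the day's drinks", {
  cfg <- cohort_config(n_per_group = 30, seed = 55,
                       missingness_log_odds = c(-Inf, -Inf, -Inf))
  trial <- simulate_cohort(cfg)
  peak <- pmax(trial$daily$brac_1, trial$daily$brac_2, trial$daily$brac_3,
               na.rm = TRUE)
  drinking <- trial$daily$reported_drinks >= 1
  expect_gt(mean(peak[drinking]), mean(peak[!drinking]) + 0.02)
  expect_true(all(peak >= 0))
})

test_that("the deterministic chooser is the value maximizer", {
  ch <- simulated_chooser(log(0.01), temperature = 0)
  expect_equal(ch(600, 1000, 100), "SS")  # value of LL is $500
  expect_equal(ch(400, 1000, 100), "LL")
  expect_error(ch(-5, 1000, 100), "non-negative")
  expect_error(simulated_chooser(-5, temperature = -1), ">= 0")
})

test_that("an extremely noisy chooser is indifferent", {
  ch <- simulated_chooser(log(0.01), temperature = 1e9)
  set.seed(77)
  picks <- replicate(1000, ch(100, 1000, 30))
  bt <- binom.test(sum(picks == "SS"), 1000, 0.5)
  expect_gt(bt$p.value, 0.001)
})

test_that("noiseless synthetic cohorts are recovered by the estimator", {
  cfg <- cohort_config(n_per_group = 10, seed = 19, noise_sd_choice = 0)
  trial <- simulate_cohort(cfg)
  disc <- discounting_table(trial$choices, trial$schedule)
  est <- tapply(disc$ln_k, disc$participant, mean)
  lat <- trial$profiles$latent_ln_k[match(names(est), trial$profiles$id)]
  expect_gt(cor(lat, est), 0.999)
  expect_lt(max(abs(lat - est)), 0.2)
})
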