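test_that("titration follows the halving update rule at the extremes", {
  sch <- titration_schedule()
  up <- run_titration(function(ss, ll, d) "LL", sch)
  tr <- attr(up, "trials")
  expect_equal(tr$ss_amount[tr$delay_days == 1],
               c(500, 750, 875, 937.5, 968.75, 984.375))
  expect_true(all(up$indifference == 992.1875))
  dn <- run_titration(function(ss, ll, d) "SS", sch)
  expect_true(all(dn$indifference == 7.8125))
})

test_that("titration equals a binary search: all 2^6 choice paths", {
  sch <- titration_schedule(delays = 100)
  res <- titration_resolution(sch)
  for (bits in 0:63) {
    path <- ifelse(bitwAnd(bits, 2^(0:5)) > 0, "SS", "LL")
    t_i <- 0
    chooser <- function(ss, ll, d) {
      t_i <<- t_i + 1
      path[t_i]
    }
    got <- run_titration(chooser, sch)$indifference
    # oracle: hand-apply the halving rule
    ss <- 500
    for (t in 1:6) ss <- ss + (if (path[t] == "SS") -1 else 1) * 1000 / 2^(t + 1)
    expect_identical(got, ss)
    # reachable values lie on the odd half-step grid within [res, A - res]
    expect_true(got >= res && got <= 1000 - res)
    expect_equal(got %% (2 * res), res)
  }
})

test_that("a monotone (threshold) chooser converges to its threshold", {
  sch <- titration_schedule(delays = 30)
  res <- titration_resolution(sch)
  for (thr in c(3, 77.2, 499, 501.5, 940.1)) {
    chooser <- function(ss, ll, d) if (ss >= thr) "SS" else "LL"
    ip <- run_titration(chooser, sch)$indifference
    expect_lte(abs(ip - thr), res)
  }
})

test_that("a deterministic hyperbolic chooser titrates to the model value", {
  sch <- titration_schedule(delays = 100)
  ip <- run_titration(simulated_chooser(log(0.01), 0), sch)$indifference
  expect_lte(abs(ip - 1000 / (1 + 0.01 * 100)), titration_resolution(sch))
})

test_that("an invalid chooser response raises a protocol error", {
  expect_error(run_titration(function(ss, ll, d) "maybe",
                             titration_schedule(delays = 1)),
               "invalid option")
})

test_that("Johnson-Bickel screen applies both criteria", {
  ok <- johnson_bickel_screen(c(990, 900, 700, 500, 300, 150, 80), 1000)
  expect_true(ok$criterion1_ok)
  expect_true(ok$criterion2_ok)
  c1 <- johnson_bickel_screen(c(990, 900, 700, 950, 300, 150, 80), 1000)
  expect_false(c1$criterion1_ok)  # 700 -> 950 rise of 250 > 200
  expect_true(c1$criterion2_ok)
  c2 <- johnson_bickel_screen(c(950, 940, 930, 920, 910, 900, 880), 1000)
  expect_true(c2$criterion1_ok)
  expect_false(c2$criterion2_ok)  # 950 - 880 = 70 < 100
  # boundary: a rise of exactly 20% of A does not violate criterion 1
  expect_true(johnson_bickel_screen(c(500, 700), 1000)$criterion1_ok)
  expect_error(johnson_bickel_screen(500, 1000), "at least 2")
})

test_that("noiseless hyperbolic curves are recovered to 1e-6", {
  sch <- titration_schedule()
  for (k in c(1e-4, 0.01, 0.3)) {
    v <- sch$A / (1 + k * sch$delays)
    fit <- fit_hyperbolic(indifference_curve(sch$delays, v), sch)
    expect_lt(abs(fit$k - k) / k, 1e-6)
    expect_equal(fit$ln_k, log(k), tolerance = 1e-6)
    expect_false(fit$boundary_flag)
  }
})

test_that("degenerate curves return boundary fits, not errors", {
  sch <- titration_schedule()
  flat <- fit_hyperbolic(indifference_curve(sch$delays,
                                            rep(sch$A, 7)), sch)
  expect_true(flat$boundary_flag)
  expect_lt(flat$k, 1e-9)
  zero <- fit_hyperbolic(indifference_curve(sch$delays, rep(0, 7)), sch)
  expect_true(zero$boundary_flag)
})

test_that("the fit dominates a dense log-grid oracle on random curves", {
  sch <- titration_schedule()
  set.seed(402)
  for (i in 1:20) {
    v <- sort(runif(7, 0, sch$A), decreasing = TRUE)
    fit <- fit_hyperbolic(indifference_curve(sch$delays, v), sch)
    orc <- oracle_hyperbolic_sse(v, sch$delays, sch$A, n_grid = 2e4)
    expect_lte(fit$sse, orc$sse + 1e-9)
  }
})

test_that("the hyperbolic fit is invariant to rescaling V and A together", {
  sch1 <- titration_schedule(A = 1000)
  sch2 <- titration_schedule(A = 10)
  v <- c(980, 850, 700, 520, 260, 90, 30)
  f1 <- fit_hyperbolic(indifference_curve(sch1$delays, v), sch1)
  f2 <- fit_hyperbolic(indifference_curve(sch2$delays, v / 100), sch2)
  expect_equal(f1$k, f2$k, tolerance = 1e-6)
})

test_that("model-object methods are coherent", {
  sch <- titration_schedule()
  v <- sch$A / (1 + 0.02 * sch$delays) + c(5, -4, 3, -2, 1, 0, -1)
  fit <- fit_hyperbolic(indifference_curve(sch$delays, v), sch)
  expect_named(coef(fit), "k")
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, data.frame(delay = 0)), sch$A)
  expect_equal(residuals(fit) + fit$fitted, v, tolerance = 1e-12)
  expect_output(print(fit), "Hyperbolic")
  expect_output(print(summary(fit)), "indifference points")
})
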