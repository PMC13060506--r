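test_that("overconsumption capping is elementwise and idempotent", {
  got <- cap_overconsumption(c(0, 10, 80))
  expect_equal(got$quantity, c(0, 10, 50))
  expect_equal(got$capped, c(FALSE, FALSE, TRUE))
  at_cap <- cap_overconsumption(50)
  expect_equal(at_cap$quantity, 50)
  expect_false(at_cap$capped)
  twice <- cap_overconsumption(got$quantity)
  expect_equal(twice$quantity, got$quantity)
  expect_false(any(twice$capped))
  expect_error(cap_overconsumption(-1), "non-negative")
})

test_that("observed metrics: intensity, Omax, and lowest-price Pmax", {
  m <- observed_metrics(demand_observations(c(0, 1, 2, 4), c(10, 8, 5, 2)))
  expect_equal(m, list(intensity = 10, omax = 10, pmax = 2))
  zero <- observed_metrics(demand_observations(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(zero, list(intensity = 0, omax = 0, pmax = 0))
  tie <- observed_metrics(demand_observations(c(0, 1, 2), c(6, 4, 2)))
  expect_equal(tie$omax, 4)
  expect_equal(tie$pmax, 1)  # lowest price attaining the maximum
})

test_that("shared span follows the pooled log10 range plus half a decade", {
  expect_equal(shared_k_span(1:50), log10(50) + 0.5)
  expect_equal(shared_k_span(rep(10, 7)), 0.5)
  expect_equal(shared_k_span(c(0, 2, 7, 20)), log10(20) - log10(2) + 0.5)
  expect_error(shared_k_span(c(0, 0)), "no positive")
})

test_that("noiseless exponentiated demand is recovered to 1e-4", {
  pr <- apt_prices()
  q <- exponentiated_demand(pr, 10, 0.003, 2)
  fit <- fit_exponentiated(demand_observations(pr, q), k_span = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$Q0 - 10) / 10, 1e-4)
  expect_lt(abs(fit$alpha - 0.003) / 0.003, 1e-4)
  expect_equal(predict(fit, data.frame(price = 0)), fit$Q0)
})

test_that("predicted demand equals Q0 at zero price and never increases", {
  pr <- seq(0, 80, length.out = 40)
  for (par in list(c(5, 0.01), c(30, 0.001), c(50, 0.1))) {
    q <- exponentiated_demand(pr, par[1], par[2], 2.5)
    expect_equal(q[1], par[1])
    expect_true(all(diff(q) <= 1e-12))
  }
})

test_that("fits dominate a dense 2-D grid oracle on noisy sets", {
  pr <- apt_prices()
  set.seed(77)
  for (i in 1:20) {
    q0 <- runif(1, 3, 40)
    al <- exp(runif(1, log(5e-4), log(0.05)))
    q <- pmin(round(exponentiated_demand(pr, q0, al, 2) *
                      10^rnorm(13, 0, 0.15)), 50)
    fit <- fit_exponentiated(demand_observations(pr, q), k_span = 2)
    if (!fit$converged) next
    orc <- oracle_demand_sse(pr, pmax(q, 0), 2, c(0.5, 100), c(1e-5, 1))
    expect_lte(fit$sse, orc$sse + 1e-6)
  }
})

test_that("price rescaling trades off exactly against alpha", {
  pr <- apt_prices()
  q1 <- exponentiated_demand(pr, 12, 0.004, 2)
  q2 <- exponentiated_demand(pr * 4, 12, 0.001, 2)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("all-zero quantity sets yield a nonconvergence result", {
  fit <- fit_exponentiated(demand_observations(apt_prices(), rep(0, 13)),
                           k_span = 2)
  expect_false(fit$converged)
  expect_true(is.na(fit$alpha))
  expect_error(predict(fit), "nonconverged")
  expect_error(fitted_pmax(fit), "did not converge")
})

test_that("fitted Pmax matches a fine-grid expenditure maximization", {
  pr <- apt_prices()
  q <- exponentiated_demand(pr, 10, 0.003, 2)
  fit <- fit_exponentiated(demand_observations(pr, q), k_span = 2)
  upper <- 10 * fit$pmax_obs + 1
  pm <- fitted_pmax(fit)
  grid <- seq(0, upper, length.out = 1e6)
  e <- grid * exponentiated_demand(grid, fit$Q0, fit$alpha, fit$k_span)
  expect_lt(abs(pm - grid[which.max(e)]), upper / 1e6 * 2)
})

test_that("fitted Pmax scales inversely with alpha and shrinks to zero", {
  pr <- apt_prices()
  mk <- function(alpha) {
    q <- exponentiated_demand(pr, 10, alpha, 2)
    fit_exponentiated(demand_observations(pr, q), k_span = 2)
  }
  base <- fitted_pmax(mk(0.002), upper = 200)
  doubled <- fitted_pmax(mk(0.004), upper = 200)
  expect_equal(doubled, base / 2, tolerance = 1e-3)
  ladder <- vapply(c(0.002, 0.01, 0.05, 0.25),
                   function(a) fitted_pmax(mk(a), upper = 200), numeric(1))
  expect_true(all(diff(ladder) < 0))
})

test_that("demand model methods are coherent", {
  pr <- apt_prices()
  q <- pmin(round(exponentiated_demand(pr, 15, 0.005, 2) *
                    10^c(0.02, -0.05, 0.1, 0, 0.03, -0.1, 0.06, 0, -0.02,
                         0.04, 0, 0.05, 0)), 50)
  fit <- fit_exponentiated(demand_observations(pr, q), k_span = 2)
  expect_named(coef(fit), c("Q0", "alpha"))
  expect_equal(residuals(fit), q - fit$fitted)
  expect_output(print(fit), "Exponentiated demand")
  expect_output(print(summary(fit)), "prices")
})
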