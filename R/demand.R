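#' Default alcohol purchase task price list
#'
#' Thirteen ascending prices per drink from $0 to $80, the shape used by
#' the purchase task (count, ordering and endpoints fixed; interior prices
#' configurable).
#'
#' @return Numeric vector of 13 prices.
#' @export
apt_prices <- function() c(0, 0.25, 0.50, 1, 1.50, 2, 2.50, 3, 4, 5, 6, 10, 80)

#' Cap overconsumption responses
#'
#' Purchase-task responses above the cap (default 50 drinks at any given
#' price, the screen for implausible 24-hour self-consumption) are
#' transformed to the cap and flagged. Capping is idempotent.
#'
#' @param quantities Non-negative integer drink counts.
#' @param cap Maximum allowed drinks per price.
#' @return A list with `quantity` (capped counts) and `capped`
#'   (logical flags).
#' @examples
#' cap_overconsumption(c(0, 10, 80))
#' @export
cap_overconsumption <- function(quantities, cap = 50) {
  if (any(!is.finite(quantities)) || any(quantities < 0))
    stop("quantities must be finite and non-negative")
  flagged <- quantities > cap
  list(quantity = pmin(quantities, cap), capped = flagged)
}

#' Demand observation set
#'
#' One purchase-task administration: aligned price and quantity vectors,
#' with quantities capped on construction.
#'
#' @param prices Strictly ascending prices in $/drink, starting at 0.
#' @param quantities Reported drink counts aligned to `prices`.
#' @param cap Overconsumption cap (default 50).
#' @return An object of class `demand_observations` (a data frame with
#'   columns `price`, `quantity`, `capped`).
#' @export
demand_observations <- function(prices, quantities, cap = 50) {
  if (length(prices) != length(quantities))
    stop("'prices' and 'quantities' must have equal length")
  if (length(prices) < 2L) stop("at least 2 prices are required")
  if (is.unsorted(prices, strictly = TRUE))
    stop("prices must be strictly ascending")
  if (prices[1L] != 0) stop("the first price must be 0 (free consumption)")
  cp <- cap_overconsumption(quantities, cap)
  out <- data.frame(price = as.numeric(prices), quantity = cp$quantity,
                    capped = cp$capped)
  attr(out, "cap") <- cap
  class(out) <- c("demand_observations", "data.frame")
  out
}

#' Observed demand metrics
#'
#' Intensity (consumption at price $0), maximum expenditure Omax over the
#' expenditure series `price * quantity`, and Pmax, the smallest price at
#' which Omax occurs.
#'
#' @param obs A [demand_observations()] object.
#' @return A list with `intensity`, `omax`, `pmax`.
#' @examples
#' observed_metrics(demand_observations(c(0, 1, 2, 4), c(10, 8, 5, 2)))
#' @export
observed_metrics <- function(obs) {
  stopifnot(inherits(obs, "demand_observations"))
  expenditure <- obs$price * obs$quantity
  omax <- max(expenditure)
  list(intensity = obs$quantity[obs$price == 0],
       omax = omax,
       pmax = obs$price[which(expenditure == omax)[1L]])
}

#' Shared span constant for exponentiated demand
#'
#' The span `k` of the exponentiated demand equation, fixed across all fits
#' in a dataset: `log10(max pooled Q) - log10(min pooled nonzero Q) + 0.5`.
#'
#' @param quantities Pooled quantities across the dataset (vector or list
#'   of vectors).
#' @return The shared span (log10 units).
#' @examples
#' shared_k_span(1:50)  # log10(50) + 0.5
#' @export
shared_k_span <- function(quantities) {
  q <- unlist(quantities, use.names = FALSE)
  q <- q[is.finite(q)]
  pos <- q[q > 0]
  if (length(pos) == 0L)
    stop("cannot compute the span: no positive quantities in the pooled data")
  log10(max(pos)) - log10(min(pos)) + 0.5
}

#' Evaluate the exponentiated demand equation
#'
#' `Q(C) = Q0 * 10^(k * (exp(-alpha * Q0 * C) - 1))`: consumption `Q` at
#' unit price `C`, with intensity `Q0`, elasticity-rate `alpha` and span
#' `k` (log10 units). Defined at `C = 0` (where `Q = Q0`) and compatible
#' with zero consumption observations, which is why fitting stays on the
#' raw consumption scale.
#'
#' @param C Prices ($/drink).
#' @param Q0 Intensity (drinks at price 0), > 0.
#' @param alpha Elasticity rate, > 0.
#' @param k_span Span of the function in log10 units, > 0.
#' @return Predicted consumption at each price.
#' @examples
#' exponentiated_demand(c(0, 1, 5), 10, 0.003, 2)
#' @export
exponentiated_demand <- function(C, Q0, alpha, k_span) {
  Q0 * 10^(k_span * (exp(-alpha * Q0 * C) - 1))
}

#' Fit the exponentiated demand equation
#'
#' Least-squares estimation of `Q0` (intensity) and `alpha` (elasticity
#' rate) in the exponentiated demand equation
#' `Q = Q0 * 10^(k * (exp(-alpha * Q0 * C) - 1))`, on the raw consumption
#' scale with zero observations retained (the exponentiated form exists to
#' keep them). The span `k` is supplied, normally from [shared_k_span()].
#' Optimization runs L-BFGS-B on log-parameters from five deterministic
#' starting points with `Q0` bounded in `(0, 2 * cap]` and `alpha` in
#' `[1e-8, 10]`; `converged` is `FALSE` when all starts fail, quantities
#' are all zero, or the optimum sits on the `alpha` bounds. Nonconverged
#' fits are excluded from downstream summaries.
#'
#' @param obs A [demand_observations()] object.
#' @param k_span Span constant (log10 units), shared across a dataset.
#' @param cap Overconsumption cap used for the `Q0` upper bound.
#' @return An object of class `demand_fit` with elements `Q0`, `alpha`,
#'   `ln_alpha`, `k_span`, `sse`, `converged`, the observed metrics
#'   (`intensity_obs`, `omax_obs`, `pmax_obs`), `fitted`, `residuals`
#'   and `obs`.
#' @examples
#' pr <- apt_prices()
#' q <- exponentiated_demand(pr, 10, 0.003, 2)
#' fit <- fit_exponentiated(demand_observations(pr, q), k_span = 2)
#' coef(fit)
#' @export
fit_exponentiated <- function(obs, k_span, cap = 50) {
  stopifnot(inherits(obs, "demand_observations"))
  if (!is.numeric(k_span) || k_span <= 0) stop("'k_span' must be positive")
  C <- obs$price
  Q <- obs$quantity
  om <- observed_metrics(obs)
  base <- list(Q0 = NA_real_, alpha = NA_real_, ln_alpha = NA_real_,
               k_span = k_span, sse = NA_real_, converged = FALSE,
               intensity_obs = om$intensity, omax_obs = om$omax,
               pmax_obs = om$pmax, fitted = rep(NA_real_, length(Q)),
               residuals = rep(NA_real_, length(Q)), obs = obs)
  if (all(Q == 0)) return(structure(base, class = "demand_fit"))

  sse_of <- function(p) {
    r <- Q - exponentiated_demand(C, exp(p[1L]), exp(p[2L]), k_span)
    sum(r * r)
  }
  lower <- log(c(1e-3, 1e-8))
  upper <- log(c(2 * cap, 10))
  q0_start <- max(om$intensity, max(Q) / 2, 0.5)
  starts <- lapply(c(1e-4, 1e-3, 3e-3, 1e-2, 1e-1),
                   function(a) log(c(min(q0_start, 2 * cap), a)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, sse_of, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e2,
                                                 maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(structure(base, class = "demand_fit"))
  # Nelder-Mead polish from the best bounded solution
  pol <- tryCatch(
    stats::optim(best$par, sse_of, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000L)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value &&
      all(pol$par >= lower - 1e-9) && all(pol$par <= upper + 1e-9))
    best <- pol
  Q0 <- exp(best$par[1L]); alpha <- exp(best$par[2L])
  on_alpha_bound <- abs(best$par[2L] - lower[2L]) < 1e-6 ||
    abs(best$par[2L] - upper[2L]) < 1e-6
  fitted <- exponentiated_demand(C, Q0, alpha, k_span)
  out <- base
  out$Q0 <- Q0; out$alpha <- alpha; out$ln_alpha <- log(alpha)
  out$sse <- best$value
  out$converged <- !on_alpha_bound
  out$fitted <- fitted
  out$residuals <- Q - fitted
  structure(out, class = "demand_fit")
}

#' @export
print.demand_fit <- function(x, digits = 5, ...) {
  cat("Exponentiated demand fit: Q = Q0 * 10^(k (exp(-alpha Q0 C) - 1))\n")
  if (!x$converged) {
    cat("  fit did not converge (excluded downstream)\n")
  } else {
    cat("  Q0 =", format(x$Q0, digits = digits),
        " alpha =", format(x$alpha, digits = digits),
        " (ln alpha =", format(x$ln_alpha, digits = digits), ")\n")
    cat("  span k =", format(x$k_span, digits = digits),
        " SSE =", format(x$sse, digits = digits), "\n")
  }
  cat("  observed: intensity =", x$intensity_obs,
      " Omax =", format(x$omax_obs), " Pmax =", format(x$pmax_obs), "\n")
  invisible(x)
}

#' @export
coef.demand_fit <- function(object, ...)
  c(Q0 = object$Q0, alpha = object$alpha)

#' @export
residuals.demand_fit <- function(object, ...) object$residuals

#' @rdname fit_exponentiated
#' @param object,x A `demand_fit`.
#' @param newdata Optional data frame with a `price` column.
#' @param ... Unused.
#' @export
predict.demand_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a nonconverged demand fit")
  C <- if (is.null(newdata)) object$obs$price else newdata$price
  exponentiated_demand(C, object$Q0, object$alpha, object$k_span)
}

#' @export
summary.demand_fit <- function(object, ...) {
  out <- unclass(object)[c("Q0", "alpha", "ln_alpha", "k_span", "sse",
                           "converged", "intensity_obs", "omax_obs",
                           "pmax_obs")]
  out$n_prices <- nrow(object$obs)
  class(out) <- "summary.demand_fit"
  out
}

#' @export
print.summary.demand_fit <- function(x, ...) {
  cat("Exponentiated demand fit on", x$n_prices, "prices\n")
  cat(sprintf("  Q0 = %.5g, alpha = %.5g (ln alpha = %.4f), span = %.4g\n",
              x$Q0, x$alpha, x$ln_alpha, x$k_span))
  cat(sprintf("  SSE = %.4g, converged: %s\n", x$sse, x$converged))
  cat(sprintf("  observed: intensity = %g, Omax = %g, Pmax = %g\n",
              x$intensity_obs, x$omax_obs, x$pmax_obs))
  invisible(x)
}

#' @export
plot.demand_fit <- function(x, ...) {
  obs <- x$obs
  plot(obs$price, obs$quantity, xlab = "Price ($/drink)",
       ylab = "Drinks purchased", main = "Alcohol purchase task", ...)
  if (x$converged) {
    cc <- seq(0, max(obs$price), length.out = 400)
    graphics::lines(cc, exponentiated_demand(cc, x$Q0, x$alpha, x$k_span))
  }
  invisible(x)
}

#' Fitted Pmax: unit-elasticity price of the fitted curve
#'
#' The price at which the fitted demand curve's expenditure
#' `E(C) = C * Qhat(C)` peaks, i.e. where the point elasticity of demand
#' is -1. Because the exponentiated curve has a nonzero floor
#' `Q0 * 10^(-k)`, expenditure eventually rises again at extreme prices;
#' the local maximum is located numerically (grid scan plus golden-section
#' refinement) on `[0, upper]`, with `upper` defaulting to
#' `10 * pmax_obs + 1`.
#'
#' @param fit A converged [fit_exponentiated()] object.
#' @param upper Upper end of the search interval in $/drink.
#' @return Price in $/drink.
#' @export
fitted_pmax <- function(fit, upper = NULL) {
  stopifnot(inherits(fit, "demand_fit"))
  if (!fit$converged)
    stop("fitted Pmax is unavailable: the demand fit did not converge")
  if (is.null(upper)) upper <- 10 * fit$pmax_obs + 1
  expend <- function(C) C * exponentiated_demand(C, fit$Q0, fit$alpha,
                                                 fit$k_span)
  # unit elasticity of expenditure: k ln10 * (alpha Q0) * C * e^(-alpha Q0 C) = 1,
  # whose smaller root (the peak before the floor branch) lies in (0, 1/(alpha Q0)]
  b <- fit$alpha * fit$Q0
  if (fit$k_span * log(10) / exp(1) > 1) {
    g <- function(C) fit$k_span * log(10) * b * C * exp(-b * C) - 1
    root <- stats::uniroot(g, c(1e-12 / b, 1 / b), tol = 1e-12)$root
    if (root <= upper) return(root)
  }
  # no interior unit-elasticity point in range: fall back to the argmax
  grid <- seq(0, upper, length.out = 4001L)
  e <- expend(grid)
  i <- which.max(e)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(expend, c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (opt$objective >= e[i]) opt$maximum else grid[i]
}
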