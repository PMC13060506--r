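#' Adjusting-amount titration schedule
#'
#' Describes the delay-discounting task: a fixed larger-later (LL) amount,
#' a set of delays, and the number of binary-choice trials per delay. The
#' default schedule is the seven-delay, six-trial task with a constant
#' $1000 larger-later amount; named calendar delays are converted to days
#' as 2 weeks = 14, 1 month = 30, 3 months = 90, 1 year = 365,
#' 5 years = 1825 and 25 years = 9125.
#'
#' @param A Larger-later amount in dollars (default 1000).
#' @param delays Strictly increasing positive delays in days.
#' @param trials_per_delay Number of titration trials per delay (default 6).
#' @return An object of class `titration_schedule`.
#' @examples
#' titration_schedule()
#' @export
titration_schedule <- function(A = 1000,
                               delays = c(1, 14, 30, 90, 365, 1825, 9125),
                               trials_per_delay = 6) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("'A' must be a single positive amount")
  if (!is.numeric(delays) || length(delays) < 1L || any(!is.finite(delays)) ||
      any(delays <= 0) || is.unsorted(delays, strictly = TRUE))
    stop("'delays' must be strictly increasing and positive")
  if (trials_per_delay < 1L || trials_per_delay != round(trials_per_delay))
    stop("'trials_per_delay' must be a positive integer")
  structure(list(A = A, delays = as.numeric(delays),
                 trials_per_delay = as.integer(trials_per_delay)),
            class = "titration_schedule")
}

#' @export
print.titration_schedule <- function(x, ...) {
  cat("Adjusting-amount titration schedule\n")
  cat("  LL amount: $", format(x$A), "; trials/delay: ", x$trials_per_delay,
      "\n  delays (days): ", paste(x$delays, collapse = ", "), "\n", sep = "")
  cat("  resolution: $", format(titration_resolution(x)), "\n", sep = "")
  invisible(x)
}

#' Titration resolution
#'
#' Smallest distinguishable difference in the indifference point:
#' `A / 2^(trials_per_delay + 1)` (e.g. $7.8125 for the default task).
#'
#' @param schedule A [titration_schedule()].
#' @return Resolution in dollars.
#' @export
titration_resolution <- function(schedule) {
  schedule$A / 2^(schedule$trials_per_delay + 1)
}

#' Run the adjusting-amount task against a chooser
#'
#' Presents binary choices between a smaller-sooner (SS) amount now and the
#' schedule's larger-later amount at each delay. Trial 1 presents SS = A/2;
#' after each choice the SS amount moves down (SS chosen) or up (LL chosen)
#' by `A / 2^(t + 1)` for trial `t`. The indifference point for a delay is
#' the SS amount that would have been presented on the trial after the last,
#' so the procedure is a binary search with resolution
#' `A / 2^(trials_per_delay + 1)`.
#'
#' @param chooser A function `(ss, ll, delay)` returning `"SS"` or `"LL"`,
#'   e.g. from [simulated_chooser()].
#' @param schedule A [titration_schedule()].
#' @param session Optional session identifier carried on the result.
#' @return An object of class `indifference_curve`: a data frame with
#'   columns `delay` and `indifference`, with the presented trials in
#'   `attr(, "trials")` (columns `delay_days`, `trial_index`, `ss_amount`,
#'   `choice`).
#' @examples
#' curve <- run_titration(function(ss, ll, d) "LL", titration_schedule())
#' curve$indifference[1]  # 992.1875
#' @export
run_titration <- function(chooser, schedule = titration_schedule(),
                          session = NA) {
  stopifnot(is.function(chooser), inherits(schedule, "titration_schedule"))
  A <- schedule$A
  n_tr <- schedule$trials_per_delay
  trials <- vector("list", length(schedule$delays))
  ip <- numeric(length(schedule$delays))
  for (i in seq_along(schedule$delays)) {
    d <- schedule$delays[i]
    ss <- A / 2
    rec <- data.frame(delay_days = rep(d, n_tr), trial_index = seq_len(n_tr),
                      ss_amount = NA_real_,
                      choice = character(n_tr))
    for (t in seq_len(n_tr)) {
      ch <- chooser(ss, A, d)
      if (!is.character(ch) || length(ch) != 1L || !ch %in% c("SS", "LL"))
        stop(sprintf(
          "chooser returned an invalid option at delay %g, trial %d", d, t))
      rec$ss_amount[t] <- ss
      rec$choice[t] <- ch
      step <- A / 2^(t + 1)
      ss <- ss + if (ch == "SS") -step else step
    }
    trials[[i]] <- rec
    ip[i] <- ss
  }
  indifference_curve(schedule$delays, ip, session = session,
                     trials = do.call(rbind, trials))
}

#' Indifference curve
#'
#' Per-delay indifference points from one administration of the
#' adjusting-amount task. Points must lie in `[0, A]`; this is checked
#' downstream against the fitting schedule.
#'
#' @param delay Delays in days.
#' @param indifference Indifference points in dollars, aligned to `delay`.
#' @param session Optional session identifier.
#' @param trials Optional trial-level record (kept as an attribute).
#' @return An object of class `indifference_curve` (a data frame).
#' @export
indifference_curve <- function(delay, indifference, session = NA,
                               trials = NULL) {
  if (length(delay) != length(indifference))
    stop("'delay' and 'indifference' must have equal length")
  if (any(!is.finite(delay)) || any(!is.finite(indifference)))
    stop("delays and indifference points must be finite")
  out <- data.frame(delay = as.numeric(delay),
                    indifference = as.numeric(indifference))
  out <- out[order(out$delay), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "session") <- session
  if (!is.null(trials)) attr(out, "trials") <- trials
  class(out) <- c("indifference_curve", "data.frame")
  out
}

#' Johnson-Bickel systematicity screen
#'
#' Flags nonsystematic indifference-point series. Criterion 1 fails if any
#' indifference point exceeds the point at the immediately preceding
#' (shorter) delay by more than `c1_prop * A` (default 20% of the
#' larger-later amount). Criterion 2 fails if the last point is not lower
#' than the first by at least `c2_prop * A` (default 10%). Data failing the
#' screen are flagged, never dropped.
#'
#' @param curve An [indifference_curve()] (or numeric vector of points in
#'   delay order).
#' @param A Larger-later amount in dollars.
#' @param c1_prop,c2_prop Screen thresholds as proportions of `A`.
#' @return A list with logical elements `criterion1_ok` and `criterion2_ok`.
#' @examples
#' johnson_bickel_screen(c(990, 900, 700, 500, 300, 150, 80), A = 1000)
#' @export
johnson_bickel_screen <- function(curve, A, c1_prop = 0.20, c2_prop = 0.10) {
  v <- if (inherits(curve, "indifference_curve")) curve$indifference
       else as.numeric(curve)
  if (length(v) < 2L) stop("at least 2 indifference points are required")
  if (any(!is.finite(v))) stop("indifference points must be finite")
  c1 <- all(diff(v) <= c1_prop * A)
  c2 <- (v[1L] - v[length(v)]) >= c2_prop * A
  list(criterion1_ok = c1, criterion2_ok = c2)
}

# Hyperbolic present value: V = A / (1 + k D)
hyperbolic_value <- function(A, k, D) A / (1 + k * D)

#' Fit the hyperbolic discounting model to an indifference curve
#'
#' Estimates the discount rate `k` of the hyperbolic model
#' `V = A / (1 + k * D)` by least squares on the indifference points,
#' searching `k` in log space over `[lower, upper]` (a coarse log-grid
#' scan followed by golden-section refinement, so the optimum cannot be
#' worse than the best grid point). Degenerate curves (all points at 0 or
#' at `A`) return a fit at the search bound with `boundary_flag` set,
#' never an error.
#'
#' @param curve An [indifference_curve()].
#' @param schedule The [titration_schedule()] the curve came from (supplies
#'   `A`); delays are taken from the curve.
#' @param lower,upper Search bounds for `k` in 1/days.
#' @param screen Apply [johnson_bickel_screen()] and carry the flags.
#' @return An object of class `discounting_fit` with elements `k`, `ln_k`,
#'   `sse`, `boundary_flag`, `systematic` (the screen flags), `fitted`,
#'   `residuals`, `curve` and `A`.
#' @examples
#' sch <- titration_schedule()
#' v <- hyperbolic_value(sch$A, 0.01, sch$delays)
#' fit <- fit_hyperbolic(indifference_curve(sch$delays, v), sch)
#' coef(fit)  # k = 0.01
#' @export
fit_hyperbolic <- function(curve, schedule = titration_schedule(),
                           lower = 1e-10, upper = 1e3, screen = TRUE) {
  stopifnot(inherits(curve, "indifference_curve"))
  A <- schedule$A
  D <- curve$delay
  V <- curve$indifference
  if (any(V < -1e-9) || any(V > A + 1e-9))
    stop("indifference points must lie in [0, A]")
  sse_of <- function(lnk) {
    r <- V - hyperbolic_value(A, exp(lnk), D)
    sum(r * r)
  }
  lo <- log(lower); hi <- log(upper)
  grid <- seq(lo, hi, length.out = 600L)
  g_sse <- vapply(grid, sse_of, numeric(1))
  i <- which.min(g_sse)
  bl <- grid[max(1L, i - 1L)]
  bu <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse_of, c(bl, bu), tol = 1e-12)
  # keep whichever of grid-best and refinement is better
  if (g_sse[i] < opt$objective) {
    lnk <- grid[i]; sse <- g_sse[i]
  } else {
    lnk <- opt$minimum; sse <- opt$objective
  }
  span <- hi - lo
  boundary <- (lnk - lo) < 1e-3 * span || (hi - lnk) < 1e-3 * span
  k <- exp(lnk)
  fitted <- hyperbolic_value(A, k, D)
  sys <- if (screen && length(V) >= 2L) johnson_bickel_screen(curve, A)
         else list(criterion1_ok = NA, criterion2_ok = NA)
  structure(list(k = k, ln_k = lnk, sse = sse, boundary_flag = boundary,
                 systematic = sys, fitted = fitted, residuals = V - fitted,
                 curve = curve, A = A, method = "least-squares on V",
                 call = match.call()),
            class = "discounting_fit")
}

#' @export
print.discounting_fit <- function(x, digits = 5, ...) {
  cat("Hyperbolic discounting fit: V = A / (1 + k D)\n")
  cat("  k =", format(x$k, digits = digits),
      " ln(k) =", format(x$ln_k, digits = digits),
      " SSE =", format(x$sse, digits = digits), "\n")
  if (x$boundary_flag) cat("  note: optimum at search boundary\n")
  if (!isTRUE(x$systematic$criterion1_ok) &&
      !is.na(x$systematic$criterion1_ok))
    cat("  flagged: Johnson-Bickel criterion 1 violated\n")
  if (!isTRUE(x$systematic$criterion2_ok) &&
      !is.na(x$systematic$criterion2_ok))
    cat("  flagged: Johnson-Bickel criterion 2 violated\n")
  invisible(x)
}

#' @export
coef.discounting_fit <- function(object, ...) c(k = object$k)

#' @export
residuals.discounting_fit <- function(object, ...) object$residuals

#' @rdname fit_hyperbolic
#' @param object,x A `discounting_fit`.
#' @param newdata Optional data frame with a `delay` column (days).
#' @param ... Unused.
#' @export
predict.discounting_fit <- function(object, newdata = NULL, ...) {
  D <- if (is.null(newdata)) object$curve$delay else newdata$delay
  hyperbolic_value(object$A, object$k, D)
}

#' @export
summary.discounting_fit <- function(object, ...) {
  out <- list(k = object$k, ln_k = object$ln_k, sse = object$sse,
              boundary_flag = object$boundary_flag,
              systematic = object$systematic,
              n_points = nrow(object$curve))
  class(out) <- "summary.discounting_fit"
  out
}

#' @export
print.summary.discounting_fit <- function(x, ...) {
  cat("Hyperbolic discounting fit on", x$n_points, "indifference points\n")
  cat(sprintf("  k = %.6g (ln k = %.4f), SSE = %.4g\n", x$k, x$ln_k, x$sse))
  cat(sprintf("  systematic: criterion1 %s, criterion2 %s; boundary: %s\n",
              x$systematic$criterion1_ok, x$systematic$criterion2_ok,
              x$boundary_flag))
  invisible(x)
}

#' @export
plot.discounting_fit <- function(x, ...) {
  D <- x$curve$delay
  plot(D, x$curve$indifference, log = "x", xlab = "Delay (days)",
       ylab = "Indifference point ($)", ylim = c(0, x$A),
       main = "Hyperbolic discounting", ...)
  dd <- exp(seq(log(min(D)), log(max(D)), length.out = 200))
  graphics::lines(dd, hyperbolic_value(x$A, x$k, dd))
  invisible(x)
}
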