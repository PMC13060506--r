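# Independent brute-force oracles used across the suite. These stay
# deliberately naive: enumeration and dense grids, no shared code with the
# implementation they check.

# Exact Fisher test by direct enumeration of the conditional
# (noncentral hypergeometric) distribution of the [1,1] cell.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  support <- lo:hi
  # two-sided p at OR = 1: tables as or less probable than observed
  probs <- stats::dhyper(support, m, n2, k)
  p <- sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
  # conditional MLE of the odds ratio
  or <- if (a == lo && a == hi) NA_real_
  else if (a == lo) 0
  else if (a == hi) Inf
  else {
    logw <- lchoose(m, support) + lchoose(n2, k - support)
    negll <- function(lpsi) {
      -(a * lpsi - matrixStats_logsumexp(logw + support * lpsi))
    }
    exp(stats::optimize(negll, c(-30, 30), tol = 1e-10)$minimum)
  }
  list(odds_ratio = or, p_value = p)
}

matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# AUC by counting ordered positive-negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Dense log-grid search for the hyperbolic discount rate.
oracle_hyperbolic_sse <- function(V, D, A, n_grid = 1e5) {
  lnk <- seq(log(1e-10), log(1e3), length.out = n_grid)
  sse <- vapply(lnk, function(l) sum((V - A / (1 + exp(l) * D))^2),
                numeric(1))
  list(ln_k = lnk[which.min(sse)], sse = min(sse))
}

# Dense 2-D grid search for the exponentiated demand parameters.
oracle_demand_sse <- function(C, Q, k_span, q0_range, alpha_range,
                              n_grid = 220) {
  q0s <- exp(seq(log(q0_range[1]), log(q0_range[2]), length.out = n_grid))
  als <- exp(seq(log(alpha_range[1]), log(alpha_range[2]),
                 length.out = n_grid))
  best <- list(sse = Inf)
  for (q0 in q0s) {
    pred0 <- 10^(k_span * (exp(-als %o% (q0 * C)) - 1)) * q0
    sse <- rowSums((matrix(Q, n_grid, length(C), byrow = TRUE) - pred0)^2)
    i <- which.min(sse)
    if (sse[i] < best$sse) best <- list(Q0 = q0, alpha = als[i],
                                        sse = sse[i])
  }
  best
}

# Coarse grid maximization of the 1-predictor logistic likelihood.
oracle_logistic_grid <- function(y, x, b0 = seq(-4, 4, by = 0.02),
                                 b1 = seq(-4, 4, by = 0.02)) {
  best <- list(ll = -Inf)
  ymat <- NULL
  for (a in b0) {
    p <- stats::plogis(outer(b1, x) + a)
    if (is.null(ymat)) ymat <- matrix(y, length(b1), length(y),
                                      byrow = TRUE)
    ll <- rowSums(log(ifelse(ymat == 1, p, 1 - p)))
    i <- which.max(ll)
    if (ll[i] > best$ll) best <- list(b0 = a, b1 = b1[i], ll = ll[i])
  }
  best
}

# Small synthetic daily table with known BrAC/report structure.
make_daily <- function(participant, drinks, brac, phase = "baseline") {
  n <- length(drinks)
  data.frame(participant = participant, day_index = seq_len(n),
             phase = phase, reported_drinks = drinks,
             brac_1 = brac, brac_2 = NA_real_, brac_3 = NA_real_)
}
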