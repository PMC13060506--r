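#' Covariate-adaptive allocation state
#'
#' Holds the rosters of already-allocated participants with the two
#' balancing covariates — square-root-transformed baseline drinks/day and
#' baseline ln(k) — plus the biased-coin parameters.
#'
#' @param bias_probability Probability of assigning to the
#'   imbalance-minimizing group (in `[0.5, 1]`; default 0.8).
#' @param lambda Weight on the group-size difference in the imbalance
#'   score (default 0.5).
#' @param covariates Names of the balancing covariate columns.
#' @return An object of class `allocation_state`.
#' @export
allocation_state <- function(bias_probability = 0.8, lambda = 0.5,
                             covariates = c("sqrt_drinks_per_day", "ln_k")) {
  if (bias_probability < 0.5 || bias_probability > 1)
    stop("'bias_probability' must lie in [0.5, 1]")
  roster <- data.frame(id = character(0), group = character(0))
  for (v in covariates) roster[[v]] <- numeric(0)
  structure(list(roster = roster, bias_probability = bias_probability,
                 lambda = lambda, covariates = covariates),
            class = "allocation_state")
}

#' @export
print.allocation_state <- function(x, ...) {
  n <- table(factor(x$roster$group, levels = c("EFT", "CET")))
  cat("Minimization allocation state: EFT", n[["EFT"]], "/ CET", n[["CET"]],
      "\n  bias", x$bias_probability, ", lambda", x$lambda,
      ", covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# Imbalance score for a hypothetical roster: sum over covariates of the
# absolute EFT-CET mean difference standardized by the pooled SD of all
# allocated participants (covariate skipped while the SD is undefined or
# zero, or while a group is empty), plus lambda * |n_EFT - n_CET|.
imbalance_score <- function(roster, covariates, lambda) {
  g <- roster$group
  nE <- sum(g == "EFT"); nC <- sum(g == "CET")
  score <- lambda * abs(nE - nC)
  if (nE > 0 && nC > 0) {
    for (v in covariates) {
      s <- stats::sd(roster[[v]])
      if (is.na(s) || s == 0) next
      score <- score +
        abs(mean(roster[[v]][g == "EFT"]) - mean(roster[[v]][g == "CET"])) / s
    }
  }
  score
}

#' Allocate one candidate by minimization
#'
#' Computes the imbalance score for each hypothetical assignment of the
#' candidate and assigns to the score-minimizing group with probability
#' `bias_probability` (the other group otherwise); exact ties are settled
#' by a fair coin. Draws come from the session RNG stream, so seed the
#' stream (or use [allocate_sequence()]) for reproducible allocation.
#'
#' @param state An [allocation_state()].
#' @param id Candidate identifier (must not already be allocated).
#' @param covariates Named numeric vector of the candidate's balancing
#'   covariates (names matching `state$covariates`).
#' @return A list with `group`, the updated `state`, `imbalance_before`
#'   and `imbalance_after`.
#' @export
allocate <- function(state, id, covariates) {
  stopifnot(inherits(state, "allocation_state"))
  if (id %in% state$roster$id) stop("candidate is already allocated")
  vals <- covariates[state$covariates]
  if (any(!is.finite(vals)))
    stop("candidate covariates must be finite")
  before <- imbalance_score(state$roster, state$covariates, state$lambda)
  cand <- data.frame(id = as.character(id), group = NA_character_)
  for (v in state$covariates) cand[[v]] <- unname(vals[v])
  score <- vapply(c("EFT", "CET"), function(g) {
    cand$group <- g
    imbalance_score(rbind(state$roster, cand), state$covariates,
                    state$lambda)
  }, numeric(1))
  if (score[["EFT"]] == score[["CET"]]) {
    grp <- if (stats::runif(1) < 0.5) "EFT" else "CET"
  } else {
    preferred <- names(score)[which.min(score)]
    other <- setdiff(c("EFT", "CET"), preferred)
    grp <- if (stats::runif(1) < state$bias_probability) preferred else other
  }
  cand$group <- grp
  state$roster <- rbind(state$roster, cand)
  list(group = grp, state = state, imbalance_before = before,
       imbalance_after = score[[grp]])
}

#' Allocate a sequence of candidates
#'
#' Seeds the RNG once and runs [allocate()] over the rows of a candidate
#' table, reproducing a full trial allocation.
#'
#' @param candidates Data frame with an `id` column and the balancing
#'   covariate columns.
#' @param bias_probability,lambda See [allocation_state()].
#' @param covariates Balancing covariate column names.
#' @param seed Integer seed for the allocation stream.
#' @return A data frame `(participant, group, imbalance_before,
#'   imbalance_after)` with the final state in `attr(, "state")`.
#' @examples
#' cand <- data.frame(id = paste0("p", 1:8),
#'                    sqrt_drinks_per_day = sqrt(c(5, 6, 4, 7, 5, 6, 5, 4)),
#'                    ln_k = c(-5, -4, -6, -5, -3, -7, -5, -4))
#' allocate_sequence(cand, seed = 1)
#' @export
allocate_sequence <- function(candidates, bias_probability = 0.8,
                              lambda = 0.5,
                              covariates = c("sqrt_drinks_per_day", "ln_k"),
                              seed = 1L) {
  state <- allocation_state(bias_probability, lambda, covariates)
  set.seed(as.integer(seed))
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cv <- unlist(candidates[i, covariates, drop = FALSE])
    names(cv) <- covariates
    res <- allocate(state, candidates$id[i], cv)
    state <- res$state
    out[[i]] <- data.frame(participant = as.character(candidates$id[i]),
                           group = res$group,
                           imbalance_before = res$imbalance_before,
                           imbalance_after = res$imbalance_after)
  }
  out <- do.call(rbind, out)
  attr(out, "state") <- state
  out
}
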