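#' Enumerate the candidate model space
#'
#' All subsets of the main effects crossed with every hierarchy-respecting
#' subset of the interaction terms (an interaction may enter only when both
#' of its main effects are present), including the intercept-only model.
#' Ordering is deterministic: by number of terms, then lexicographic.
#'
#' @param mains Character vector of main-effect names.
#' @param interactions Character vector of interaction terms written as
#'   `"a:b"`, each component of which must appear in `mains`.
#' @return A list of character vectors of terms; the first element is
#'   `character(0)` (intercept-only).
#' @examples
#' enumerate_models(c("A", "B"), "A:B")  # 5 models
#' @export
enumerate_models <- function(mains, interactions = character(0)) {
  stopifnot(is.character(mains), !anyDuplicated(mains))
  parts <- strsplit(interactions, ":", fixed = TRUE)
  for (p in parts) {
    if (length(p) != 2L || !all(p %in% mains))
      stop("interaction terms must be 'a:b' with both main effects ",
           "in the model space")
  }
  models <- list()
  m <- length(mains)
  for (bits in 0:(2^m - 1)) {
    keep <- mains[bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0]
    ok_int <- interactions[vapply(parts, function(p) all(p %in% keep),
                                  logical(1))]
    ni <- length(ok_int)
    for (ibits in 0:(2^ni - 1)) {
      ints <- if (ni) ok_int[bitwAnd(ibits, 2^(seq_len(ni) - 1L)) > 0]
              else character(0)
      models[[length(models) + 1L]] <- c(keep, ints)
    }
  }
  ord <- order(lengths(models),
               vapply(models, function(x) paste(x, collapse = " "),
                      character(1)))
  models[ord]
}

#' Exhaustive BIC selection of logistic adherence models
#'
#' Fits every candidate model by maximum-likelihood logistic regression
#' (`stats::glm`, IRLS) for a binary submitted/missing outcome and ranks
#' models by `BIC = -2 loglik + p log(n)` (parameter count `p` includes
#' the intercept; categorical predictors are dummy-coded against their
#' first level). Models that fail to converge, or show complete
#' separation, are flagged and excluded from the ranking with a warning.
#' The optimal model is the one with the lowest BIC.
#'
#' @param data Data frame containing the outcome and predictors.
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param mains,interactions Passed to [enumerate_models()].
#' @return An object of class `bic_selection`: a list with `table` (one
#'   row per converged model: `model`, `n_terms`, `loglik`, `params`,
#'   `bic`, ascending in BIC), `best` (terms of the lowest-BIC model),
#'   `n`, and `excluded` (formulas of nonconverged models).
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.3), g = gl(2, 100))
#' select_by_bic(d, "y", mains = "g")
#' @export
select_by_bic <- function(data, outcome, mains,
                          interactions = character(0)) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  data$.y <- y
  n <- nrow(data)
  models <- enumerate_models(mains, interactions)
  rows <- vector("list", length(models))
  excluded <- character(0)
  for (i in seq_along(models)) {
    terms <- models[[i]]
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fml <- stats::as.formula(paste(".y ~", rhs))
    sep_warn <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        stats::glm(fml, family = stats::binomial(), data = data,
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w)))
            sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    # divergent coefficients mark (quasi-)complete separation even when
    # IRLS reports convergence
    if (is.null(fit) || !fit$converged || sep_warn ||
        anyNA(stats::coef(fit)) ||
        any(abs(stats::coef(fit)) > 20)) {
      excluded <- c(excluded, rhs)
      next
    }
    ll <- as.numeric(stats::logLik(fit))
    p <- length(stats::coef(fit))
    rows[[i]] <- data.frame(model = rhs, n_terms = length(terms),
                            loglik = ll, params = p,
                            bic = -2 * ll + p * log(n))
  }
  if (length(excluded))
    warning(length(excluded), " candidate model(s) did not converge and ",
            "were excluded")
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no candidate model converged")
  tab <- tab[order(tab$bic), , drop = FALSE]
  rownames(tab) <- NULL
  best_terms <- models[[match(tab$model[1L],
                              vapply(models, function(t)
                                if (length(t)) paste(t, collapse = " + ")
                                else "1", character(1)))]]
  structure(list(table = tab, best = best_terms, n = n,
                 excluded = excluded),
            class = "bic_selection")
}

#' @export
print.bic_selection <- function(x, max_rows = 10, ...) {
  cat("Exhaustive BIC model selection (logistic),", nrow(x$table),
      "converged models, n =", x$n, "\n")
  cat("Best model: ~",
      if (length(x$best)) paste(x$best, collapse = " + ") else "1", "\n")
  print(utils::head(x$table, max_rows))
  if (length(x$excluded))
    cat("Excluded (nonconverged):", length(x$excluded), "\n")
  invisible(x)
}
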