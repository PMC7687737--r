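# Two-stage variable selection, per estimation method:
#   1. univariate screen — keep candidates with robust Wald p < 0.1
#   2. best-subset choice by AIC (LR) or QIC (GEE/CWGEE), exhaustive for
#      small candidate sets, forward search otherwise
#   3. backward pruning — iteratively drop the least significant covariate
#      with p >= 0.05 and refit, until all retained covariates are
#      significant.

.fit_by_method <- function(table, covariates, method) {
  switch(method,
         LR = fit_logistic(table, covariates),
         GEE = fit_gee(table, covariates),
         CWGEE = fit_cwgee(table, covariates),
         stop("unknown method: ", method))
}

#' Univariate screening of candidate covariates
#'
#' Fits a one-covariate model (by the given method) for each candidate and
#' keeps those whose robust Wald p-value is below `alpha`. A candidate whose
#' fit fails or does not converge is reported as excluded with its reason,
#' never silently dropped.
#'
#' @param train Training discharge table.
#' @param candidates Covariate names to screen; default all covariates.
#' @param method `"LR"`, `"GEE"` or `"CWGEE"`.
#' @param alpha Screening significance level.
#' @return Character vector of selected covariates, in input order, with
#'   the full screen (`data.frame`: candidate, estimate, p-value, status)
#'   attached as attribute `"trace"`.
#' @export
univariate_screen <- function(train, candidates = NULL,
                              method = c("LR", "GEE", "CWGEE"),
                              alpha = 0.1) {
  method <- match.arg(method)
  train <- validate_discharge_table(train)
  if (is.null(candidates)) candidates <- covariate_names(train)
  miss <- setdiff(candidates, names(train))
  if (length(miss) > 0L) {
    stop("candidate(s) not in table: ", paste(miss, collapse = ", "))
  }
  rows <- lapply(candidates, function(v) {
    res <- tryCatch({
      fit <- .fit_by_method(train, v, method)
      wi <- wald_inference(fit)
      pv <- wi$p_value[wi$term == v]
      status <- if (!fit$converged) "not converged"
      else if (isTRUE(fit$separated)) "separated"
      else "ok"
      data.frame(candidate = v, estimate = wi$estimate[wi$term == v],
                 p_value = pv, status = status)
    }, error = function(e) {
      data.frame(candidate = v, estimate = NA_real_, p_value = NA_real_,
                 status = paste("error:", conditionMessage(e)))
    })
    res
  })
  trace <- do.call(rbind, rows)
  trace$selected <- trace$status == "ok" & !is.na(trace$p_value) &
    trace$p_value < alpha
  selected <- trace$candidate[trace$selected]
  attr(selected, "trace") <- trace
  selected
}

.subset_key <- function(vars) paste(sort(vars), collapse = "+")

# All non-empty subsets of `vars`, ordered by size then lexically — a fixed
# enumeration order makes the criterion tie-break deterministic.
.enumerate_subsets <- function(vars) {
  out <- list()
  for (k in seq_along(vars)) {
    cmb <- combn(vars, k, simplify = FALSE)
    keys <- vapply(cmb, .subset_key, character(1))
    out <- c(out, cmb[order(keys)])
  }
  out
}

.try_criterion <- function(train, vars, method) {
  tryCatch({
    fit <- suppressWarnings(.fit_by_method(train, vars, method))
    if (!fit$converged) return(list(crit = Inf, fit = NULL,
                                    note = "not converged"))
    list(crit = model_criterion(fit), fit = fit, note = "ok")
  }, error = function(e) list(crit = Inf, fit = NULL,
                              note = conditionMessage(e)))
}

#' Best-subset selection with backward pruning
#'
#' Among candidate subsets of the screened covariates, chooses the one
#' minimizing AIC (LR) or QIC (GEE/CWGEE) — exhaustively when the screened
#' count is at most `exhaustive_limit`, by forward search under the same
#' criterion otherwise. The chosen model is then pruned: while any retained
#' covariate has robust Wald p >= `alpha`, the least significant one is
#' removed (ties broken by smaller |z| removed first, then reverse lexical
#' name order) and the model refit. Rank-deficient subsets (e.g. containing
#' collinear covariates) are infeasible and skipped with a note, so of two
#' perfectly collinear covariates exactly one can be retained.
#'
#' @param train Training discharge table.
#' @param screened Covariates that passed [univariate_screen()].
#' @param method `"LR"`, `"GEE"` or `"CWGEE"`.
#' @param alpha Retention significance level for the pruning stage.
#' @param exhaustive_limit Largest screened count for which all `2^p - 1`
#'   non-empty subsets are enumerated.
#' @return A list of class `subset_selection`: `spec` (the final
#'   [model_spec()]), `fit` (the final `readmit_fit`; intercept-only models
#'   are allowed and flagged via `empty`), `criterion`, and `trace` (subset
#'   criteria and pruning steps).
#' @export
best_subset_select <- function(train, screened,
                               method = c("LR", "GEE", "CWGEE"),
                               alpha = 0.05, exhaustive_limit = 15L) {
  method <- match.arg(method)
  train <- validate_discharge_table(train)
  if (length(screened) == 0L) stop("screened covariate list is empty")
  trace <- list()

  if (length(screened) <= exhaustive_limit) {
    subsets <- .enumerate_subsets(screened)
    crits <- vapply(subsets, function(s) .try_criterion(train, s, method)$crit,
                    numeric(1))
    trace$subsets <- data.frame(
      subset = vapply(subsets, .subset_key, character(1)),
      size = lengths(subsets), criterion = crits)
    best_idx <- which.min(crits)          # first minimum: smallest, lexical
    if (!is.finite(crits[best_idx])) stop("no feasible subset")
    current <- subsets[[best_idx]]
  } else {
    current <- character()
    best_crit <- Inf
    repeat {
      remaining <- setdiff(screened, current)
      if (length(remaining) == 0L) break
      cand_crits <- vapply(sort(remaining), function(v) {
        .try_criterion(train, c(current, v), method)$crit
      }, numeric(1))
      if (min(cand_crits) >= best_crit) break
      pick <- names(cand_crits)[which.min(cand_crits)]
      current <- c(current, pick)
      best_crit <- min(cand_crits)
      trace$forward <- rbind(trace$forward,
                             data.frame(added = pick, criterion = best_crit))
    }
    if (length(current) == 0L) {
      # forward search never improved on nothing; fall back to the single
      # best one-covariate model
      singles <- vapply(sort(screened), function(v) {
        .try_criterion(train, v, method)$crit
      }, numeric(1))
      current <- names(singles)[which.min(singles)]
    }
    current <- intersect(screened, current)  # restore input order
  }

  # Backward pruning at `alpha` on robust Wald p-values.
  prune_log <- NULL
  fit <- suppressWarnings(.fit_by_method(train, current, method))
  repeat {
    if (length(current) == 0L) break
    wi <- wald_inference(fit)
    wi <- wi[wi$term != "(Intercept)", , drop = FALSE]
    bad <- wi[wi$p_value >= alpha | is.na(wi$p_value), , drop = FALSE]
    if (nrow(bad) == 0L) break
    # drop the least significant: largest p, then smallest |z|, then
    # reverse lexical order, so the survivor of a tie is the lexically
    # first name
    ord <- order(-bad$p_value, abs(bad$z), -rank(bad$term))
    drop_var <- bad$term[ord[1L]]
    prune_log <- rbind(prune_log,
                       data.frame(dropped = drop_var,
                                  p_value = bad$p_value[ord[1L]]))
    current <- setdiff(current, drop_var)
    fit <- if (length(current) > 0L) {
      suppressWarnings(.fit_by_method(train, current, method))
    } else {
      suppressWarnings(.fit_intercept_only(train, method))
    }
  }
  trace$pruning <- prune_log

  empty <- length(current) == 0L
  if (empty) warning("all covariates pruned; returning intercept-only model")
  structure(list(spec = model_spec(method, current),
                 fit = fit, criterion = model_criterion(fit),
                 empty = empty, trace = trace),
            class = "subset_selection")
}

.fit_intercept_only <- function(table, method) {
  switch(method,
         LR = fit_logistic(table, character()),
         GEE = fit_gee(table, character()),
         CWGEE = fit_cwgee(table, character()))
}
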