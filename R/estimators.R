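# Marginal-model estimators for clustered binary outcomes:
#   LR    — ordinary logistic regression (independence), IRLS
#   GEE   — generalized estimating equations, exchangeable working
#           correlation, Fisher scoring with a moment update for rho
#   CWGEE — GEE with whole-cluster weights 1/n_i, valid when cluster size
#           is informative
# All three report a cluster-robust sandwich covariance. The exchangeable
# inverse R^{-1} = [I - rho/(1 + (n_i-1) rho) J] / (1 - rho) is applied in
# closed form, so every pass over the data is a grouped vector operation —
# no per-cluster matrix inversions.

#' Specification of one readmission model
#'
#' @param method One of `"LR"`, `"GEE"`, `"CWGEE"`.
#' @param covariates Character vector of covariate column names.
#' @param correlation Working correlation structure; `"independence"` or
#'   `"exchangeable"`. LR implies independence.
#' @return A `model_spec` list.
#' @export
model_spec <- function(method = c("LR", "GEE", "CWGEE"),
                       covariates = character(),
                       correlation = NULL) {
  method <- match.arg(method)
  if (is.null(correlation)) {
    correlation <- if (method == "LR") "independence" else "exchangeable"
  }
  correlation <- match.arg(correlation, c("independence", "exchangeable"))
  if (method == "LR" && correlation != "independence") {
    stop("LR implies an independence structure")
  }
  structure(list(method = method, covariates = as.character(covariates),
                 correlation = correlation),
            class = "model_spec")
}

.design_matrix <- function(table, covariates) {
  miss <- setdiff(covariates, names(table))
  if (length(miss) > 0L) {
    stop("covariate(s) not in table: ", paste(miss, collapse = ", "))
  }
  X <- cbind("(Intercept)" = 1,
             as.matrix(as.data.frame(table)[, covariates, drop = FALSE]))
  if (length(covariates) > 0L) colnames(X) <- c("(Intercept)", covariates)
  storage.mode(X) <- "double"
  X
}

.check_rank <- function(X) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
}

.MU_EPS <- 1e-10

# Independence IRLS for the logistic model, with optional per-row weights.
.irls_logistic <- function(y, X, w, tol = 1e-10, maxit = 50L) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / v
    wv <- w * v
    beta_new <- drop(solve(crossprod(X, wv * X), crossprod(X, wv * z)))
    if (max(abs(beta_new - beta)) < tol) {
      return(list(beta = beta_new, iterations = it, converged = TRUE))
    }
    beta <- beta_new
  }
  list(beta = beta, iterations = maxit, converged = FALSE)
}

# Moment update for the exchangeable correlation, following the standard
# convention (Pearson residuals, dispersion estimated with N - p degrees of
# freedom, pair count reduced by p), so estimates agree with general-purpose
# GEE software.
.rho_update <- function(e, cl, f_cluster, p) {
  n_i <- tabulate(cl)
  f <- f_cluster
  ssr_i <- drop(rowsum(e^2, cl, reorder = FALSE))
  S_i <- drop(rowsum(e, cl, reorder = FALSE))
  nobs <- length(e)
  fsum1 <- sum(f * n_i)
  scale <- sum(f * ssr_i) / (fsum1 * (nobs - p) / nobs)
  pairs_i <- n_i * (n_i - 1) / 2
  n_pairs <- sum(pairs_i)
  if (n_pairs <= 0) return(list(rho = 0, scale = scale))
  fsum2 <- sum(f * pairs_i)
  num <- sum(f * (S_i^2 - ssr_i) / 2) / scale
  den <- fsum2 * (n_pairs - p) / n_pairs
  if (den <= 0) den <- fsum2   # tiny-sample fallback
  list(rho = num / den, scale = scale)
}

# Core solver for all three estimators. `cluster_weights` is one positive
# weight per cluster, applied as a whole-cluster multiplier of the
# estimating-function contribution (and consistently in bread and meat).
.gee_engine <- function(y, X, cluster, cluster_weights = NULL,
                        correlation = c("independence", "exchangeable"),
                        tol = 1e-8, maxit = 100L) {
  correlation <- match.arg(correlation)
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes")
  }
  .check_rank(X)
  uid <- unique(cluster)
  cli <- match(cluster, uid)
  n_clusters <- length(uid)
  n_i <- tabulate(cli, nbins = n_clusters)
  p <- ncol(X)
  if (is.null(cluster_weights)) cluster_weights <- rep(1, n_clusters)
  if (length(cluster_weights) == 1L) {
    cluster_weights <- rep(cluster_weights, n_clusters)
  }
  stopifnot(length(cluster_weights) == n_clusters, all(cluster_weights > 0))
  w_row <- cluster_weights[cli]

  init <- .irls_logistic(y, X, w_row)
  beta <- init$beta
  rho <- 0
  scale <- 1
  converged <- init$converged
  iterations <- init$iterations
  rho_clamped <- FALSE
  # Positive-definiteness bound for the exchangeable matrix.
  rho_lo <- if (max(n_i) > 1L) -1 / (max(n_i) - 1) + 1e-6 else 0
  rho_hi <- 0.99

  if (correlation == "exchangeable" && max(n_i) > 1L) {
    converged <- FALSE
    for (it in seq_len(maxit)) {
      eta <- drop(X %*% beta)
      mu <- plogis(eta)
      s <- sqrt(pmax(mu * (1 - mu), 1e-12))
      e <- (y - mu) / s
      upd <- .rho_update(e, cli, cluster_weights, p)
      scale <- upd$scale
      rho <- upd$rho
      rho_clamped <- rho < rho_lo || rho > rho_hi   # final-iteration status
      if (rho_clamped) rho <- min(max(rho, rho_lo), rho_hi)
      c_i <- rho / (1 + (n_i - 1) * rho)
      Z <- X * s
      U <- rowsum(Z, cli, reorder = FALSE)                       # cluster column sums of Z
      Se <- drop(rowsum(e, cli, reorder = FALSE))
      Ze <- rowsum(Z * e, cli, reorder = FALSE)
      G <- (Ze - (c_i * Se) * U) * (cluster_weights / (1 - rho))
      score <- colSums(G)
      H <- (crossprod(Z * sqrt(w_row)) -
              crossprod(U, U * (cluster_weights * c_i))) / (1 - rho)
      delta <- drop(solve(H, score))
      # trust-region-style damping: a huge proposed step signals an
      # ill-conditioned working correlation, not a distant optimum
      if (max(abs(delta)) > 2) delta <- delta * (2 / max(abs(delta)))
      beta <- beta + delta
      if (max(abs(delta)) < tol) {
        converged <- TRUE
        iterations <- it
        break
      }
      iterations <- it
    }
    if (rho_clamped) {
      warning("working correlation estimate clamped to [",
              signif(rho_lo, 3), ", ", rho_hi, "]")
    }
  }

  # Final quantities at beta-hat.
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  s <- sqrt(pmax(mu * (1 - mu), 1e-12))
  e <- (y - mu) / s
  c_i <- if (correlation == "exchangeable") {
    rho / (1 + (n_i - 1) * rho)
  } else rep(0, n_clusters)
  Z <- X * s
  U <- rowsum(Z, cli, reorder = FALSE)
  Se <- drop(rowsum(e, cli, reorder = FALSE))
  Ze <- rowsum(Z * e, cli, reorder = FALSE)
  G <- (Ze - (c_i * Se) * U) * (cluster_weights / (1 - rho))
  H <- (crossprod(Z * sqrt(w_row)) -
          crossprod(U, U * (cluster_weights * c_i))) / (1 - rho)
  bread <- solve(H)
  meat <- crossprod(G)
  robust <- bread %*% meat %*% bread
  robust <- (robust + t(robust)) / 2
  if (correlation == "independence") {
    # Pearson dispersion, for the GEE-style naive covariance
    scale <- sum(w_row * e^2) / (sum(w_row * 1) * (length(y) - p) / length(y))
  }
  naive <- bread * scale
  separated <- max(abs(eta)) > 30 || max(abs(beta)) > 1e3
  if (separated) {
    warning("possible separation: fitted probabilities at machine bounds")
  }

  mu_c <- pmin(pmax(mu, .MU_EPS), 1 - .MU_EPS)
  quasi_loglik <- sum(w_row * (y * log(mu_c) + (1 - y) * log(1 - mu_c)))
  info_ind <- crossprod(Z * sqrt(w_row))       # independence information
  qic <- -2 * quasi_loglik + 2 * sum(diag(info_ind %*% robust))

  dimnames(robust) <- dimnames(naive) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(beta, colnames(X)),
       robust_covariance = robust, naive_covariance = naive,
       working_correlation = rho, scale = scale,
       cluster_weights = setNames(cluster_weights, uid),
       converged = converged, n_iterations = iterations,
       separated = separated, quasi_loglik = quasi_loglik, qic = qic,
       n_obs = length(y), n_clusters = n_clusters)
}

.finish_fit <- function(engine, method, correlation, covariates) {
  fit <- engine
  fit$method <- method
  fit$correlation <- correlation
  fit$covariates <- covariates
  fit$intercept <- unname(fit$coefficients[1L])
  k <- length(fit$coefficients)
  fit$aic <- -2 * fit$quasi_loglik + 2 * k
  class(fit) <- "readmit_fit"
  fit
}

#' Fit an ordinary logistic regression
#'
#' Maximizes the Bernoulli likelihood by iteratively reweighted least
#' squares. Reports both the naive (inverse-information, with Pearson
#' dispersion) and the cluster-robust sandwich covariance; clusters are
#' defined by `patient_id`, so on an all-discharges table the robust SEs
#' account for repeated discharges even though the point estimates do not.
#'
#' @param table A discharge table.
#' @param covariates Covariate names; default all covariate columns.
#' @return A `readmit_fit`.
#' @export
fit_logistic <- function(table, covariates = NULL) {
  table <- validate_discharge_table(table)
  if (is.null(covariates)) covariates <- covariate_names(table)
  X <- .design_matrix(table, covariates)
  eng <- .gee_engine(table$outcome, X, table$patient_id,
                     correlation = "independence")
  .finish_fit(eng, "LR", "independence", covariates)
}

#' Fit a GEE logistic regression
#'
#' Solves the generalized estimating equations
#' \eqn{\sum_i w_i D_i^\top V_i^{-1} (Y_i - \mu_i) = 0} with a logit mean
#' and (by default) an exchangeable working correlation whose parameter
#' \eqn{\rho} is re-estimated at each outer iteration by a moment estimator
#' on Pearson residuals. The iteration starts from the independence
#' (logistic) solution and stops when the largest coefficient update falls
#' below `1e-8` (at most 100 iterations; non-convergence is flagged, not
#' hidden). The sandwich covariance applies the cluster weights in both
#' bread and meat.
#'
#' @param table A discharge table; clusters are patients.
#' @param covariates Covariate names; default all covariate columns.
#' @param weights Per-cluster positive weights, one per patient (in the
#'   order of first appearance) or a single value; default 1.
#' @param correlation `"exchangeable"` (default) or `"independence"`.
#' @return A `readmit_fit`.
#' @export
fit_gee <- function(table, covariates = NULL, weights = NULL,
                    correlation = "exchangeable") {
  table <- validate_discharge_table(table)
  if (is.null(covariates)) covariates <- covariate_names(table)
  X <- .design_matrix(table, covariates)
  eng <- .gee_engine(table$outcome, X, table$patient_id,
                     cluster_weights = weights, correlation = correlation)
  .finish_fit(eng, "GEE", correlation, covariates)
}

#' Fit a cluster-weighted GEE logistic regression
#'
#' Identical machinery to [fit_gee()] with whole-cluster weights
#' \eqn{w_i = 1/n_i}. Under informative cluster size — when the outcome
#' distribution within a cluster depends on the cluster's size — CWGEE
#' targets the per-patient (rather than per-discharge) marginal model,
#' which unweighted GEE does not.
#'
#' @inheritParams fit_gee
#' @return A `readmit_fit` with the `1/n_i` weights recorded.
#' @export
fit_cwgee <- function(table, covariates = NULL,
                      correlation = "exchangeable") {
  table <- validate_discharge_table(table)
  if (is.null(covariates)) covariates <- covariate_names(table)
  sizes <- rle(as.character(table$patient_id))$lengths
  X <- .design_matrix(table, covariates)
  eng <- .gee_engine(table$outcome, X, table$patient_id,
                     cluster_weights = 1 / sizes, correlation = correlation)
  .finish_fit(eng, "CWGEE", correlation, covariates)
}

#' Fit a model described by a [model_spec()]
#'
#' @param table A discharge table.
#' @param spec A `model_spec`.
#' @param ... Passed to the underlying fitter.
#' @return A `readmit_fit`.
#' @export
fit_model <- function(table, spec, ...) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$method,
         LR = fit_logistic(table, spec$covariates, ...),
         GEE = fit_gee(table, spec$covariates,
                       correlation = spec$correlation, ...),
         CWGEE = fit_cwgee(table, spec$covariates,
                           correlation = spec$correlation, ...))
}

#' Predicted readmission probabilities
#'
#' \eqn{\hat p = \mathrm{expit}(\hat\alpha + \hat\beta^\top x)}, computed
#' overflow-safely and clamped to the open interval (0, 1).
#'
#' @param fit A `readmit_fit`.
#' @param newdata A discharge table / data frame containing the fit's
#'   covariate columns, or a numeric matrix (columns in covariate order),
#'   or a single numeric vector of covariate values.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, newdata) {
  stopifnot(inherits(fit, "readmit_fit"))
  k <- length(fit$covariates)
  if (is.data.frame(newdata)) {
    X <- .design_matrix(newdata, fit$covariates)
  } else {
    m <- if (is.matrix(newdata)) newdata else matrix(newdata, ncol = k)
    if (ncol(m) != k) stop("covariate dimension mismatch: expected ", k)
    X <- cbind(1, m)
  }
  eta <- drop(X %*% fit$coefficients)
  p <- plogis(eta)
  pmin(pmax(p, .MU_EPS), 1 - .MU_EPS)
}

#' Wald inference from the robust covariance
#'
#' @param fit A `readmit_fit`.
#' @return A data frame with one row per coefficient: estimate, robust SE,
#'   z statistic and two-sided normal p-value.
#' @export
wald_inference <- function(fit) {
  stopifnot(inherits(fit, "readmit_fit"))
  est <- fit$coefficients
  se <- sqrt(pmax(diag(fit$robust_covariance), 0))
  z <- ifelse(se > 0, est / se, NA_real_)
  data.frame(term = names(est), estimate = unname(est),
             robust_se = unname(se), z = unname(z),
             p_value = unname(2 * pnorm(-abs(z))),
             row.names = NULL)
}

#' Model-choice criterion: AIC for LR, QIC otherwise
#'
#' QIC pairs the independence quasi-likelihood with a penalty
#' \eqn{2\,\mathrm{tr}(\hat\Omega_I \hat V_r)} built from the independence
#' information and the robust covariance.
#'
#' @param fit A `readmit_fit`.
#' @return A single number; smaller is better.
#' @export
model_criterion <- function(fit) {
  stopifnot(inherits(fit, "readmit_fit"))
  if (fit$method == "LR") fit$aic else fit$qic
}

#' @export
print.readmit_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s working correlation), %d obs in %d clusters\n",
              x$method, x$correlation, x$n_obs, x$n_clusters))
  print(wald_inference(x), digits = 4)
  if (x$correlation == "exchangeable") {
    cat(sprintf("rho-hat = %.4f\n", x$working_correlation))
  }
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' Serialize a fit to a JSON report
#'
#' @param fit A `readmit_fit`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "readmit_fit"))
  rpt <- list(
    method = fit$method,
    correlation = fit$correlation,
    coefficients = as.list(fit$coefficients),
    robust_se = as.list(setNames(sqrt(diag(fit$robust_covariance)),
                                 names(fit$coefficients))),
    naive_se = as.list(setNames(sqrt(diag(fit$naive_covariance)),
                                names(fit$coefficients))),
    working_correlation = fit$working_correlation,
    cluster_weights = as.list(setNames(
      as.numeric(quantile(fit$cluster_weights, c(0, 0.5, 1))),
      c("min", "median", "max"))),
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    n_obs = fit$n_obs, n_clusters = fit$n_clusters)
  js <- jsonlite::toJSON(rpt, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
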