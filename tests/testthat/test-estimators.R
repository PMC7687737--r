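# Dense per-cluster oracle for the exchangeable estimating function and
# sandwich covariance: builds every V_i explicitly and inverts it, the slow
# way the fast grouped algebra is supposed to reproduce.
dense_gee_pieces <- function(tab, covariates, beta, rho, weights = NULL) {
  X <- cbind(1, as.matrix(as.data.frame(tab)[, covariates, drop = FALSE]))
  y <- tab$outcome
  ids <- unique(tab$patient_id)
  if (is.null(weights)) weights <- rep(1, length(ids))
  p <- ncol(X)
  score <- numeric(p)
  bread_inv <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (k in seq_along(ids)) {
    rows <- which(tab$patient_id == ids[k])
    Xi <- X[rows, , drop = FALSE]
    yi <- y[rows]
    mui <- plogis(drop(Xi %*% beta))
    Ai <- diag(mui * (1 - mui), nrow = length(rows))
    R <- matrix(rho, length(rows), length(rows)); diag(R) <- 1
    Vi <- sqrt(Ai) %*% R %*% sqrt(Ai)
    Di <- Ai %*% Xi
    gi <- weights[k] * t(Di) %*% solve(Vi, yi - mui)
    score <- score + gi
    meat <- meat + gi %*% t(gi)
    bread_inv <- bread_inv + weights[k] * t(Di) %*% solve(Vi, Di)
  }
  B <- solve(bread_inv)
  list(score = score, robust = B %*% meat %*% B)
}

test_that("logistic fit on a 2x2 table matches the closed-form log odds", {
  # x = 0: 10 events of 40; x = 1: 20 events of 40
  x <- rep(c(0, 1), each = 40)
  y <- c(rep(1, 10), rep(0, 30), rep(1, 20), rep(0, 20))
  tab <- toy_table(rep(1L, 80), outcomes = y, covariates = data.frame(x = x))
  fit <- fit_logistic(tab)
  expect_equal(unname(fit$coefficients[1]), log(10 / 30), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[2]),
               log((20 / 20) / (10 / 30)), tolerance = 1e-8)
  # saturated fitted value at x = 1 is the cell incidence 20/40
  expect_equal(predict_probability(fit, 1), 0.5, tolerance = 1e-8)
})

test_that("duplicating every row leaves point estimates unchanged", {
  tab <- small_cohort(150, seed = 12)
  fit1 <- fit_logistic(tab)
  dup <- strip_dt(tab)
  dup2 <- dup
  dup2$patient_id <- paste0(dup2$patient_id, "bis")
  both <- as_discharge_table(rbind(dup, dup2))
  fit2 <- fit_logistic(both)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
})

test_that("perfect separation is flagged, not silently returned", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- as.integer(x)
  tab <- toy_table(rep(1L, 40), outcomes = y, covariates = data.frame(x = x))
  expect_warning(fit <- fit_logistic(tab), "separation")
  expect_true(fit$separated)
})

test_that("rank deficiency errors name the collinear columns", {
  tab <- small_cohort(100, seed = 13)
  tab$xdup <- tab$xv1 * 2
  expect_error(fit_logistic(as_discharge_table(strip_dt(tab))), "collinear")
})

test_that("GEE collapses to logistic regression in the degenerate limits", {
  singles <- first_discharges(small_cohort(300, seed = 14))
  lr <- fit_logistic(singles)
  gee <- fit_gee(singles)
  expect_equal(gee$coefficients, lr$coefficients, tolerance = 1e-6)

  clustered <- small_cohort(300, seed = 14)
  lr2 <- fit_logistic(clustered)
  gee_ind <- fit_gee(clustered, correlation = "independence")
  expect_equal(gee_ind$coefficients, lr2$coefficients, tolerance = 1e-6)
})

test_that("CWGEE equals GEE for equal cluster sizes and LR for singletons", {
  cfg <- lean_config(250)
  tab <- generate_cohort(cfg, seed = 15)
  equal_sized <- as_discharge_table(
    strip_dt(tab)[tab$discharge_index <= 2 & tab$patient_id %in%
                    names(which(table(tab$patient_id) >= 2)), , drop = FALSE])
  gee <- fit_gee(equal_sized)
  cw <- fit_cwgee(equal_sized)
  expect_equal(cw$coefficients, gee$coefficients, tolerance = 1e-6)

  singles <- first_discharges(tab)
  expect_equal(fit_cwgee(singles)$coefficients,
               fit_logistic(singles)$coefficients, tolerance = 1e-6)
})

test_that("estimates are invariant to cluster order", {
  tab <- tame_cohort(300, seed = 16)
  ids <- unique(tab$patient_id)
  set.seed(1)
  remap <- setNames(sprintf("Q%07d", sample(seq_along(ids))), ids)
  perm <- strip_dt(tab)
  perm$patient_id <- unname(remap[perm$patient_id])
  perm <- as_discharge_table(perm)
  f1 <- fit_gee(tab)
  f2 <- fit_gee(perm)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$working_correlation, f2$working_correlation,
               tolerance = 1e-8)
})

test_that("the estimating function vanishes at the returned estimates", {
  tab <- generate_cohort(lean_config(120), seed = 17)
  sizes <- as.vector(table(factor(tab$patient_id,
                                  levels = unique(tab$patient_id))))
  covs <- covariate_names(tab)

  lr <- fit_logistic(tab)
  g0 <- dense_gee_pieces(tab, covs, lr$coefficients, 0)
  expect_lt(max(abs(g0$score)), 1e-5)

  gee <- fit_gee(tab)
  g1 <- dense_gee_pieces(tab, covs, gee$coefficients, gee$working_correlation)
  expect_lt(max(abs(g1$score)), 1e-5)
  # sandwich covariance agrees with the dense oracle
  expect_equal(unname(gee$robust_covariance), unname(g1$robust),
               tolerance = 1e-6)

  cw <- fit_cwgee(tab)
  g2 <- dense_gee_pieces(tab, covs, cw$coefficients, cw$working_correlation,
                         weights = 1 / sizes)
  expect_lt(max(abs(g2$score)), 1e-5)
  expect_equal(unname(cw$robust_covariance), unname(g2$robust),
               tolerance = 1e-6)
})

test_that("duplicating all clusters halves the sandwich covariance", {
  tab <- tame_cohort(300, seed = 18)
  plain <- strip_dt(tab)
  copy <- plain
  copy$patient_id <- paste0(copy$patient_id, "bis")
  doubled <- as_discharge_table(rbind(plain, copy))
  f1 <- fit_gee(tab)
  f2 <- fit_gee(doubled)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-3)
  expect_equal(unname(diag(f2$robust_covariance)),
               unname(diag(f1$robust_covariance)) / 2, tolerance = 0.02)
})

test_that("predicted probabilities are overflow-safe and correct at 0", {
  tab <- toy_table(rep(1L, 40),
                   outcomes = rep(c(0L, 1L), 20),
                   covariates = data.frame(x = rnorm(40)))
  fit <- fit_logistic(tab)
  fit$coefficients <- c("(Intercept)" = 0, x = 1)
  expect_equal(predict_probability(fit, 0), 0.5)
  p <- predict_probability(fit, 1e6)
  expect_true(p < 1 && p > 0.999)
  expect_true(predict_probability(fit, -1e6) > 0)
})

test_that("Wald inference follows the standard normal reference", {
  tab <- small_cohort(150, seed = 19)
  fit <- fit_gee(tab)
  wi <- wald_inference(fit)
  # self-consistency with the robust covariance
  expect_equal(wi$robust_se, unname(sqrt(diag(fit$robust_covariance))))
  expect_equal(wi$p_value, 2 * pnorm(-abs(wi$estimate / wi$robust_se)))
  # a zero estimate has p = 1; z = 1.96 sits at p ~ 0.05
  fit$coefficients[2] <- 0
  expect_equal(wald_inference(fit)$p_value[2], 1)
  fit$coefficients[3] <- 1.96 * sqrt(diag(fit$robust_covariance))[3]
  expect_equal(wald_inference(fit)$p_value[3], 0.05, tolerance = 1e-3)
})

test_that("outcome with a single class is rejected", {
  tab <- toy_table(rep(2L, 20), outcomes = rep(0L, 40),
                   covariates = data.frame(x = rnorm(40)))
  expect_error(fit_logistic(tab), "both classes")
})
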