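# A compact informative cohort reused across study tests.
study_cohort <- function(n = 700, seed = 61) {
  generate_cohort(generator_config(
    n_patients = n,
    covariate_effects = c(0.4, 0.2, 0.5, -0.3),
    n_constant_covariates = 2L, n_varying_covariates = 2L), seed = seed)
}

test_that("run_study records one value per grid cell, method and metric", {
  cohort <- study_cohort()
  cfg <- study_config(size_grid = c(200L, 400L), seed = 5)
  res <- run_study(cohort, cfg)
  expect_equal(nrow(res$records), 2L * 4L * 5L)
  expect_setequal(unique(res$records$method),
                  c("LR-first", "LR-all", "GEE", "CWGEE"))
  expect_equal(nrow(res$observed_rates), 2L)
})

test_that("the study is deterministic given its seed", {
  cohort <- study_cohort(400, seed = 62)
  cfg <- study_config(size_grid = c(150L, 300L), methods = c("LR-first", "LR-all"),
                      seed = 17)
  r1 <- run_study(cohort, cfg)
  r2 <- run_study(cohort, cfg)
  expect_identical(r1$records, r2$records)
})

test_that("the first-discharge frame shows the lower observed rate at every size", {
  cohort <- study_cohort(900, seed = 63)
  cfg <- study_config(size_grid = c(300L, 600L), methods = "LR-all", seed = 3)
  res <- run_study(cohort, cfg)
  expect_true(all(res$observed_rates$first_rate < res$observed_rates$all_rate))
})

test_that("a failing cell records NA metrics and the study continues", {
  # first discharges all non-events: the LR-first cell cannot fit
  tab <- toy_table(rep(2L, 60),
                   outcomes = rep(c(0L, 1L), 60),
                   covariates = data.frame(x = rnorm(120)))
  cfg <- study_config(size_grid = 40L, methods = c("LR-first", "LR-all"),
                      seed = 2)
  res <- suppressWarnings(run_study(tab, cfg))
  first_vals <- res$records$value[res$records$method == "LR-first"]
  expect_true(all(is.na(first_vals)))
  expect_false(is.null(res$failures))
  all_vals <- res$records$value[res$records$method == "LR-all"]
  expect_true(any(!is.na(all_vals)))
})

test_that("slope analysis recovers exact linear and constant trends", {
  sizes <- c(2000, 3000, 4000, 5000, 6000)
  rec <- rbind(
    data.frame(size = sizes, method = "GEE", metric = "auc",
               value = 0.6 + 0.00002 * sizes, replicate = 1L, seed = 1L),
    data.frame(size = sizes, method = "GEE", metric = "brier",
               value = rep(0.15, 5), replicate = 1L, seed = 1L),
    data.frame(size = sizes, method = "LR-all", metric = "auc",
               value = 0.7 + 0.00001 * sizes, replicate = 1L, seed = 1L),
    data.frame(size = sizes, method = "LR-all", metric = "brier",
               value = rep(0.15, 5), replicate = 1L, seed = 1L))
  res <- structure(list(records = rec, config = study_config(size_grid = sizes)),
                   class = "study_result")
  sl <- slope_analysis(res)
  auc_gee <- sl$slopes[sl$slopes$method == "GEE" & sl$slopes$metric == "auc", ]
  expect_equal(auc_gee$slope_per_1000, 0.02, tolerance = 1e-10)
  brier_row <- sl$slopes[sl$slopes$method == "GEE" & sl$slopes$metric == "brier", ]
  expect_equal(brier_row$slope_per_1000, 0, tolerance = 1e-12)
  expect_equal(brier_row$p_value, 1)
  # hand-rolled OLS oracle on the 5-point series
  x <- sizes / 1000; y <- 0.6 + 0.00002 * sizes
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(auc_gee$slope_per_1000, b, tolerance = 1e-10)
  # slopes differ between GEE and LR-all for auc: interaction detected
  auc_anc <- sl$ancova[sl$ancova$metric == "auc", ]
  expect_lt(auc_anc$interaction_p, 0.01)
})

test_that("discharge correlations match a direct oracle and detect coupling", {
  sizes <- c(1L, 2L, 3L, 4L)
  outcomes <- unlist(lapply(sizes, function(m) c(rep(1L, m - 1L), 0L)))
  tab <- toy_table(sizes, outcomes)
  dc <- discharge_correlations(tab)
  expect_equal(dc$r_count, 1)        # readmissions = n_i - 1 exactly

  cohort <- study_cohort(600, seed = 64)
  fits <- list(GEE = fit_gee(cohort), CWGEE = fit_cwgee(cohort))
  dc2 <- discharge_correlations(cohort, fits)
  expect_gt(dc2$r_count, 0)
  expect_true(all(dc2$r_predicted > 0))
  # two-pass oracle for r_count
  per <- dc2$per_patient
  oracle <- cor(per$n_discharges, per$n_readmissions)
  expect_equal(dc2$r_count, oracle)

  # non-informative cohort: predicted risk decouples from cluster size
  flat <- generate_cohort(generator_config(
    n_patients = 800, informativeness = 0, frailty_sd = 1,
    covariate_effects = c(0.4, 0.2, 0.5, -0.3),
    n_constant_covariates = 2L, n_varying_covariates = 2L), seed = 65)
  fit_flat <- fit_gee(flat)
  dc3 <- discharge_correlations(flat, list(GEE = fit_flat))
  expect_lt(abs(dc3$r_predicted[["GEE"]]), 0.15)
})

test_that("plot_study writes one figure per metric plus the size-bin chart", {
  cohort <- study_cohort(400, seed = 66)
  cfg <- study_config(size_grid = c(150L, 250L, 350L),
                      methods = c("LR-all", "GEE"), seed = 4)
  res <- run_study(cohort, cfg)
  out <- tempfile("figs")
  files <- plot_study(res, out, clusters = cluster_summary(cohort))
  expect_length(files, 6L)
  expect_true(all(file.exists(files)))
})

test_that("study outputs serialize to tidy CSVs with a manifest", {
  cohort <- study_cohort(400, seed = 67)
  cfg <- study_config(size_grid = c(150L, 250L, 350L), methods = "LR-all",
                      seed = 6)
  res <- run_study(cohort, cfg)
  out <- tempfile("study")
  write_study_result(res, out)
  expect_true(file.exists(file.path(out, "study_records.csv")))
  expect_true(file.exists(file.path(out, "study_slopes.csv")))
  man <- yaml::read_yaml(file.path(out, "run_manifest.yml"))
  expect_equal(man$seed, 6)
  back <- data.table::fread(file.path(out, "study_records.csv"))
  expect_equal(nrow(back), nrow(res$records))
})
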