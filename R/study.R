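# The resampling experiment: draw cohorts of increasing size from a master
# cohort, run screening + best-subset selection + fitting for each of the
# four modeling strategies, evaluate on the patient-level validation split,
# and analyze how each performance measure changes with sample size.

.METHODS <- c("LR-first", "LR-all", "GEE", "CWGEE")
.METRICS <- c("auc", "correlation", "coef_discrimination",
              "brier", "scaled_brier")

#' Configuration of the resampling study
#'
#' @param size_grid Patient counts to draw from the master cohort.
#' @param replicates Independent draws per size. The single-draw default
#'   mirrors the jagged one-trajectory-per-size design typical of this kind
#'   of experiment; use more replicates to study dispersion.
#' @param train_fraction Fraction of patients used for model development.
#' @param methods Subset of `"LR-first"`, `"LR-all"`, `"GEE"`, `"CWGEE"`.
#' @param screen_alpha Univariate screening level.
#' @param retain_alpha Multivariable retention level.
#' @param exhaustive_limit Passed to [best_subset_select()]; the study
#'   default (8) keeps the per-cell subset enumeration affordable across a
#'   full size grid.
#' @param seed Integer seed; every cell's patient draw and split derive
#'   from it deterministically.
#' @return A `study_config` list.
#' @export
study_config <- function(size_grid = seq(2000L, 17000L, by = 1000L),
                         replicates = 1L,
                         train_fraction = 0.6,
                         methods = .METHODS,
                         screen_alpha = 0.1,
                         retain_alpha = 0.05,
                         exhaustive_limit = 8L,
                         seed = 1L) {
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)
  stopifnot(replicates >= 1L, length(size_grid) >= 1L)
  structure(list(size_grid = as.integer(size_grid),
                 replicates = as.integer(replicates),
                 train_fraction = train_fraction, methods = methods,
                 screen_alpha = screen_alpha, retain_alpha = retain_alpha,
                 exhaustive_limit = as.integer(exhaustive_limit),
                 seed = as.integer(seed)),
            class = "study_config")
}

# Frame selector: LR-first trains and validates on first discharges; the
# other three strategies use all discharges.
.frame_for <- function(method, table) {
  if (method == "LR-first") first_discharges(table) else all_discharges(table)
}

.base_method <- function(method) {
  switch(method, "LR-first" = "LR", "LR-all" = "LR", method)
}

# Full pipeline for one (subset, method) cell: screen, select, fit,
# evaluate. Returns the five metrics plus bookkeeping.
.run_cell <- function(subset_table, method, config, split_seed) {
  frame <- .frame_for(method, subset_table)
  sides <- split_by_patient(frame, config$train_fraction, split_seed)
  base <- .base_method(method)
  screened <- univariate_screen(sides$train, method = base,
                                alpha = config$screen_alpha)
  if (length(screened) == 0L) {
    fit <- suppressWarnings(.fit_intercept_only(sides$train, base))
  } else {
    sel <- suppressWarnings(
      best_subset_select(sides$train, screened, method = base,
                         alpha = config$retain_alpha,
                         exhaustive_limit = config$exhaustive_limit))
    fit <- sel$fit
  }
  rpt <- evaluate_model(fit, sides$validation)
  list(report = rpt, fit = fit,
       train_rate = mean(sides$train$outcome))
}

#' Run the resampling study
#'
#' For every `(size, replicate)` cell: sample that many patients without
#' replacement from the master cohort, split 60/40 by patient, run the full
#' screening + best-subset + fitting pipeline for each modeling strategy,
#' and evaluate on the validation side (each model in its own sampling
#' frame). Fully deterministic given `config$seed`. A failed cell records
#' `NA` metrics with a reason and the study continues.
#'
#' @param cohort The master discharge table.
#' @param config A [study_config()].
#' @return A `study_result` list: `records` (tidy data frame of
#'   size/method/metric/value/replicate/seed), `observed_rates`, `failures`
#'   and the `config`.
#' @export
run_study <- function(cohort, config = study_config()) {
  cohort <- validate_discharge_table(cohort)
  patients <- sort(unique(cohort$patient_id))
  if (max(config$size_grid) > length(patients)) {
    stop("size grid exceeds available patients (", length(patients), ")")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  n_cells <- length(config$size_grid) * config$replicates
  cell_seeds <- matrix(sample.int(2147483646L, 2L * n_cells, replace = TRUE),
                       ncol = 2L)

  records <- list()
  rates <- list()
  failures <- list()
  cell <- 0L
  for (rep_i in seq_len(config$replicates)) {
    for (size in config$size_grid) {
      cell <- cell + 1L
      draw_seed <- cell_seeds[cell, 1L]
      split_seed <- cell_seeds[cell, 2L]
      set.seed(draw_seed)
      ids <- sample(patients, size)
      subset_table <- as_discharge_table(
        cohort[cohort$patient_id %in% ids, , drop = FALSE])
      rates[[length(rates) + 1L]] <- data.frame(
        size = size, replicate = rep_i,
        first_rate = mean(first_discharges(subset_table)$outcome),
        all_rate = mean(subset_table$outcome))
      for (method in config$methods) {
        res <- tryCatch(
          .run_cell(subset_table, method, config, split_seed),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            size = size, method = method, replicate = rep_i,
            reason = conditionMessage(res))
          vals <- setNames(rep(NA_real_, length(.METRICS)), .METRICS)
        } else {
          vals <- unlist(res$report[1L, .METRICS])
        }
        records[[length(records) + 1L]] <- data.frame(
          size = size, method = method, metric = .METRICS,
          value = unname(vals), replicate = rep_i, seed = draw_seed,
          row.names = NULL)
      }
    }
  }
  structure(list(records = do.call(rbind, records),
                 observed_rates = do.call(rbind, rates),
                 failures = if (length(failures)) do.call(rbind, failures),
                 config = config),
            class = "study_result")
}

#' Slope of each performance measure over sample size
#'
#' Per `(method, metric)`: ordinary least squares of the metric on cohort
#' size, reported per 1000 patients, with a normal-theory test of zero
#' slope. Per metric, an ANCOVA-style comparison of slopes across methods
#' is added: the p-value of the size-by-method interaction (full-interaction
#' model against the common-slope model), alongside the common-slope
#' model's fit.
#'
#' @param result A `study_result`.
#' @return A list with `slopes` (method, metric, slope per 1000 patients,
#'   SE, p-value, n used, n dropped) and `ancova` (metric, interaction F,
#'   p-value).
#' @export
slope_analysis <- function(result) {
  stopifnot(inherits(result, "study_result"))
  rec <- result$records
  if (length(unique(rec$size)) < 3L) stop("need at least 3 grid sizes")
  combos <- unique(rec[, c("method", "metric")])
  slopes <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- rec[rec$method == combos$method[i] & rec$metric == combos$metric[i], ]
    dropped <- sum(is.na(sub$value))
    sub <- sub[!is.na(sub$value), ]
    if (nrow(sub) < 3L || var(sub$size) == 0) {
      return(data.frame(method = combos$method[i], metric = combos$metric[i],
                        slope_per_1000 = NA_real_, se = NA_real_,
                        p_value = NA_real_, n_used = nrow(sub),
                        n_dropped = dropped))
    }
    fit <- lm(value ~ I(size / 1000), data = sub)
    slope <- unname(coef(fit)[2L])
    resid_sd <- sqrt(sum(fit$residuals^2) / fit$df.residual)
    if (!is.finite(resid_sd) ||
        resid_sd < 1e-10 * max(1, mean(abs(sub$value)))) {
      # exact fit: a (near-)zero slope is indistinguishable from flat
      data.frame(method = combos$method[i], metric = combos$metric[i],
                 slope_per_1000 = slope, se = 0,
                 p_value = if (abs(slope) < 1e-10) 1 else 0,
                 n_used = nrow(sub), n_dropped = dropped)
    } else {
      sm <- summary(fit)$coefficients
      data.frame(method = combos$method[i], metric = combos$metric[i],
                 slope_per_1000 = sm[2L, 1L], se = sm[2L, 2L],
                 p_value = sm[2L, 4L], n_used = nrow(sub),
                 n_dropped = dropped)
    }
  }))
  ancova <- do.call(rbind, lapply(unique(rec$metric), function(m) {
    sub <- rec[rec$metric == m & !is.na(rec$value), ]
    if (length(unique(sub$method)) < 2L || nrow(sub) < 6L) {
      return(data.frame(metric = m, interaction_F = NA_real_,
                        interaction_p = NA_real_))
    }
    full <- lm(value ~ I(size / 1000) * method, data = sub)
    common <- lm(value ~ I(size / 1000) + method, data = sub)
    av <- anova(common, full)
    data.frame(metric = m, interaction_F = av$F[2L],
               interaction_p = av$`Pr(>F)`[2L])
  }))
  list(slopes = slopes, ancova = ancova)
}

#' Correlations between discharge count and readmission burden / predicted risk
#'
#' Per patient: the discharge count \eqn{n_i}, the readmission count, and
#' (per supplied fit) the mean predicted probability over the patient's
#' discharges. Reports the Pearson correlation between discharge count and
#' readmission count, between discharge count and mean predicted risk for
#' each method, the correlation of log discharge count with the per-patient
#' readmission proportion, and readmitted-discharge percentages by
#' cluster-size bin.
#'
#' @param cohort A discharge table.
#' @param fits Named list of `readmit_fit` objects (one per method);
#'   may be empty.
#' @param size_breaks Passed to [cluster_summary()].
#' @return A list: `r_count`, `r_predicted` (named vector), `r_log_risk`,
#'   `bins`, `per_patient`.
#' @export
discharge_correlations <- function(cohort, fits = list(),
                                   size_breaks = c(1L, 2L, 3L, 4L, 5L)) {
  cohort <- validate_discharge_table(cohort)
  cs <- cluster_summary(cohort, size_breaks)
  per <- cs$per_patient
  degenerate <- var(per$n_discharges) == 0
  r_count <- if (degenerate) NA_real_ else
    cor(per$n_discharges, per$n_readmissions)
  r_pred <- vapply(fits, function(fit) {
    p <- predict_probability(fit, cohort)
    mp <- tapply(p, cohort$patient_id, mean)
    mp <- mp[match(per$patient_id, names(mp))]
    if (degenerate || var(mp) == 0) NA_real_ else
      cor(per$n_discharges, as.numeric(mp))
  }, numeric(1))
  list(r_count = r_count, r_predicted = r_pred,
       r_log_risk = cs$r_log_size_rate, bins = cs$bins, per_patient = per)
}

#' Plot the study trajectories
#'
#' One line chart per performance measure (x = cohort size, one series per
#' method, replicates averaged), plus — when a [cluster_summary()] is
#' supplied — a bar chart of the readmitted-discharge percentage by
#' cluster-size bin.
#'
#' @param result A `study_result`.
#' @param out_dir Directory for PNG files (created if needed).
#' @param clusters Optional `cluster_summary` for the size-bin chart.
#' @return Character vector of the files written, invisibly.
#' @export
plot_study <- function(result, out_dir, clusters = NULL) {
  stopifnot(inherits(result, "study_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- result$records[!is.na(result$records$value), ]
  files <- character()
  for (m in unique(rec$metric)) {
    sub <- rec[rec$metric == m, ]
    agg <- aggregate(value ~ size + method, data = sub, FUN = mean)
    gg <- ggplot2::ggplot(agg, ggplot2::aes(
      x = .data$size, y = .data$value, colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "Cohort size (patients)", y = m,
                    colour = "Method",
                    title = paste0(m, " in validation samples")) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, paste0("study_", m, ".png"))
    ggplot2::ggsave(f, gg, width = 7, height = 4.5, dpi = 150)
    files <- c(files, f)
  }
  if (!is.null(clusters)) {
    bins <- clusters$bins
    gg <- ggplot2::ggplot(bins, ggplot2::aes(
      x = factor(.data$size_bin, levels = .data$size_bin),
      y = .data$readmit_pct)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "Discharges per patient",
                    y = "Readmitted discharges (%)",
                    title = "Readmission risk by discharge count") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "readmission_by_cluster_size.png")
    ggplot2::ggsave(f, gg, width = 6, height = 4, dpi = 150)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write study outputs as tidy CSVs
#'
#' @param result A `study_result`.
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_study_result <- function(result, out_dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec_path <- file.path(out_dir, "study_records.csv")
  data.table::fwrite(result$records, rec_path)
  sl <- slope_analysis(result)
  sl_path <- file.path(out_dir, "study_slopes.csv")
  data.table::fwrite(sl$slopes, sl_path)
  manifest <- list(seed = result$config$seed,
                   size_grid = result$config$size_grid,
                   replicates = result$config$replicates,
                   methods = result$config$methods,
                   package_version = as.character(
                     utils::packageVersion("readmitclust")))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yml"))
  invisible(c(rec_path, sl_path))
}

#' @importFrom rlang .data
NULL
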