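# The five performance measures for a probabilistic binary-outcome model:
# C statistic (AUC), outcome-prediction correlation, coefficient of
# discrimination (Tjur's D), Brier score, and the scaled Brier score
# 1 - Brier/Brier_max with Brier_max = mean(p) (1 - mean(p)).
# Metrics that are undefined on a degenerate sample (single outcome class,
# zero-variance predictions) return NA_real_ — an explicit undefined
# marker, never a silent 0.

.check_metric_input <- function(outcomes, predictions) {
  stopifnot(length(outcomes) == length(predictions), length(outcomes) > 0L)
  if (anyNA(outcomes) || anyNA(predictions)) stop("missing values")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
}

#' C statistic (area under the ROC curve)
#'
#' Mann-Whitney formulation: the probability that a randomly chosen event
#' receives a higher prediction than a randomly chosen non-event, with tied
#' prediction pairs counting 1/2.
#'
#' @param outcomes Binary 0/1 vector.
#' @param predictions Predicted probabilities (any monotone score works).
#' @return AUC in \[0, 1\], or `NA` if only one outcome class is present.
#' @export
c_statistic <- function(outcomes, predictions) {
  .check_metric_input(outcomes, predictions)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(predictions)                      # midranks handle ties as 1/2
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Correlation between outcome and prediction
#'
#' Pearson product-moment correlation (point-biserial, given a binary
#' outcome) between the observed outcome and the predicted probability.
#'
#' @inheritParams c_statistic
#' @return Correlation in \[-1, 1\], or `NA` when either side has zero
#'   variance.
#' @export
outcome_correlation <- function(outcomes, predictions) {
  .check_metric_input(outcomes, predictions)
  if (var(outcomes) == 0 || var(predictions) == 0) return(NA_real_)
  cor(outcomes, predictions)
}

#' Coefficient of discrimination (D)
#'
#' Absolute difference between the mean predicted probability among events
#' (model successes) and among non-events (model failures).
#'
#' @inheritParams c_statistic
#' @return Non-negative D, or `NA` if only one class is present.
#' @export
coefficient_of_discrimination <- function(outcomes, predictions) {
  .check_metric_input(outcomes, predictions)
  if (all(outcomes == 1) || all(outcomes == 0)) return(NA_real_)
  abs(mean(predictions[outcomes == 1]) - mean(predictions[outcomes == 0]))
}

#' Brier score
#'
#' Mean squared deviation between the predicted probability and the binary
#' outcome; 0 for a perfect model, up to 0.25 for a noninformative model at
#' 50% incidence.
#'
#' @inheritParams c_statistic
#' @return Non-negative Brier score.
#' @export
brier_score <- function(outcomes, predictions) {
  .check_metric_input(outcomes, predictions)
  mean((predictions - outcomes)^2)
}

#' Scaled Brier score
#'
#' `1 - Brier/Brier_max` with `Brier_max = mean(p) * (1 - mean(p))`. By
#' default `mean(p)` is the observed outcome incidence of the evaluation
#' sample (for a calibrated model the mean prediction approximately equals
#' the incidence); set `brier_max = "mean_prediction"` to use the mean
#' predicted probability instead. Unlike the raw Brier score the scaled
#' score does not depend on the incidence; it can be negative for a model
#' worse than the noninformative baseline.
#'
#' @inheritParams c_statistic
#' @param brier_max Convention for `mean(p)`: `"incidence"` (default) or
#'   `"mean_prediction"`.
#' @return Scaled Brier score (at most 1), or `NA` when `Brier_max` is 0
#'   (single-class sample).
#' @export
scaled_brier <- function(outcomes, predictions,
                         brier_max = c("incidence", "mean_prediction")) {
  .check_metric_input(outcomes, predictions)
  brier_max <- match.arg(brier_max)
  pbar <- if (brier_max == "incidence") mean(outcomes) else mean(predictions)
  bmax <- pbar * (1 - pbar)
  if (bmax <= 0) return(NA_real_)
  1 - brier_score(outcomes, predictions) / bmax
}

#' Evaluate a fitted model on a validation sample
#'
#' Computes predictions on the validation rows and assembles the five
#' performance measures plus the observed incidence and sample size. The
#' caller supplies the validation table in the fit's own sampling frame
#' (first discharges for a first-discharge model, all discharges
#' otherwise).
#'
#' @param fit A `readmit_fit`.
#' @param validation A discharge table.
#' @param brier_max Passed to [scaled_brier()].
#' @return A `performance_report`: a one-row data frame with columns
#'   `auc`, `correlation`, `coef_discrimination`, `brier`, `brier_max`,
#'   `scaled_brier`, `observed_rate`, `n`.
#' @export
evaluate_model <- function(fit, validation, brier_max = "incidence") {
  validation <- validate_discharge_table(validation)
  p <- predict_probability(fit, validation)
  y <- validation$outcome
  pbar <- if (brier_max == "incidence") mean(y) else mean(p)
  rpt <- data.frame(
    auc = c_statistic(y, p),
    correlation = outcome_correlation(y, p),
    coef_discrimination = coefficient_of_discrimination(y, p),
    brier = brier_score(y, p),
    brier_max = pbar * (1 - pbar),
    scaled_brier = scaled_brier(y, p, brier_max),
    observed_rate = mean(y),
    n = length(y))
  class(rpt) <- c("performance_report", class(rpt))
  rpt
}
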