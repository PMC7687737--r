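# Shared fixtures, all built in code.

# Drop the discharge_table class so validation runs from scratch.
strip_dt <- function(x) {
  x <- as.data.frame(x)
  class(x) <- "data.frame"
  x
}

# A hand-made table: patients with given cluster sizes and outcomes.
toy_table <- function(sizes, outcomes = NULL, covariates = NULL) {
  pid <- rep(sprintf("P%03d", seq_along(sizes)), sizes)
  n <- sum(sizes)
  if (is.null(outcomes)) outcomes <- rep(0L, n)
  tab <- data.frame(patient_id = pid,
                    discharge_index = sequence(sizes),
                    outcome = as.integer(outcomes))
  if (!is.null(covariates)) tab <- cbind(tab[1:2], covariates, outcome = tab$outcome)
  as_discharge_table(tab)
}

# A timestamped single-patient table with given inter-stay gaps (hours) and
# lengths of stay (hours).
timeline_table <- function(gaps_h, los_h = rep(24, length(gaps_h) + 1),
                           patient = "P001") {
  m <- length(los_h)
  adm <- numeric(m)
  for (j in seq_len(m)) {
    adm[j] <- if (j == 1) 0 else adm[j - 1] + los_h[j - 1] * 3600 +
      gaps_h[j - 1] * 3600
  }
  origin <- as.POSIXct("2004-01-01", tz = "UTC")
  as_discharge_table(data.frame(
    patient_id = patient, discharge_index = seq_len(m),
    admission_time = origin + adm,
    discharge_time = origin + adm + los_h * 3600,
    outcome = 0L))
}

# Small default-structure cohort for pipeline tests.
small_cohort <- function(n_patients = 400, seed = 1, ...) {
  generate_cohort(generator_config(n_patients = n_patients, ...), seed = seed)
}

# Moderately informative cohort with a light cluster-size tail: used for
# algebraic-property tests where an extreme cluster draw would only test
# solver robustness, not the property at hand.
tame_cohort <- function(n_patients = 300, seed = 1) {
  generate_cohort(generator_config(
    n_patients = n_patients, informativeness = 0.8, cluster_rate = 1.1,
    covariate_effects = c(0.4, 0.2, 0.5, -0.3),
    n_constant_covariates = 2L, n_varying_covariates = 2L), seed = seed)
}

# A compact generator setup used where full covariate defaults are overkill.
lean_config <- function(n_patients, beta = c(0.5, -0.3), ...) {
  generator_config(n_patients = n_patients,
                   covariate_effects = beta,
                   n_constant_covariates = 1L, n_varying_covariates = 1L,
                   ...)
}
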