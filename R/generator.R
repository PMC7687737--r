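# Synthetic clustered-cohort generator with informative cluster size.
#
# One latent patient-level frailty u_i drives BOTH the number of discharges
# (cluster size) and the per-discharge readmission risk, so cluster size is
# informative: patients who return often are also readmitted often. This is
# the minimal shared-parameter mechanism producing the strong coupling
# between discharge counts and readmission counts seen in real hospital
# cohorts.

.SECONDS_PER_DAY <- 86400
.TIME_ORIGIN <- as.POSIXct("2004-01-01 00:00:00", tz = "UTC")

#' Configuration of the synthetic clustered cohort
#'
#' Defaults emulate the structure of a large single-center adult cohort:
#' roughly 17,000 patients averaging ~2.5 discharges each, a ~10%
#' readmission rate among first discharges and ~20% among all discharges.
#'
#' @param n_patients Number of patients (clusters) to generate.
#' @param frailty_sd Standard deviation \eqn{\sigma} of the latent
#'   patient-level frailty \eqn{u_i \sim N(0, \sigma^2)}.
#' @param cluster_rate Poisson rate \eqn{\lambda}: mean number of discharges
#'   beyond the first for a patient with frailty 0
#'   (\eqn{n_i = 1 + \mathrm{Poisson}(\lambda e^{\gamma u_i})}).
#' @param informativeness Effect \eqn{\gamma} of the frailty on the
#'   cluster-size intensity; 0 makes cluster size non-informative.
#' @param baseline_logit Intercept \eqn{\alpha} of the outcome model
#'   \eqn{\mathrm{logit}\,P(Y_{ij}=1) = \alpha + \beta^\top X_{ij} + u_i}.
#' @param covariate_effects Numeric vector \eqn{\beta}, one per covariate:
#'   first the patient-constant covariates, then the discharge-varying ones.
#' @param n_constant_covariates Number of patient-constant binary
#'   covariates, drawn once per patient as
#'   Bernoulli(expit(`frailty_loading` \eqn{\times u_i})) — marginally
#'   Bernoulli(0.5), but correlated with the frailty the way chronic
#'   comorbidity indicators track a patient's underlying illness burden.
#' @param frailty_loading Strength \eqn{\kappa} of the frailty's effect on
#'   the constant covariates; 0 makes all covariates independent of the
#'   frailty (and hence of cluster size).
#' @param n_varying_covariates Number of discharge-varying standard-normal
#'   covariates.
#' @param readmission_window_days Outcome window (days); a readmission is a
#'   next admission within this many days of a discharge.
#' @param merge_window_hours Gap (hours) at or below which a readmission is
#'   regarded as an in-hospital transfer and merged with the index stay.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 17284L,
                             frailty_sd = 1.0,
                             cluster_rate = 0.67,
                             informativeness = 1.3,
                             baseline_logit = -3.0,
                             covariate_effects = c(0.35, 0.2, 0.1, 0,
                                                   0.4, -0.3, 0.2, -0.15,
                                                   0.1, -0.1, 0.05, 0),
                             n_constant_covariates = 4L,
                             n_varying_covariates = 8L,
                             frailty_loading = 0.6,
                             readmission_window_days = 30,
                             merge_window_hours = 8) {
  config <- list(
    n_patients = as.integer(n_patients),
    frailty_sd = frailty_sd,
    cluster_rate = cluster_rate,
    informativeness = informativeness,
    baseline_logit = baseline_logit,
    covariate_effects = covariate_effects,
    n_constant_covariates = as.integer(n_constant_covariates),
    n_varying_covariates = as.integer(n_varying_covariates),
    frailty_loading = frailty_loading,
    readmission_window_days = readmission_window_days,
    merge_window_hours = merge_window_hours
  )
  if (config$n_patients < 1L) stop("n_patients must be >= 1")
  if (config$frailty_sd < 0) stop("frailty_sd must be >= 0")
  if (config$cluster_rate <= 0) stop("cluster_rate must be > 0")
  n_cov <- config$n_constant_covariates + config$n_varying_covariates
  if (length(config$covariate_effects) != n_cov) {
    stop("covariate_effects must have length n_constant + n_varying = ", n_cov)
  }
  class(config) <- "generator_config"
  config
}

# Per-patient child seeds from one global seed. Each patient's draws come
# from an RNG stream seeded by their own child seed, so extending the cohort
# never perturbs earlier patients' data.
.patient_seeds <- function(seed, n) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  sample.int(2147483646L, n, replace = TRUE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic clustered discharge cohort
#'
#' For each patient `i` a frailty \eqn{u_i \sim N(0, \sigma^2)} is drawn;
#' the cluster size is \eqn{n_i = 1 + \mathrm{Poisson}(\lambda e^{\gamma u_i})};
#' patient-constant covariates are drawn once per patient
#' (Bernoulli(0.5)) and discharge-varying covariates per discharge (standard
#' normal); the outcome is
#' \eqn{Y_{ij} \sim \mathrm{Bernoulli}(\mathrm{expit}(\alpha + \beta^\top X_{ij} + u_i))}.
#'
#' With `timestamps = TRUE`, admission/discharge times are emitted such that
#' the 30-day labeling rule reconstructs the latent outcomes exactly:
#' inter-admission gaps are drawn above the merge window and within the
#' readmission window when \eqn{Y_{ij} = 1}, and between the readmission
#' window and one year otherwise. Each patient's last discharge is forced to
#' \eqn{Y = 0} in this mode, since no later admission exists to observe.
#'
#' The same `(config, seed)` pair always yields a byte-identical table.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for the global stream.
#' @param timestamps Emit admission/discharge timestamps (timeline mode).
#' @return A `discharge_table`, with the per-patient frailties attached as
#'   attribute `"frailty"`.
#' @export
generate_cohort <- function(config = generator_config(), seed = 1L,
                            timestamps = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  n_pat <- config$n_patients
  if (n_pat < 1L) stop("zero patients requested")
  k_const <- config$n_constant_covariates
  k_vary <- config$n_varying_covariates
  beta <- config$covariate_effects
  seeds <- .patient_seeds(seed, n_pat)

  old <- .save_rng()
  on.exit(.restore_rng(old))

  # Pass 1: frailty and cluster size, to pre-size the output.
  u <- numeric(n_pat)
  n_i <- integer(n_pat)
  for (i in seq_len(n_pat)) {
    set.seed(seeds[i])
    u[i] <- rnorm(1L, 0, config$frailty_sd)
    n_i[i] <- 1L + rpois(1L, config$cluster_rate *
                           exp(config$informativeness * u[i]))
  }
  total <- sum(n_i)
  offsets <- c(0L, cumsum(n_i))

  X <- matrix(0, nrow = total, ncol = k_const + k_vary)
  y <- integer(total)
  adm <- dis <- numeric(total)
  pid <- character(total)
  d_idx <- integer(total)

  win_sec <- config$readmission_window_days * .SECONDS_PER_DAY
  merge_sec <- config$merge_window_hours * 3600

  # Pass 2: replay each patient's stream (frailty and size first, in the
  # same order) then draw covariates, outcomes and the timeline.
  for (i in seq_len(n_pat)) {
    set.seed(seeds[i])
    rnorm(1L); rpois(1L, 1)              # consume pass-1 draws identically
    m <- n_i[i]
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    xc <- if (k_const > 0L) {
      rbinom(k_const, 1L, plogis(config$frailty_loading * u[i]))
    } else numeric()
    xv <- if (k_vary > 0L) matrix(rnorm(m * k_vary), nrow = m) else
      matrix(0, m, 0L)
    Xi <- cbind(matrix(rep(xc, each = m), nrow = m), xv)
    eta <- config$baseline_logit + as.vector(Xi %*% beta) + u[i]
    if (any(!is.finite(eta))) stop("non-finite linear predictor")
    yi <- rbinom(m, 1L, plogis(eta))
    if (timestamps) {
      yi[m] <- 0L                         # no later admission to observe
      los <- round(runif(m, 1, 10) * .SECONDS_PER_DAY)
      gaps <- numeric(m - 1L)
      if (m > 1L) {
        for (j in seq_len(m - 1L)) {
          gaps[j] <- if (yi[j] == 1L) {
            round(runif(1L, merge_sec + 1, win_sec))
          } else {
            round(runif(1L, win_sec + 3600, 365 * .SECONDS_PER_DAY))
          }
        }
      }
      a0 <- round(runif(1L, 0, 2000 * .SECONDS_PER_DAY))
      ai <- numeric(m)
      ai[1L] <- a0
      if (m > 1L) for (j in 2L:m) ai[j] <- ai[j - 1L] + los[j - 1L] + gaps[j - 1L]
      adm[rows] <- ai
      dis[rows] <- ai + los
    }
    X[rows, ] <- Xi
    y[rows] <- yi
    pid[rows] <- sprintf("P%07d", i)
    d_idx[rows] <- seq_len(m)
  }

  cov_names <- c(if (k_const > 0L) paste0("xc", seq_len(k_const)),
                 if (k_vary > 0L) paste0("xv", seq_len(k_vary)))
  colnames(X) <- cov_names
  tab <- data.frame(patient_id = pid, discharge_index = d_idx,
                    check.names = FALSE)
  if (timestamps) {
    tab$admission_time <- .TIME_ORIGIN + adm
    tab$discharge_time <- .TIME_ORIGIN + dis
  }
  tab <- cbind(tab, as.data.frame(X), outcome = y)
  tab <- as_discharge_table(tab)
  attr(tab, "frailty") <- setNames(u, sprintf("P%07d", seq_len(n_pat)))
  tab
}

#' Summarize the clustering structure of a cohort
#'
#' Tabulates patients by cluster-size bin, counts readmissions per patient,
#' and reports the Pearson correlation between the log cluster size and the
#' per-patient readmission count — the quantity that reveals informative
#' cluster size.
#'
#' @param table A discharge table.
#' @param size_breaks Integer cut points for the cluster-size bins; a bin
#'   `k` holds patients with exactly `k` discharges, and the last bin is
#'   open-ended (`k+`).
#' @return A list of class `cluster_summary` with elements `bins`
#'   (patients and readmitted-discharge percentage per bin), `per_patient`
#'   (cluster size and readmission count per patient), `r_log_size`
#'   (correlation of log size with readmission count; `NA` when all cluster
#'   sizes are equal) and `r_log_size_rate` (correlation of log size with
#'   the per-patient readmission proportion).
#' @export
cluster_summary <- function(table, size_breaks = c(1L, 2L, 3L)) {
  table <- validate_discharge_table(table)
  if (nrow(table) == 0L) stop("empty discharge table")
  per <- aggregate(outcome ~ patient_id, data = table,
                   FUN = function(v) c(n = length(v), readmits = sum(v)))
  per_patient <- data.frame(patient_id = per$patient_id,
                            n_discharges = per$outcome[, "n"],
                            n_readmissions = per$outcome[, "readmits"])
  n_i <- per_patient$n_discharges
  size_breaks <- sort(unique(as.integer(size_breaks)))
  labels <- c(as.character(head(size_breaks, -1L)),
              paste0(tail(size_breaks, 1L), "+"))
  bin_of <- findInterval(n_i, size_breaks)
  bins <- do.call(rbind, lapply(seq_along(size_breaks), function(b) {
    sel <- bin_of == b
    disc <- table$outcome[table$patient_id %in% per_patient$patient_id[sel]]
    data.frame(size_bin = labels[b],
               n_patients = sum(sel),
               pct_patients = 100 * mean(sel),
               n_discharges = sum(n_i[sel]),
               readmit_pct = if (sum(sel) > 0L) 100 * mean(disc) else NA_real_)
  }))
  rownames(bins) <- NULL
  degen <- stats::var(n_i) == 0 ||
    stats::var(per_patient$n_readmissions) == 0
  r_log_size <- if (degen) NA_real_ else
    cor(log(n_i), per_patient$n_readmissions)
  r_rate <- if (degen || stats::var(per_patient$n_readmissions / n_i) == 0)
    NA_real_ else cor(log(n_i), per_patient$n_readmissions / n_i)
  structure(list(bins = bins, per_patient = per_patient,
                 r_log_size = r_log_size, r_log_size_rate = r_rate),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("Cluster-size distribution:\n")
  print(x$bins, row.names = FALSE)
  cat(sprintf("Pearson r, log(cluster size) vs readmission count: %s\n",
              ifelse(is.na(x$r_log_size), "undefined",
                     sprintf("%.3f", x$r_log_size))))
  invisible(x)
}
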