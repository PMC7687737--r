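# Cohort-construction rules for timestamped discharge tables: fuse
# near-immediate readmissions (in-hospital transfers) into the index stay,
# then label the 30-day all-cause readmission outcome.

#' Merge near-immediate readmissions into the index stay
#'
#' An admission beginning at or below `window_hours` after the previous
#' discharge of the same patient is regarded as an in-hospital transfer and
#' fused into that stay: the fused stay keeps the first component's
#' admission time and covariates (the index admission's characteristics),
#' extends its discharge time to the last component's, and takes the last
#' component's outcome (readmission status relative to what follows the
#' fused stay). Fusing is closed under chaining — a run of stays each within
#' the window of its predecessor collapses to one stay — and
#' `discharge_index` is re-assigned contiguously.
#'
#' @param table A discharge table with timestamps, ordered within patient.
#' @param window_hours Merge window, hours; the boundary is inclusive
#'   (a gap of exactly `window_hours` merges).
#' @return A discharge table with fused stays.
#' @export
merge_short_interval_readmissions <- function(table, window_hours = 8) {
  table <- validate_discharge_table(table, require_timestamps = TRUE)
  window_sec <- window_hours * 3600
  covs <- covariate_names(table)
  ord <- order(table$patient_id, table$discharge_index)
  if (!identical(ord, seq_len(nrow(table)))) {
    stop("input rows must be ordered by (patient_id, discharge_index)")
  }

  adm <- as.numeric(table$admission_time)
  dis <- as.numeric(table$discharge_time)
  pid <- table$patient_id
  new_pat <- c(TRUE, pid[-1L] != pid[-length(pid)])
  gap <- c(NA_real_, adm[-1L] - dis[-length(dis)])
  overlap <- !new_pat & gap < 0
  if (any(overlap)) {
    stop("overlapping stays (admission before prior discharge) for patient ",
         pid[which(overlap)[1L]])
  }
  # A stay starts a new group when it opens a new patient or its gap to the
  # immediately preceding discharge exceeds the window. Because stays do not
  # overlap, a group's running discharge time is always its latest member's,
  # so this single scan realizes the transitive closure of the merge rule.
  starts <- new_pat | gap > window_sec
  grp <- cumsum(starts)

  first <- which(starts)
  last <- c(first[-1L] - 1L, length(grp))
  out <- table[first, , drop = FALSE]
  out$discharge_time <- table$discharge_time[last]
  out$outcome <- table$outcome[last]
  out$discharge_index <- unlist(lapply(
    rle(pid[first])$lengths, seq_len), use.names = FALSE)
  rownames(out) <- NULL
  as_discharge_table(out)
}

#' Label the 30-day all-cause readmission outcome
#'
#' Sets \eqn{Y_{ij} = 1} iff the same patient has a later admission with
#' \eqn{0 < t^{adm}_{i,j+1} - t^{dis}_{ij} \le} `window_days` (boundary
#' inclusive at exactly `window_days` x 24h). A patient's last discharge is
#' always 0 — no later admission exists. The operation is idempotent and
#' assumes [merge_short_interval_readmissions()] has already been applied.
#'
#' @param table A discharge table with timestamps.
#' @param window_days Outcome window, days.
#' @return The table with `outcome` re-labeled.
#' @export
label_readmissions <- function(table, window_days = 30) {
  table <- validate_discharge_table(table, require_timestamps = TRUE)
  window_sec <- window_days * .SECONDS_PER_DAY
  ord <- order(table$patient_id, table$discharge_index)
  table <- table[ord, , drop = FALSE]
  adm <- as.numeric(table$admission_time)
  dis <- as.numeric(table$discharge_time)
  pid <- table$patient_id
  n <- nrow(table)
  next_adm <- c(adm[-1L], NA_real_)
  same_pat <- c(pid[-n] == pid[-1L], FALSE)
  gap <- next_adm - dis
  table$outcome <- as.integer(same_pat & !is.na(gap) &
                                gap > 0 & gap <= window_sec)
  rownames(table) <- NULL
  as_discharge_table(table)
}

#' Filter discharges by an exclusion rule
#'
#' Hook for cohort exclusion criteria (age limits, transfers, deaths, ...):
#' applies a row predicate and re-assigns `discharge_index` contiguously
#' within each retained patient.
#'
#' @param table A discharge table.
#' @param keep Logical vector (one per row) or a function of the table
#'   returning one.
#' @return The filtered, re-indexed discharge table.
#' @export
exclude_discharges <- function(table, keep) {
  table <- validate_discharge_table(table)
  if (is.function(keep)) keep <- keep(table)
  stopifnot(is.logical(keep), length(keep) == nrow(table))
  out <- table[keep & !is.na(keep), , drop = FALSE]
  out <- out[order(out$patient_id, out$discharge_index), , drop = FALSE]
  out$discharge_index <- unlist(lapply(
    rle(out$patient_id)$lengths, seq_len), use.names = FALSE)
  rownames(out) <- NULL
  as_discharge_table(out)
}
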