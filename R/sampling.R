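# The two discharge sampling strategies and the patient-level
# train/validation split. The split is always at the PATIENT level so that
# no cluster straddles the two sides — the integrity property every
# clustering-aware analysis depends on.

#' Keep only the first discharge of each patient
#'
#' @param table A discharge table.
#' @return A discharge table with exactly one row per patient (the
#'   `discharge_index == 1` row); patient count preserved.
#' @export
first_discharges <- function(table) {
  table <- validate_discharge_table(table)
  out <- table[table$discharge_index == 1L, , drop = FALSE]
  rownames(out) <- NULL
  as_discharge_table(out)
}

#' Keep all discharges of each patient
#'
#' Identity with schema validation: the all-discharges sampling frame.
#'
#' @param table A discharge table.
#' @return The validated table, unchanged.
#' @export
all_discharges <- function(table) {
  table <- validate_discharge_table(table)
  as_discharge_table(table)
}

#' Split a cohort into training and validation sets by patient
#'
#' Patients are randomly permuted (deterministically given `seed`) and the
#' first `round(train_fraction * N)` patients form the training side; every
#' discharge of a patient lands on exactly one side. The permutation depends
#' only on the sorted set of patient identifiers, so splitting commutes with
#' per-patient row filters such as [first_discharges()].
#'
#' @param table A discharge table.
#' @param train_fraction Fraction of patients assigned to training.
#' @param seed Integer seed.
#' @return A list with `train` and `validation` discharge tables.
#' @export
split_by_patient <- function(table, train_fraction = 0.6, seed = 1L) {
  table <- validate_discharge_table(table)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  patients <- sort(unique(table$patient_id))
  n <- length(patients)
  if (n < 2L) stop("need at least 2 patients to split")
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample(patients)
  train_ids <- perm[seq_len(n_train)]
  in_train <- table$patient_id %in% train_ids
  list(train = as_discharge_table(table[in_train, , drop = FALSE]),
       validation = as_discharge_table(table[!in_train, , drop = FALSE]))
}
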