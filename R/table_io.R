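#' @importFrom data.table fread fwrite as.data.table setDF setDT :=
#' @importFrom stats plogis rnorm rpois rbinom runif sd cor qnorm pnorm
#'   quantile lm anova coef vcov pf var aggregate complete.cases setNames
#' @importFrom utils head tail combn
NULL

# Columns every discharge table must carry, in canonical order (outcome last).
.RESERVED_COLS <- c("patient_id", "discharge_index",
                    "admission_time", "discharge_time", "outcome")

#' Covariate column names of a discharge table
#'
#' Every column that is not part of the reserved schema
#' (`patient_id`, `discharge_index`, `admission_time`, `discharge_time`,
#' `outcome`) is treated as a covariate.
#'
#' @param table A discharge table (`data.frame`).
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function(table) {
  setdiff(names(table), .RESERVED_COLS)
}

#' Validate a discharge table against the schema
#'
#' Checks the invariants every stage of the pipeline relies on: required
#' columns present, `outcome` binary in `{0, 1}`, no duplicated
#' `(patient_id, discharge_index)` key, `discharge_index` contiguous
#' `1..n_i` within each patient, covariates numeric, and — when timestamps
#' are present — admissions ordered and consistent with `discharge_index`.
#'
#' @param table A `data.frame` to validate.
#' @param require_timestamps Require `admission_time`/`discharge_time`
#'   columns (needed by the labeling operations).
#' @return The validated table, invisibly, with class `discharge_table`.
#' @export
validate_discharge_table <- function(table, require_timestamps = FALSE) {
  if (!is.data.frame(table)) stop("discharge table must be a data.frame")
  has_ts0 <- all(c("admission_time", "discharge_time") %in% names(table))
  if (inherits(table, "discharge_table") &&
      (!require_timestamps || has_ts0)) {
    return(invisible(table))    # already validated by construction
  }
  required <- c("patient_id", "discharge_index", "outcome")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    stop("discharge table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  has_ts <- all(c("admission_time", "discharge_time") %in% names(table))
  if (require_timestamps && !has_ts) {
    stop("discharge table has no admission_time/discharge_time columns")
  }

  y <- table$outcome
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome column must be binary 0/1 with no missing values")
  }
  key <- paste(table$patient_id, table$discharge_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (patient_id, discharge_index) keys present")
  }
  ord <- order(table$patient_id, table$discharge_index)
  pid_s <- table$patient_id[ord]
  idx_s <- as.integer(table$discharge_index[ord])
  expected <- sequence(rle(as.character(pid_s))$lengths)
  if (!identical(idx_s, as.integer(expected))) {
    bad <- unique(pid_s[idx_s != expected])
    stop("discharge_index not contiguous 1..n_i for patient(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  covs <- covariate_names(table)
  not_num <- covs[!vapply(table[covs], is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    stop("non-numeric covariate column(s): ", paste(not_num, collapse = ", "))
  }
  if (has_ts) {
    if (anyNA(table$admission_time) || anyNA(table$discharge_time)) {
      stop("missing timestamps")
    }
    adm <- as.numeric(table$admission_time)[ord]
    dis <- as.numeric(table$discharge_time)[ord]
    if (any(dis < adm)) {
      stop("discharge before admission for patient ",
           pid_s[which(dis < adm)[1L]])
    }
    same_pat <- c(FALSE, pid_s[-1L] == pid_s[-length(pid_s)])
    disordered <- same_pat & c(FALSE, diff(adm) <= 0)
    if (any(disordered)) {
      stop("admissions out of order for patient ",
           pid_s[which(disordered)[1L]])
    }
  }
  class(table) <- unique(c("discharge_table", class(table)))
  invisible(table)
}

#' Coerce a data frame to a discharge table
#'
#' Reorders columns to the canonical layout (identifiers first, covariates,
#' `outcome` last), sorts rows by `(patient_id, discharge_index)` and
#' validates the schema.
#'
#' @param table A `data.frame` with the required columns.
#' @return A validated `discharge_table`.
#' @export
as_discharge_table <- function(table) {
  validate_discharge_table(table)   # descriptive error before any reshaping
  has_ts <- all(c("admission_time", "discharge_time") %in% names(table))
  ts_cols <- if (has_ts) c("admission_time", "discharge_time") else character()
  covs <- covariate_names(table)
  table <- table[order(table$patient_id, table$discharge_index),
                 c("patient_id", "discharge_index", ts_cols, covs, "outcome"),
                 drop = FALSE]
  rownames(table) <- NULL
  class(table) <- unique(c("discharge_table", "data.frame"))
  table
}

#' Read a discharge table from CSV
#'
#' Expects the dialect written by [write_discharge_table()]: comma-separated,
#' UTF-8, header row, ISO-8601 timestamps in UTC. All non-reserved columns
#' are read as numeric covariates. Validation failures raise descriptive
#' errors; malformed text never crashes the reader silently.
#'
#' @param path Path to a CSV file.
#' @return A validated `discharge_table`.
#' @export
read_discharge_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = list(character = "patient_id"),
                          data.table = FALSE, encoding = "UTF-8")
  if (nrow(dt) == 0L) stop("empty discharge table: ", path)
  for (col in intersect(c("admission_time", "discharge_time"), names(dt))) {
    dt[[col]] <- as.POSIXct(dt[[col]], format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
    if (anyNA(dt[[col]])) stop("unparseable ISO-8601 timestamps in ", col)
  }
  covs <- covariate_names(dt)
  for (col in covs) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    if (anyNA(v) && !anyNA(dt[[col]])) {
      stop("covariate column ", col, " is not numeric")
    }
    dt[[col]] <- v
  }
  as_discharge_table(dt)
}

#' Write a discharge table to CSV
#'
#' Deterministic formatting: canonical column order, rows sorted by
#' `(patient_id, discharge_index)`, timestamps as ISO-8601 UTC with second
#' precision, and floating-point covariates in shortest round-trippable
#' representation — identical tables produce identical bytes.
#'
#' @param table A discharge table.
#' @param path Output file path.
#' @param config Optional named list of generator/run parameters; when given,
#'   it is written as a YAML sidecar at `paste0(path, ".yml")`.
#' @return `path`, invisibly.
#' @export
write_discharge_table <- function(table, path, config = NULL) {
  table <- as_discharge_table(table)
  out <- as.data.frame(table)
  for (col in intersect(c("admission_time", "discharge_time"), names(out))) {
    out[[col]] <- format(out[[col]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  for (col in names(out)) {       # full-precision, parse-stable doubles
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  data.table::fwrite(out, path, sep = ",", quote = FALSE, eol = "\n",
                     scipen = 0L)
  if (!is.null(config)) {
    yaml::write_yaml(config, paste0(path, ".yml"))
  }
  invisible(path)
}
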