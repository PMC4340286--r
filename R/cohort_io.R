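#' Read a per-fraction couch-shift log
#'
#' Reads a CSV shift log with columns
#' `patient_id,fraction,modality,ap_cm,si_cm,lr_cm` into a validated
#' `cohort_shift_table`. Each row is one fraction's three-axis couch
#' displacement for one patient, registered against one reference modality
#' (`CT` or `MRI`). Displacements are signed and stored in cm; the sign
#' convention only has to be consistent within a table, since every
#' downstream statistic is covariant under a global sign flip.
#'
#' Files may declare units with a comment line `# units: mm` (or `cm`) before
#' the header, or by naming the shift columns `ap_mm,si_mm,lr_mm`;
#' millimetre values are converted to cm on read. Lines starting with `#`
#' are ignored otherwise. Missing shift values are kept as `NA` and dropped
#' per axis in downstream summaries (a warning reports how many cells were
#' missing).
#'
#' @param path path to a CSV file.
#' @param units `NULL` to take units from the file (default cm), or one of
#'   `"cm"`, `"mm"` to override.
#' @return a `cohort_shift_table`: a data frame with columns `patient_id`
#'   (character), `fraction` (integer), `modality` (character, `"CT"` or
#'   `"MRI"`), `ap_cm`, `si_cm`, `lr_cm` (numeric, cm).
#' @seealso [write_shift_table()], [summarize_patients()]
#' @export
read_shift_table <- function(path, units = NULL) {
  raw <- read_csv_checked(path, units)
  df <- raw$df
  need <- c("patient_id", "fraction", "modality")
  axis_cols <- paste0(AXES, "_", raw$units)
  missing_cols <- setdiff(c(need, axis_cols), names(df))
  if (length(missing_cols) > 0) {
    stop_schema("shift table %s is missing column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    fraction = df$fraction,
    modality = as.character(df$modality),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(AXES)) {
    out[[SHIFT_COLS[i]]] <- parse_shift_column(df[[axis_cols[i]]],
                                               axis_cols[i], path)
  }
  if (raw$units == "mm") {
    out[SHIFT_COLS] <- out[SHIFT_COLS] / 10
  }
  as_cohort_shift_table(out)
}

#' Construct and validate a cohort shift table
#'
#' Validates an in-memory shift log (see [read_shift_table()] for the
#' column contract) and stamps the `cohort_shift_table` class.
#'
#' @param x a data frame with columns `patient_id`, `fraction`, `modality`,
#'   `ap_cm`, `si_cm`, `lr_cm`.
#' @return the validated `cohort_shift_table`.
#' @export
as_cohort_shift_table <- function(x) {
  need <- c("patient_id", "fraction", "modality", SHIFT_COLS)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop_schema("shift table is missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  x$patient_id <- as.character(x$patient_id)
  x$modality <- as.character(x$modality)
  bad_mod <- setdiff(unique(x$modality), c("CT", "MRI"))
  if (length(bad_mod) > 0) {
    stop_validation("modality must be 'CT' or 'MRI'; found: %s",
                    paste(bad_mod, collapse = ", "))
  }
  frac <- suppressWarnings(as.integer(x$fraction))
  if (any(is.na(frac) != is.na(x$fraction)) || any(frac < 1, na.rm = TRUE)) {
    stop_validation("fraction indices must be positive integers")
  }
  x$fraction <- frac
  for (col in SHIFT_COLS) {
    v <- x[[col]]
    if (!is.numeric(v)) stop_validation("column %s must be numeric", col)
    if (any(is.infinite(v) | is.nan(v))) {
      stop_validation("column %s contains non-finite shifts", col)
    }
  }
  key <- paste(x$patient_id, x$fraction, x$modality, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- strsplit(key[which(dup)[1]], "\r", fixed = TRUE)[[1]]
    stop_validation(
      "duplicate record for patient '%s', fraction %s, modality %s",
      k[1], k[2], k[3])
  }
  n_missing <- sum(is.na(as.matrix(x[SHIFT_COLS])))
  if (n_missing > 0) {
    warning(sprintf(
      "%d missing shift value(s); dropped per axis in summaries", n_missing),
      call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("cohort_shift_table", "data.frame")
  x
}

#' Write a cohort shift table to CSV
#'
#' Inverse of [read_shift_table()]; `read_shift_table(write_shift_table(x))`
#' is the identity on validated tables.
#'
#' @param x a `cohort_shift_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(x, path) {
  stopifnot(inherits(x, "cohort_shift_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-patient shift summary table
#'
#' Reads pre-summarized per-patient statistics (the form in which published
#' cohort tables report shift data: one mean +/- SD cell per patient, axis
#' and modality) with columns
#' `patient_id,modality,ap_mean,ap_sd,si_mean,si_sd,lr_mean,lr_sd,n_fractions`.
#' `n_fractions` may be blank when unknown. Values are in cm unless the file
#' declares `# units: mm`.
#'
#' @param path path to a CSV file.
#' @return a `patient_summaries` data frame, sorted by modality then
#'   patient id.
#' @seealso [summarize_patients()] for computing summaries from raw
#'   fractions; [fixture_path()] for the bundled cohort fixtures.
#' @export
read_summary_table <- function(path) {
  raw <- read_csv_checked(path, units = NULL)
  df <- raw$df
  need <- c("patient_id", "modality",
            paste0(rep(AXES, each = 2), c("_mean", "_sd")), "n_fractions")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_schema("summary table %s is missing column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  num_cols <- setdiff(need, c("patient_id", "modality"))
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if (raw$units == "mm") {
    cm_cols <- setdiff(num_cols, "n_fractions")
    df[cm_cols] <- df[cm_cols] / 10
  }
  df$patient_id <- as.character(df$patient_id)
  df$modality <- as.character(df$modality)
  as_patient_summaries(df[need])
}

# Validate and class a per-patient summary table.
as_patient_summaries <- function(x) {
  bad_mod <- setdiff(unique(x$modality), c("CT", "MRI"))
  if (length(bad_mod) > 0) {
    stop_validation("modality must be 'CT' or 'MRI'; found: %s",
                    paste(bad_mod, collapse = ", "))
  }
  sd_cols <- paste0(AXES, "_sd")
  if (any(as.matrix(x[sd_cols]) < 0, na.rm = TRUE)) {
    stop_validation("per-patient SDs must be >= 0")
  }
  key <- paste(x$patient_id, x$modality)
  if (anyDuplicated(key)) {
    stop_validation("duplicate patient/modality row: %s",
                    key[duplicated(key)][1])
  }
  x <- x[order(x$modality, x$patient_id), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("patient_summaries", "data.frame")
  x
}

#' Read a paired two-modality measurement table
#'
#' Reads per-patient paired scalar measurements (structure volumes in cc or
#' dose metrics in Gy, one value per modality) with columns
#' `patient_id,structure_or_metric,value_mri,value_ct`. All values must be
#' strictly positive; each patient may appear once per structure or metric.
#'
#' @param path path to a CSV file.
#' @param quantity what the values are: `"volume_cc"` or `"dose_gy"`.
#' @return a `paired_measurements` data frame with attribute `quantity`.
#' @seealso [compare_paired()]
#' @export
read_paired_table <- function(path, quantity = c("volume_cc", "dose_gy")) {
  quantity <- match.arg(quantity)
  raw <- read_csv_checked(path, units = NULL)
  df <- raw$df
  need <- c("patient_id", "structure_or_metric", "value_mri", "value_ct")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_schema("paired table %s is missing column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  df <- df[need]
  df$patient_id <- as.character(df$patient_id)
  df$structure_or_metric <- as.character(df$structure_or_metric)
  for (col in c("value_mri", "value_ct")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(df[[col]]))) {
      stop_validation("non-numeric %s value in %s", col, path)
    }
  }
  as_paired_measurements(df, quantity)
}

# Validate and class a paired measurement table.
as_paired_measurements <- function(x, quantity) {
  bad <- !is.finite(x$value_mri) | !is.finite(x$value_ct) |
    x$value_mri <= 0 | x$value_ct <= 0
  if (any(bad)) {
    stop_validation("non-positive measurement for patient '%s' (%s)",
                    x$patient_id[bad][1], x$structure_or_metric[bad][1])
  }
  key <- paste(x$patient_id, x$structure_or_metric)
  if (anyDuplicated(key)) {
    stop_validation("patient '%s' appears twice for '%s'",
                    x$patient_id[duplicated(key)][1],
                    x$structure_or_metric[duplicated(key)][1])
  }
  x <- as.data.frame(x)
  rownames(x) <- NULL
  attr(x, "quantity") <- quantity
  class(x) <- c("paired_measurements", "data.frame")
  x
}

#' Summarize daily shifts per patient
#'
#' Collapses a per-fraction shift log to per-patient, per-axis mean and
#' sample SD (n - 1 divisor) for one reference modality — the per-patient
#' statistics on which the population error decomposition operates. Missing
#' shift values are dropped per axis. Patients with fewer than two fractions
#' have no defined SD and are excluded with a warning (or an error, if
#' requested).
#'
#' @param table a `cohort_shift_table`.
#' @param modality `"CT"` or `"MRI"`.
#' @param on_few_fractions `"warn"` (default) to drop patients with < 2
#'   fractions, `"error"` to fail.
#' @return a `patient_summaries` data frame sorted by patient id.
#' @export
summarize_patients <- function(table, modality = c("CT", "MRI"),
                               on_few_fractions = c("warn", "error")) {
  stopifnot(inherits(table, "cohort_shift_table"))
  modality <- match.arg(modality)
  on_few_fractions <- match.arg(on_few_fractions)
  sub <- table[table$modality == modality, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_insufficient("no records for modality %s", modality)
  }
  ids <- sort(unique(sub$patient_id))
  rows <- lapply(ids, function(id) {
    rec <- sub[sub$patient_id == id, , drop = FALSE]
    if (nrow(rec) < 2) {
      if (on_few_fractions == "error") {
        stop_insufficient("patient '%s' has %d fraction(s); need >= 2",
                          id, nrow(rec))
      }
      warning(sprintf("patient '%s' excluded: %d fraction(s) under %s",
                      id, nrow(rec), modality), call. = FALSE)
      return(NULL)
    }
    out <- data.frame(patient_id = id, modality = modality,
                      stringsAsFactors = FALSE)
    for (i in seq_along(AXES)) {
      v <- rec[[SHIFT_COLS[i]]]
      out[[paste0(AXES[i], "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(AXES[i], "_sd")]] <- sample_sd(v)
    }
    out$n_fractions <- nrow(rec)
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    stop_insufficient("no patient with >= 2 fractions under %s", modality)
  }
  as_patient_summaries(do.call(rbind, rows))
}

#' Path to a bundled cohort fixture
#'
#' The package ships the per-patient rows of a ten-patient open-MRI prostate
#' simulation cohort as plain-text fixtures:
#' \describe{
#'   \item{`table4_patient_summaries.csv`}{per-patient daily-shift mean and
#'     SD per axis, for CT-reference and MRI-reference CBCT registration
#'     (9 patients x 2 modalities; one patient was not evaluable).}
#'   \item{`table2_volumes.csv`}{paired MRI/CT structure volumes (cc) for
#'     prostate, seminal vesicles, penile bulb and CTV (10 patients).}
#'   \item{`table3_doses.csv`}{paired MRI/CT plan dose metrics (Gy): plan
#'     maximum, D99 and D95 (9 patients).}
#' }
#'
#' @param name fixture file name; with no argument, lists available fixtures.
#' @return a file path, or a character vector of fixture names.
#' @examples
#' read_summary_table(fixture_path("table4_patient_summaries.csv"))
#' @export
fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "setupmargins")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop_validation("no bundled fixture '%s'; available: %s", name,
                    paste(list.files(dir), collapse = ", "))
  }
  path
}

#' Bulk electron-density assignment used for MRI-based dose calculation
#'
#' The uniform CT numbers substituted for contoured tissue classes when a
#' plan is recalculated on MRI (which carries no electron-density
#' information): bone 480 HU, soft tissue 0 HU (water equivalent), air
#' -1000 HU. Recorded as documented constants; this package performs no
#' dose calculation.
#'
#' @return named numeric vector of Hounsfield units.
#' @export
bulk_density_map <- function() {
  c(bone = 480, soft_tissue = 0, air = -1000)
}

# Shared CSV reader: skips '#' comment lines, honours a '# units:' line,
# checks the file exists and has a header.
read_csv_checked <- function(path, units) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  unit_line <- grep("^#\\s*units\\s*:", head_lines, value = TRUE)
  file_units <- if (length(unit_line) > 0) {
    trimws(sub("^#\\s*units\\s*:", "", unit_line[1]))
  }
  if (is.null(units)) units <- file_units
  if (is.null(units)) units <- "cm"
  if (!units %in% c("cm", "mm")) {
    stop_schema("units must be 'cm' or 'mm', got '%s'", units)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        strip.white = TRUE)
  list(df = df, units = units)
}

# Parse one shift column; non-numeric text is a validation error, empty
# cells become NA.
parse_shift_column <- function(v, col, path) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- trimws(as.character(v))
  v[v == ""] <- NA
  num <- suppressWarnings(as.numeric(v))
  bad <- !is.na(v) & is.na(num)
  if (any(bad)) {
    stop_validation("non-numeric shift '%s' in column %s of %s",
                    v[bad][1], col, path)
  }
  num
}

#' @export
print.cohort_shift_table <- function(x, ...) {
  cat(sprintf("Cohort shift table: %d records, %d patient(s), modalities: %s\n",
              nrow(x), length(unique(x$patient_id)),
              paste(sort(unique(x$modality)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
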