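#' Compare couch shifts between two reference modalities
#'
#' For patients imaged against both reference datasets (CT and MRI), computes
#' the per-patient difference of mean daily shifts (MRI - CT) on each axis,
#' and the cohort mean and sample SD of those differences. The pairing level
#' is `"patient_mean"`: differences of per-patient mean shifts, which is what
#' published summary tables make recoverable. (Per-fraction pairing would
#' need the raw fraction-level shift pairs; when you have them, pair the two
#' `cohort_shift_table`s yourself and summarize the per-fraction differences.)
#'
#' @param summaries_ct `patient_summaries` for the CT reference.
#' @param summaries_mri `patient_summaries` for the MRI reference.
#' @return a `modality_comparison` object: list with `per_patient` (data
#'   frame of per-patient mean differences, cm), `cohort_mean` and
#'   `cohort_sd` (named per-axis vectors, cm), `n`, and
#'   `pairing_level = "patient_mean"`.
#' @examples
#' summ <- read_summary_table(fixture_path("table4_patient_summaries.csv"))
#' compare_modalities(summ[summ$modality == "CT", ],
#'                    summ[summ$modality == "MRI", ])
#' @export
compare_modalities <- function(summaries_ct, summaries_mri) {
  stopifnot(is.data.frame(summaries_ct), is.data.frame(summaries_mri))
  common <- intersect(summaries_ct$patient_id, summaries_mri$patient_id)
  if (length(common) < 2) {
    stop_insufficient(
      "modality comparison needs >= 2 patients under both modalities; have %d",
      length(common))
  }
  common <- sort(common)
  ct <- summaries_ct[match(common, summaries_ct$patient_id), , drop = FALSE]
  mri <- summaries_mri[match(common, summaries_mri$patient_id), , drop = FALSE]
  per_patient <- data.frame(patient_id = common, stringsAsFactors = FALSE)
  for (a in AXES) {
    col <- paste0(a, "_mean")
    per_patient[[a]] <- mri[[col]] - ct[[col]]
  }
  cohort_mean <- vapply(AXES, function(a) mean(per_patient[[a]]), numeric(1))
  cohort_sd <- vapply(AXES, function(a) stats::sd(per_patient[[a]]),
                      numeric(1))
  structure(
    list(per_patient = per_patient, cohort_mean = cohort_mean,
         cohort_sd = cohort_sd, n = length(common),
         pairing_level = "patient_mean"),
    class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat(sprintf(
    "Shift differences MRI - CT (%d patients, pairing level: %s)\n",
    x$n, x$pairing_level))
  for (a in AXES) {
    cat(sprintf("  %s: %+.2f +/- %.2f cm\n", toupper(a),
                round_away(x$cohort_mean[[a]], 2),
                round_away(x$cohort_sd[[a]], 2)))
  }
  invisible(x)
}

#' Read a registration-repeat log
#'
#' Repeated registrations of the same image pair, used to quantify
#' registration reproducibility. Columns: `task_id,repeat,ap_cm,si_cm,lr_cm`
#' (one row per repeat of one registration task).
#'
#' @param path path to a CSV file.
#' @return a data frame with columns `task_id`, `repeat_index`, `ap_cm`,
#'   `si_cm`, `lr_cm`.
#' @export
read_repeats_table <- function(path) {
  raw <- read_csv_checked(path, units = NULL)
  df <- raw$df
  names(df)[names(df) == "repeat."] <- "repeat"  # read.csv mangles 'repeat'
  need <- c("task_id", "repeat", SHIFT_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_schema("repeats table %s is missing column(s): %s",
                path, paste(miss, collapse = ", "))
  }
  out <- data.frame(task_id = as.character(df$task_id),
                    repeat_index = as.integer(df[["repeat"]]),
                    stringsAsFactors = FALSE)
  for (col in SHIFT_COLS) out[[col]] <- as.numeric(df[[col]])
  if (raw$units == "mm") out[SHIFT_COLS] <- out[SHIFT_COLS] / 10
  out
}

#' Registration reproducibility
#'
#' Pooled per-axis SD of repeated registrations: the square root of the mean
#' within-task sample variance, over tasks with at least two repeats. This
#' estimates the operator/algorithm reproducibility of the manual
#' registration itself, independent of true patient displacement.
#'
#' @param repeats a data frame as returned by [read_repeats_table()] (or any
#'   data frame with columns `task_id`, `ap_cm`, `si_cm`, `lr_cm`).
#' @return named numeric vector: pooled SD per axis (`ap`, `si`, `lr`), cm.
#' @export
registration_reproducibility <- function(repeats) {
  stopifnot(is.data.frame(repeats))
  need <- c("task_id", SHIFT_COLS)
  miss <- setdiff(need, names(repeats))
  if (length(miss) > 0) {
    stop_schema("repeats need column(s): %s", paste(miss, collapse = ", "))
  }
  counts <- table(repeats$task_id)
  usable <- names(counts)[counts >= 2]
  if (length(usable) == 0) {
    stop_insufficient("every task has a single repeat; need >= 2 for >= 1 task")
  }
  out <- vapply(AXES, function(a) {
    v <- repeats[[paste0(a, "_cm")]]
    vars <- vapply(usable, function(id) {
      stats::var(v[repeats$task_id == id])
    }, numeric(1))
    sqrt(mean(vars))
  }, numeric(1))
  names(out) <- AXES
  out
}
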