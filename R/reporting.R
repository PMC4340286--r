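#' Run the full cohort analysis pipeline
#'
#' Ties the stages together: per-modality setup-error decomposition and
#' margins, CT-vs-MRI shift-difference summary (when both modalities are
#' present), and paired volume and dose comparisons. Any input may be
#' omitted; at least one stage must be runnable.
#'
#' @param shifts a `patient_summaries` table (possibly covering both
#'   modalities) or a `cohort_shift_table`; `NULL` to skip the shift stages.
#' @param volumes a `paired_measurements` table of structure volumes, or
#'   `NULL`.
#' @param doses a `paired_measurements` table of dose metrics, or `NULL`.
#' @param exclude patient ids excluded from the decomposition (all four
#'   statistics); recorded in the report.
#' @param rounding margin rounding mode, see [decompose_setup_error()].
#' @return an `analysis_report`: list with `decompositions` (per modality),
#'   `modality_comparison`, `volumes`, `doses`, and a `provenance` block
#'   (package version, options, input summary, a hash of the report body).
#' @examples
#' summ <- read_summary_table(fixture_path("table4_patient_summaries.csv"))
#' vols <- read_paired_table(fixture_path("table2_volumes.csv"), "volume_cc")
#' run_pipeline(shifts = summ, volumes = vols)
#' @export
run_pipeline <- function(shifts = NULL, volumes = NULL, doses = NULL,
                         exclude = character(),
                         rounding = c("table", "raw")) {
  rounding <- match.arg(rounding)
  if (is.null(shifts) && is.null(volumes) && is.null(doses)) {
    stop_insufficient(paste(
      "nothing to analyze: all stages missing their inputs",
      "(shifts: none; volumes: none; doses: none)"))
  }
  warnings_seen <- character()
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  report <- withCallingHandlers({
    decompositions <- NULL
    mod_cmp <- NULL
    if (!is.null(shifts)) {
      if (inherits(shifts, "cohort_shift_table")) {
        mods <- sort(unique(shifts$modality))
        summaries <- do.call(rbind, lapply(mods, function(m) {
          summarize_patients(shifts, m)
        }))
        summaries <- as_patient_summaries(summaries)
      } else {
        summaries <- shifts
        mods <- sort(unique(summaries$modality))
      }
      decompositions <- lapply(stats::setNames(mods, mods), function(m) {
        decompose_setup_error(summaries, m, exclude = exclude,
                              rounding = rounding)
      })
      if (all(c("CT", "MRI") %in% mods)) {
        mod_cmp <- compare_modalities(
          summaries[summaries$modality == "CT", ],
          summaries[summaries$modality == "MRI", ])
      }
    }
    list(
      decompositions = decompositions,
      modality_comparison = mod_cmp,
      volumes = if (!is.null(volumes)) compare_paired(volumes),
      doses = if (!is.null(doses)) compare_paired(doses))
  }, warning = note)
  body <- report_body_json(report)
  report$provenance <- list(
    package = "setupmargins",
    version = as.character(utils::packageVersion("setupmargins")),
    rounding = rounding,
    excluded_patients = as.character(exclude),
    inputs = list(
      shifts = !is.null(shifts), volumes = !is.null(volumes),
      doses = !is.null(doses)),
    warnings = warnings_seen,
    body_md5 = md5_of_string(body))
  class(report) <- "analysis_report"
  report
}

# Canonical JSON of the numerical report body (no provenance, no
# timestamps) — the hashed, reproducibility-bearing part.
report_body_json <- function(report) {
  ser <- list(
    decompositions = lapply(report$decompositions, function(d) {
      list(modality = d$modality, axes = d$axes, n_patients = d$n_patients,
           excluded = d$excluded, rounding = d$rounding)
    }),
    modality_comparison = if (!is.null(report$modality_comparison)) {
      m <- report$modality_comparison
      list(per_patient = m$per_patient,
           cohort_mean = as.list(m$cohort_mean),
           cohort_sd = as.list(m$cohort_sd),
           n = m$n, pairing_level = m$pairing_level)
    },
    volumes = strip_attrs(report$volumes),
    doses = strip_attrs(report$doses))
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
}

strip_attrs <- function(x) {
  if (is.null(x)) return(NULL)
  as.data.frame(x)
}

md5_of_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Write an analysis report to disk
#'
#' JSON output carries the full-precision report body plus the provenance
#' block; CSV output writes one file per stage next to `path` (suffixes
#' `_margins.csv`, `_modality.csv`, `_volumes.csv`, `_doses.csv`). Reports
#' are deterministic: identical inputs give byte-identical JSON.
#'
#' @param report an `analysis_report`.
#' @param path output path (for CSV, the stem).
#' @param format `"json"` or `"csv"`.
#' @return the path(s) written, invisibly.
#' @export
write_analysis_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  if (format == "json") {
    body <- jsonlite::fromJSON(report_body_json(report),
                               simplifyVector = FALSE)
    body$provenance <- report$provenance
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(path))
  }
  stem <- sub("\\.csv$", "", path)
  written <- character()
  if (!is.null(report$decompositions)) {
    tab <- do.call(rbind, lapply(report$decompositions, as.data.frame))
    f <- paste0(stem, "_margins.csv")
    utils::write.csv(format_cm(tab), f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if (!is.null(report$modality_comparison)) {
    m <- report$modality_comparison
    tab <- data.frame(axis = AXES,
                      mean_diff_cm = round_away(unname(m$cohort_mean), 2),
                      sd_cm = round_away(unname(m$cohort_sd), 2),
                      n = m$n, pairing_level = m$pairing_level)
    f <- paste0(stem, "_modality.csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  for (stage in c("volumes", "doses")) {
    if (is.null(report[[stage]])) next
    tab <- as.data.frame(report[[stage]])
    tab$mean_pct_diff <- round_away(tab$mean_pct_diff, 1)
    tab$sd_pct_diff <- round_away(tab$sd_pct_diff, 1)
    tab$p_value <- round_away(tab$p_value, 3)
    f <- paste0(stem, "_", stage, ".csv")
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

format_cm <- function(tab) {
  for (col in c("M", "Sigma", "sigma", "margin")) {
    tab[[col]] <- round_away(tab[[col]], 2)
  }
  tab
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Cohort analysis report ==\n")
  for (d in x$decompositions) {
    print(d)
    cat("\n")
  }
  if (!is.null(x$modality_comparison)) {
    print(x$modality_comparison)
    cat("\n")
  }
  if (!is.null(x$volumes)) {
    print(x$volumes)
    cat("\n")
  }
  if (!is.null(x$doses)) {
    print(x$doses)
    cat("\n")
  }
  pv <- x$provenance
  cat(sprintf("provenance: %s %s, rounding=%s%s, body md5 %s\n",
              pv$package, pv$version, pv$rounding,
              if (length(pv$excluded_patients) > 0) {
                paste0(", excluded: ",
                       paste(pv$excluded_patients, collapse = ","))
              } else "",
              pv$body_md5))
  if (length(pv$warnings) > 0) {
    cat("warnings:\n")
    for (w in pv$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}
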