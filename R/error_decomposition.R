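#' @name error_decomposition
#' @title Population setup-error statistics
#'
#' @description
#' The population decomposition of daily setup errors follows the standard
#' image-guidance recipe. For each axis:
#' \describe{
#'   \item{M, group mean error}{the mean over patients of the per-patient
#'     mean daily shift — a cohort-wide directional bias.}
#'   \item{Sigma, systematic (inter-patient) uncertainty}{the sample SD
#'     (n - 1 divisor) over patients of the per-patient mean shifts.}
#'   \item{sigma, random (inter-fraction) uncertainty}{the root mean square
#'     (divisor = number of patients) of the per-patient daily-shift SDs.}
#' }
#' Each patient contributes one mean and one SD regardless of fraction
#' count (patients are weighted equally).
#'
#' @param summaries a `patient_summaries` data frame for one modality (see
#'   [summarize_patients()] / [read_summary_table()]).
#' @param axis one of `"ap"`, `"si"`, `"lr"`.
NULL

# Pull one modality's per-patient means or SDs, dropping NAs.
axis_stat <- function(summaries, axis, what = c("mean", "sd")) {
  axis <- match.arg(axis, AXES)
  what <- match.arg(what)
  v <- summaries[[paste0(axis, "_", what)]]
  v[!is.na(v)]
}

#' @describeIn error_decomposition group mean error M (cm).
#' @export
group_mean <- function(summaries, axis) {
  m <- axis_stat(summaries, axis, "mean")
  if (length(m) < 1) stop_insufficient("no patient means for axis %s", axis)
  mean(m)
}

#' @describeIn error_decomposition systematic uncertainty Sigma (cm): sample
#'   SD of per-patient mean shifts. Requires >= 2 patients.
#' @export
systematic_uncertainty <- function(summaries, axis) {
  m <- axis_stat(summaries, axis, "mean")
  if (length(m) < 2) {
    stop_insufficient("Sigma needs >= 2 patients; have %d", length(m))
  }
  stats::sd(m)
}

#' @describeIn error_decomposition random uncertainty sigma (cm): RMS of
#'   per-patient daily-shift SDs. Requires >= 1 patient with a defined SD;
#'   zero-variance patients contribute 0 to the RMS.
#' @export
random_uncertainty <- function(summaries, axis) {
  s <- axis_stat(summaries, axis, "sd")
  if (length(s) < 1) stop_insufficient("no defined SDs for axis %s", axis)
  sqrt(mean(s^2))
}

#' Van Herk CTV-to-PTV margin
#'
#' The margin recipe `2.5 * Sigma + 0.7 * sigma`, designed so that 90% of
#' the patient population receives at least 95% of the prescribed dose to
#' the CTV: the 2.5 coefficient covers the 90th percentile of a 3D Gaussian
#' systematic-error distribution (see [coverage_monte_carlo()]) and the 0.7
#' coefficient accounts for the blurring of the dose distribution by random
#' day-to-day errors.
#'
#' @param Sigma systematic uncertainty, cm (>= 0).
#' @param sigma random uncertainty, cm (>= 0).
#' @param coefficients the two margin coefficients; the defaults
#'   `c(2.5, 0.7)` are the standard population recipe.
#' @return margin in cm; vectorized over `Sigma`/`sigma`.
#' @examples
#' van_herk_margin(0.24, 0.38) # 0.866
#' @export
van_herk_margin <- function(Sigma, sigma, coefficients = c(2.5, 0.7)) {
  check_numeric(Sigma, "Sigma")
  check_numeric(sigma, "sigma")
  if (any(Sigma < 0) || any(sigma < 0)) {
    stop_domain("Sigma and sigma must be >= 0")
  }
  check_numeric(coefficients, "coefficients")
  stopifnot(length(coefficients) == 2)
  coefficients[1] * Sigma + coefficients[2] * sigma
}

#' Decompose a cohort's setup errors and compute per-axis margins
#'
#' Computes M, Sigma, sigma and the van Herk margin on each axis for one
#' reference modality, optionally excluding patients (an excluded patient is
#' removed from all four statistics).
#'
#' `rounding = "table"` rounds Sigma and sigma to two decimals (half away
#' from zero) before applying the margin formula, then rounds the margin to
#' two decimals — the convention used when reporting margins in clinical
#' tables, and the mode under which this package reproduces its bundled
#' cohort's published margin row. `rounding = "raw"` keeps full precision,
#' so `margin == 2.5 * Sigma + 0.7 * sigma` holds exactly.
#'
#' @param x a `cohort_shift_table` (summarized internally) or a
#'   `patient_summaries` data frame.
#' @param modality `"CT"` or `"MRI"`; may be omitted when `x` contains a
#'   single modality.
#' @param exclude character vector of patient ids to drop.
#' @param rounding `"table"` (default, report convention) or `"raw"`.
#' @param coefficients margin coefficients, passed to [van_herk_margin()].
#' @return an `error_decomposition` object: list with `modality`, `axes` (a
#'   data frame with one row per axis and columns `M`, `Sigma`, `sigma`,
#'   `margin`, all cm), `n_patients`, `excluded`, `rounding`.
#' @examples
#' summ <- read_summary_table(fixture_path("table4_patient_summaries.csv"))
#' decompose_setup_error(summ, "CT")
#' @export
decompose_setup_error <- function(x, modality = NULL, exclude = character(),
                                  rounding = c("table", "raw"),
                                  coefficients = c(2.5, 0.7)) {
  rounding <- match.arg(rounding)
  if (inherits(x, "cohort_shift_table")) {
    if (is.null(modality)) {
      mods <- unique(x$modality)
      if (length(mods) != 1) {
        stop_validation("table has modalities %s; pick one",
                        paste(mods, collapse = ", "))
      }
      modality <- mods
    }
    summaries <- summarize_patients(x, modality)
  } else if (inherits(x, "patient_summaries") || is.data.frame(x)) {
    summaries <- x
    if (is.null(modality)) {
      mods <- unique(summaries$modality)
      if (length(mods) != 1) {
        stop_validation("summaries cover modalities %s; pick one",
                        paste(mods, collapse = ", "))
      }
      modality <- mods
    }
    summaries <- summaries[summaries$modality == modality, , drop = FALSE]
  } else {
    stop_validation("x must be a cohort_shift_table or patient_summaries")
  }
  summaries <- summaries[!(summaries$patient_id %in% exclude), , drop = FALSE]
  if (nrow(summaries) < 2) {
    stop_insufficient(
      "decomposition needs >= 2 patients after exclusion; have %d",
      nrow(summaries))
  }
  axes <- do.call(rbind, lapply(AXES, function(a) {
    M <- group_mean(summaries, a)
    Sig <- systematic_uncertainty(summaries, a)
    sig <- random_uncertainty(summaries, a)
    if (rounding == "table") {
      M <- round_away(M, 2)
      Sig <- round_away(Sig, 2)
      sig <- round_away(sig, 2)
      marg <- round_away(van_herk_margin(Sig, sig, coefficients), 2)
    } else {
      marg <- van_herk_margin(Sig, sig, coefficients)
    }
    data.frame(axis = a, M = M, Sigma = Sig, sigma = sig, margin = marg,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(modality = modality, axes = axes,
         n_patients = nrow(summaries),
         excluded = as.character(exclude), rounding = rounding,
         coefficients = coefficients),
    class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf(
    "Setup-error decomposition (%s reference, %d patients%s, rounding=%s)\n",
    x$modality, x$n_patients,
    if (length(x$excluded) > 0) {
      sprintf(", excluding %s", paste(x$excluded, collapse = ", "))
    } else "",
    x$rounding))
  tab <- x$axes
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.2f", round_away(v, 2)))
  names(tab) <- c("axis", "M (cm)", "Sigma (cm)", "sigma (cm)", "margin (cm)")
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.error_decomposition <- function(x, ...) {
  out <- x$axes
  out$modality <- x$modality
  out[c("modality", "axis", "M", "Sigma", "sigma", "margin")]
}
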