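#' Percent difference of a paired measurement, CT relative to MRI
#'
#' `100 * (value_ct - value_mri) / value_mri`: how much larger (positive) or
#' smaller (negative) the CT-based measurement is than the MRI-based one,
#' as a percentage of the MRI value. Scale-invariant: multiplying both
#' values by the same positive factor leaves the result unchanged.
#'
#' @param value_mri MRI-based measurement (> 0); the denominator.
#' @param value_ct CT-based measurement.
#' @return percent difference; vectorized.
#' @examples
#' percent_difference(84.20, 117.60) # ~ 39.7
#' percent_difference(50, 25)        # -50
#' @export
percent_difference <- function(value_mri, value_ct) {
  check_numeric(value_mri, "value_mri")
  check_numeric(value_ct, "value_ct")
  if (any(value_mri <= 0)) {
    stop_domain("value_mri must be > 0 (it is the denominator)")
  }
  100 * (value_ct - value_mri) / value_mri
}

#' Paired two-modality comparison of volumes or dose metrics
#'
#' For each structure or metric: the per-patient percent differences (CT
#' relative to MRI, see [percent_difference()]) with their cohort mean and
#' sample SD, and a two-sided paired t-test on the raw paired values
#' (d = CT - MRI, t = dbar / (s_d / sqrt(n)), n - 1 degrees of freedom).
#' Note the convention: percent differences are averaged per patient
#' (a mean of ratios, not a ratio of means), while the t-test is on the raw
#' values, not the percentages.
#'
#' Degenerate pairs (s_d = 0) cannot support a t-test: the result row is
#' flagged `degenerate` with p = 1 when all differences are zero and p = 0
#' when they are a nonzero constant.
#'
#' @param table a `paired_measurements` data frame (see
#'   [read_paired_table()]).
#' @param structure_or_metric restrict to one structure/metric label;
#'   default all present.
#' @return a `paired_comparison` data frame, one row per structure/metric:
#'   `structure_or_metric`, `n`, `mean_pct_diff`, `sd_pct_diff`, `t`, `df`,
#'   `p_value`, `degenerate`. Per-patient percent differences are in
#'   attribute `"per_patient"`.
#' @examples
#' vols <- read_paired_table(fixture_path("table2_volumes.csv"), "volume_cc")
#' compare_paired(vols, "prostate")
#' @export
compare_paired <- function(table, structure_or_metric = NULL) {
  stopifnot(inherits(table, "paired_measurements") || is.data.frame(table))
  labels <- unique(table$structure_or_metric)
  if (!is.null(structure_or_metric)) {
    missing_lab <- setdiff(structure_or_metric, labels)
    if (length(missing_lab) > 0) {
      stop_validation("no rows for '%s'", missing_lab[1])
    }
    labels <- structure_or_metric
  }
  per_patient <- list()
  rows <- lapply(labels, function(lab) {
    sub <- table[table$structure_or_metric == lab, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) {
      stop_insufficient("'%s' has %d pair(s); paired test needs >= 2", lab, n)
    }
    pct <- percent_difference(sub$value_mri, sub$value_ct)
    per_patient[[lab]] <<- data.frame(patient_id = sub$patient_id,
                                      pct_diff = pct,
                                      stringsAsFactors = FALSE)
    d <- sub$value_ct - sub$value_mri
    s_d <- stats::sd(d)
    if (s_d == 0) {
      degenerate <- TRUE
      tstat <- NA_real_
      p <- if (mean(d) == 0) 1 else 0
    } else {
      degenerate <- FALSE
      ht <- stats::t.test(sub$value_ct, sub$value_mri, paired = TRUE)
      tstat <- unname(ht$statistic)
      p <- ht$p.value
    }
    data.frame(structure_or_metric = lab, n = n,
               mean_pct_diff = mean(pct), sd_pct_diff = stats::sd(pct),
               t = tstat, df = n - 1L, p_value = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_patient") <- per_patient
  attr(out, "quantity") <- attr(table, "quantity")
  class(out) <- c("paired_comparison", "data.frame")
  out
}

#' @export
print.paired_comparison <- function(x, ...) {
  qty <- attr(x, "quantity")
  cat(sprintf("Paired CT vs MRI comparison%s\n",
              if (!is.null(qty)) paste0(" (", qty, ")") else ""))
  tab <- data.frame(
    structure_or_metric = x$structure_or_metric,
    n = x$n,
    `mean %diff` = sprintf("%.1f", round_away(x$mean_pct_diff, 1)),
    `SD %` = sprintf("%.1f", round_away(x$sd_pct_diff, 1)),
    p = ifelse(x$degenerate, sprintf("%.0f*", x$p_value),
               sprintf("%.3f", round_away(x$p_value, 3))),
    check.names = FALSE)
  print.data.frame(tab, row.names = FALSE)
  if (any(x$degenerate)) cat("* degenerate: zero variance of differences\n")
  invisible(x)
}
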