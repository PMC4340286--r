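# Independent brute-force oracles, kept deliberately naive: explicit loops
# and quadrature, no reuse of the package's code paths.

# Sample SD of per-patient means, from first principles.
oracle_systematic <- function(means) {
  n <- length(means)
  mu <- sum(means) / n
  ss <- 0
  for (m in means) ss <- ss + (m - mu)^2
  sqrt(ss / (n - 1))
}

# RMS of per-patient SDs, divisor = number of patients.
oracle_random <- function(sds) {
  ss <- 0
  for (s in sds) ss <- ss + s^2
  sqrt(ss / length(sds))
}

# Streaming (Welford) mean and sample variance.
oracle_welford <- function(x) {
  n <- 0
  mean <- 0
  m2 <- 0
  for (v in x) {
    n <- n + 1
    d <- v - mean
    mean <- mean + d / n
    m2 <- m2 + d * (v - mean)
  }
  list(mean = mean, sd = if (n >= 2) sqrt(m2 / (n - 1)) else NA_real_)
}

# Two-sided paired t-test: explicit formula plus a numerically integrated
# Student-t CDF (no call to pt()).
oracle_paired_t <- function(ct, mri) {
  d <- ct - mri
  n <- length(d)
  dbar <- sum(d) / n
  s_d <- oracle_systematic(d)  # sample SD of the differences
  t <- dbar / (s_d / sqrt(n))
  df <- n - 1
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
  list(t = t, df = df, p = 2 * tail)
}

# Build a plain per-patient summary data frame (decompose_setup_error and
# compare_modalities accept any data frame with the summary columns).
make_summaries <- function(ids, modality, ap_mean, ap_sd,
                           si_mean = ap_mean, si_sd = ap_sd,
                           lr_mean = ap_mean, lr_sd = ap_sd) {
  data.frame(patient_id = as.character(ids), modality = modality,
             ap_mean = ap_mean, ap_sd = ap_sd,
             si_mean = si_mean, si_sd = si_sd,
             lr_mean = lr_mean, lr_sd = lr_sd,
             n_fractions = NA_integer_, stringsAsFactors = FALSE)
}

# Random raw shift log as a plain data frame -> cohort_shift_table.
random_shift_log <- function(n_patients, n_fractions, modality = "CT") {
  df <- expand.grid(fraction = seq_len(n_fractions),
                    patient_id = sprintf("P%02d", seq_len(n_patients)),
                    stringsAsFactors = FALSE)
  df$modality <- modality
  df$ap_cm <- stats::rnorm(nrow(df), 0, 0.4)
  df$si_cm <- stats::rnorm(nrow(df), 0, 0.4)
  df$lr_cm <- stats::rnorm(nrow(df), 0, 0.4)
  as_cohort_shift_table(df)
}

# The bundled cohort fixtures, loaded once per test file.
load_table4 <- function() {
  read_summary_table(fixture_path("table4_patient_summaries.csv"))
}
load_table2 <- function() {
  read_paired_table(fixture_path("table2_volumes.csv"), "volume_cc")
}
load_table3 <- function() {
  read_paired_table(fixture_path("table3_doses.csv"), "dose_gy")
}
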