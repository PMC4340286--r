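test_that("generation is deterministic under config + seed and leaves the
           caller's RNG untouched", {
  cfg <- synthetic_cohort_config(n_patients = 5, n_fractions = 6, seed = 42L)
  set.seed(999)
  before <- .Random.seed
  a <- simulate_shift_log(cfg)
  expect_identical(.Random.seed, before)
  b <- simulate_shift_log(cfg)
  expect_identical(a, b)

  pair <- simulate_paired_modality_log(cfg)
  pair2 <- simulate_paired_modality_log(cfg)
  expect_identical(pair, pair2)

  other <- simulate_shift_log(synthetic_cohort_config(
    n_patients = 5, n_fractions = 6, seed = 43L))
  expect_false(identical(a$ap_cm, other$ap_cm))
})

test_that("config validation rejects impossible parameterizations", {
  expect_error(synthetic_cohort_config(n_patients = 1),
               class = "validation_error")
  expect_error(synthetic_cohort_config(n_fractions = 1),
               class = "validation_error")
  expect_error(synthetic_cohort_config(systematic_sd = -0.1),
               class = "validation_error")
  expect_error(
    synthetic_cohort_config(volume_model = list(
      x = list(meanlog = 1, sdlog = 0.1, delta_mean = -1.5,
               delta_sd = 0.1))),
    class = "validation_error")
})

test_that("zero-variance config produces shifts equal to the mean error", {
  cfg <- synthetic_cohort_config(
    n_patients = 4, n_fractions = 5,
    mean_error = c(ap = 0.14, si = 0.04, lr = 0.03),
    systematic_sd = 0, random_sd = 0, seed = 1L)
  log <- simulate_shift_log(cfg)
  expect_true(all(log$ap_cm == 0.14))
  expect_true(all(log$si_cm == 0.04))
  expect_true(all(log$lr_cm == 0.03))
})

test_that("decomposition recovers the generating parameters within 3
           standard errors", {
  cfg <- synthetic_cohort_config(
    n_patients = 50, n_fractions = 40,
    mean_error = 0, systematic_sd = 0.3, random_sd = 0.4, seed = 2024L)
  dec <- decompose_setup_error(simulate_shift_log(cfg),
                               rounding = "raw")$axes
  # SE(Sigma-hat) ~ Sigma / sqrt(2 (n-1)); SE(sigma-hat) ~ sigma /
  # sqrt(2 n (m-1))
  expect_true(all(abs(dec$Sigma - 0.3) < 3 * 0.3 / sqrt(2 * 49)))
  expect_true(all(abs(dec$sigma - 0.4) < 3 * 0.4 / sqrt(2 * 50 * 39)))
  se_m <- sqrt(0.3^2 / 50 + 0.4^2 / (50 * 40))
  expect_true(all(abs(dec$M - 0) < 3 * se_m))
})

test_that("replicate simulations at the default config show no recovery
           bias beyond Monte-Carlo noise", {
  cfg0 <- synthetic_cohort_config()
  n_rep <- 200
  sig_hat <- matrix(NA_real_, n_rep, 3)
  rnd_hat <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_cohort_config(seed = 5000L + r)
    dec <- decompose_setup_error(simulate_shift_log(cfg),
                                 rounding = "raw")$axes
    sig_hat[r, ] <- dec$Sigma
    rnd_hat[r, ] <- dec$sigma
  }
  # the bias check runs on the variance scale, where the estimators are
  # exactly unbiased: E[SD(patient means)^2] = Sigma^2 + sigma^2/m (so the
  # sigma^2/m term is subtracted) and E[sigma-hat^2] = sigma^2; the SD-scale
  # estimators themselves carry known finite-sample bias at n = 9
  m <- cfg0$n_fractions
  for (j in 1:3) {
    sig2_adj <- sig_hat[, j]^2 - rnd_hat[, j]^2 / m
    truth <- unname(cfg0$systematic_sd[j])^2
    mc_se <- sd(sig2_adj) / sqrt(n_rep)
    expect_lt(abs(mean(sig2_adj) - truth), 2 * mc_se)
    rnd2 <- rnd_hat[, j]^2
    truth <- unname(cfg0$random_sd[j])^2
    mc_se <- sd(rnd2) / sqrt(n_rep)
    expect_lt(abs(mean(rnd2) - truth), 2 * mc_se)
  }
})

test_that("paired-modality simulation carries the configured bias", {
  cfg <- synthetic_cohort_config(
    n_patients = 4, n_fractions = 5,
    modality_bias = 0, registration_noise_sd = 0, seed = 8L)
  pair <- simulate_paired_modality_log(cfg)
  cmp <- compare_modalities(summarize_patients(pair$ct, "CT"),
                            summarize_patients(pair$mri, "MRI"))
  expect_equal(unname(cmp$cohort_mean), c(0, 0, 0), tolerance = 1e-12)

  cfg <- synthetic_cohort_config(
    n_patients = 60, n_fractions = 30,
    modality_bias = c(ap = -0.15, si = 0, lr = 0),
    registration_noise_sd = 0.1, seed = 9L)
  pair <- simulate_paired_modality_log(cfg)
  cmp <- compare_modalities(summarize_patients(pair$ct, "CT"),
                            summarize_patients(pair$mri, "MRI"))
  # per-patient mean difference = bias + mean of 30 noise draws
  se <- (0.1 / sqrt(30)) / sqrt(60)
  expect_lt(abs(cmp$cohort_mean[["ap"]] - (-0.15)), 3 * se)
})

test_that("paired-measurement simulation respects its discrepancy model", {
  cfg <- synthetic_cohort_config(
    n_patients = 6,
    volume_model = list(prostate = list(meanlog = 3.8, sdlog = 0.4,
                                        delta_mean = 0.4, delta_sd = 0)),
    seed = 12L)
  tab <- simulate_paired_measurements(cfg, "volume_cc")
  expect_equal(percent_difference(tab$value_mri, tab$value_ct),
               rep(40, 6), tolerance = 1e-12)

  cfg <- synthetic_cohort_config(
    n_patients = 200,
    volume_model = list(prostate = list(meanlog = 3.76, sdlog = 0.46,
                                        delta_mean = 0.397,
                                        delta_sd = 0.185)),
    seed = 13L)
  res <- compare_paired(simulate_paired_measurements(cfg, "volume_cc"))
  expect_lt(abs(res$mean_pct_diff - 39.7), 3 * 18.5 / sqrt(200))

  cfg <- synthetic_cohort_config(
    n_patients = 5,
    volume_model = list(prostate = list(meanlog = 3.8, sdlog = 0.4,
                                        delta_mean = 0, delta_sd = 0)),
    seed = 14L)
  res <- compare_paired(simulate_paired_measurements(cfg, "volume_cc"))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("dose simulation stays near the prescription level", {
  cfg <- synthetic_cohort_config(seed = 15L)
  tab <- simulate_paired_measurements(cfg, "dose_gy")
  expect_setequal(unique(tab$structure_or_metric),
                  c("plan_max", "d99", "d95"))
  expect_true(all(tab$value_mri > 55 & tab$value_mri < 95))
})

test_that("heterogeneous per-patient random error keeps the configured RMS", {
  cfg <- synthetic_cohort_config(
    n_patients = 80, n_fractions = 40, systematic_sd = 0,
    random_sd = 0.4, sigma_heterogeneity = TRUE, seed = 16L)
  dec <- decompose_setup_error(simulate_shift_log(cfg),
                               rounding = "raw")$axes
  # chi-mixing widens the spread of per-patient SDs but preserves the RMS
  expect_true(all(abs(dec$sigma - 0.4) < 0.04))
})

test_that("Monte-Carlo coverage matches the chi(3) closed form across
           radii", {
  expect_equal(coverage_monte_carlo(1000, 0), 0)
  expect_gte(coverage_monte_carlo(10000, 10, seed = 1), 0.9999)
  for (r in c(1, 2, 2.5, 3)) {
    est <- coverage_monte_carlo(2e5, r, seed = 17L)
    truth <- pchisq(r^2, df = 3)
    mc_se <- sqrt(truth * (1 - truth) / 2e5)
    expect_lt(abs(est - truth), 4 * mc_se)
  }
})
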