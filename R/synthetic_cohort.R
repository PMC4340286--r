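#' Configure a synthetic cohort
#'
#' Parameterizes the generative model behind every pipeline input, so the
#' whole analysis can be exercised and validated without external data.
#' The model, per axis a:
#' \itemize{
#'   \item each patient p draws a systematic offset
#'     `s_pa ~ N(mean_error_a, systematic_sd_a^2)` (their planning/setup
#'     error, constant over the course);
#'   \item each fraction f adds an independent random error:
#'     `shift_pfa = s_pa + e_pfa`, `e ~ N(0, random_sd_a^2)`;
#'   \item the MRI-referenced registration of the same fraction differs from
#'     the CT-referenced one by a fixed per-axis bias plus registration
#'     noise: `shift_MRI = shift_CT + modality_bias_a + eta`,
#'     `eta ~ N(0, registration_noise_sd_a^2)`.
#' }
#' Paired measurements (volumes, dose metrics) draw the MRI value from a
#' log-normal (volumes) or normal (doses) baseline and set
#' `value_ct = value_mri * (1 + delta)`, `delta ~ N(delta_mean,
#' delta_sd^2)` truncated below at -0.99 so values stay positive.
#'
#' Defaults reproduce the conditions of the bundled prostate cohort: nine
#' evaluable patients, 42 fractions (the 75.6 Gy prescription), CT-reference
#' error components from its published decomposition, the observed
#' CT-to-MRI bias, registration noise at the measured reproducibility, a
#' prostate volume distribution fitted to the cohort's MRI volumes with the
#' cohort's mean/SD relative CT-MRI discrepancy, and plan dose levels near
#' the prescription.
#'
#' @param n_patients number of patients (>= 2).
#' @param n_fractions fractions per patient (>= 2).
#' @param mean_error per-axis true group mean error M, cm (named `ap`, `si`,
#'   `lr`).
#' @param systematic_sd per-axis true systematic SD Sigma, cm (>= 0).
#' @param random_sd per-axis true random SD sigma, cm (>= 0).
#' @param modality_bias per-axis MRI-minus-CT registration bias, cm.
#' @param registration_noise_sd per-axis SD of registration noise, cm
#'   (>= 0).
#' @param sigma_heterogeneity if `TRUE`, each patient's random-error SD is
#'   drawn from a scaled chi distribution with RMS `random_sd` (df
#'   `heterogeneity_df`) instead of being constant.
#' @param heterogeneity_df degrees of freedom of the heterogeneity chi draw.
#' @param volume_model named list, one entry per structure, each a list with
#'   `meanlog`, `sdlog` (log-normal MRI volume, cc) and `delta_mean`,
#'   `delta_sd` (relative CT-MRI discrepancy).
#' @param dose_model named list, one entry per metric, each a list with
#'   `mean`, `sd` (normal MRI dose level, Gy) and `delta_mean`, `delta_sd`.
#' @param seed integer RNG seed; identical config and seed give identical
#'   output.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(
    n_patients = 9,
    n_fractions = 42,
    mean_error = c(ap = 0.14, si = 0.04, lr = 0.03),
    systematic_sd = c(ap = 0.24, si = 0.14, lr = 0.17),
    random_sd = c(ap = 0.38, si = 0.42, lr = 0.38),
    modality_bias = c(ap = -0.15, si = 0.05, lr = -0.01),
    registration_noise_sd = c(ap = 0.08, si = 0.09, lr = 0.07),
    sigma_heterogeneity = FALSE,
    heterogeneity_df = 8,
    volume_model = list(
      prostate = list(meanlog = 3.76, sdlog = 0.46,
                      delta_mean = 0.397, delta_sd = 0.185)),
    dose_model = list(
      plan_max = list(mean = 77.5, sd = 2.9,
                      delta_mean = -0.0101, delta_sd = 0.0169),
      d99 = list(mean = 72.9, sd = 2.7,
                 delta_mean = -0.0011, delta_sd = 0.0170),
      d95 = list(mean = 73.2, sd = 2.7,
                 delta_mean = 0.0012, delta_sd = 0.0145)),
    seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_fractions = as.integer(n_fractions),
              mean_error = axis_param(mean_error, "mean_error"),
              systematic_sd = axis_param(systematic_sd, "systematic_sd",
                                         min = 0),
              random_sd = axis_param(random_sd, "random_sd", min = 0),
              modality_bias = axis_param(modality_bias, "modality_bias"),
              registration_noise_sd = axis_param(registration_noise_sd,
                                                 "registration_noise_sd",
                                                 min = 0),
              sigma_heterogeneity = isTRUE(sigma_heterogeneity),
              heterogeneity_df = heterogeneity_df,
              volume_model = volume_model, dose_model = dose_model,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "synthetic_cohort_config"
  cfg
}

# Recycle a scalar to the three axes and check it.
axis_param <- function(x, name, min = NULL) {
  if (length(x) == 1) x <- stats::setNames(rep(x, 3), AXES)
  if (is.null(names(x))) names(x) <- AXES
  if (!setequal(names(x), AXES)) {
    stop_validation("`%s` must be named ap/si/lr (or a scalar)", name)
  }
  check_numeric(x, name, min = min)
  x[AXES]
}

validate_config <- function(cfg) {
  if (cfg$n_patients < 2) stop_validation("n_patients must be >= 2")
  if (cfg$n_fractions < 2) stop_validation("n_fractions must be >= 2")
  for (nm in names(cfg$volume_model)) {
    m <- cfg$volume_model[[nm]]
    if (!all(c("meanlog", "sdlog", "delta_mean", "delta_sd") %in% names(m))) {
      stop_validation("volume_model entry '%s' is incomplete", nm)
    }
    if (m$sdlog < 0 || m$delta_sd < 0) {
      stop_validation("volume_model entry '%s' has a negative SD", nm)
    }
    if (m$delta_mean <= -1) {
      stop_validation("volume_model '%s': delta_mean must be > -1", nm)
    }
  }
  for (nm in names(cfg$dose_model)) {
    m <- cfg$dose_model[[nm]]
    if (!all(c("mean", "sd", "delta_mean", "delta_sd") %in% names(m))) {
      stop_validation("dose_model entry '%s' is incomplete", nm)
    }
    if (m$sd < 0 || m$delta_sd < 0) {
      stop_validation("dose_model entry '%s' has a negative SD", nm)
    }
  }
  invisible(cfg)
}

# Patient ids P01, P02, ... and the per-patient systematic offsets + daily
# shifts for one modality; shared by the single- and paired-log generators.
draw_shift_matrix <- function(cfg) {
  n <- cfg$n_patients
  m <- cfg$n_fractions
  shifts <- array(NA_real_, dim = c(n, m, 3))
  for (i in seq_along(AXES)) {
    a <- AXES[i]
    sys <- stats::rnorm(n, cfg$mean_error[[a]], cfg$systematic_sd[[a]])
    sds <- if (cfg$sigma_heterogeneity) {
      k <- cfg$heterogeneity_df
      cfg$random_sd[[a]] * sqrt(stats::rchisq(n, k) / k)
    } else {
      rep(cfg$random_sd[[a]], n)
    }
    shifts[, , i] <- sys + stats::rnorm(n * m, 0, rep(sds, m))
  }
  shifts
}

shift_array_to_table <- function(shifts, modality) {
  n <- dim(shifts)[1]
  m <- dim(shifts)[2]
  ids <- sprintf("P%02d", seq_len(n))
  out <- data.frame(
    patient_id = rep(ids, each = m),
    fraction = rep(seq_len(m), times = n),
    modality = modality,
    stringsAsFactors = FALSE)
  for (i in seq_along(AXES)) {
    out[[SHIFT_COLS[i]]] <- as.vector(t(shifts[, , i]))
  }
  as_cohort_shift_table(out)
}

#' Simulate a daily couch-shift log
#'
#' Draws one cohort's per-fraction shifts under the systematic + random
#' Gaussian model of [synthetic_cohort_config()]. With both SDs zero every
#' shift equals the configured mean error exactly.
#'
#' @param config a `synthetic_cohort_config`.
#' @param modality label for the generated records (`"CT"` or `"MRI"`).
#' @return a `cohort_shift_table`.
#' @export
simulate_shift_log <- function(config, modality = "CT") {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  with_seed(config$seed, {
    shift_array_to_table(draw_shift_matrix(config), modality)
  })
}

#' Simulate paired CT- and MRI-referenced shift logs
#'
#' Generates one cohort's CT-referenced shifts, then derives the
#' MRI-referenced shift of each fraction by adding the per-axis modality
#' bias and independent registration noise.
#'
#' @param config a `synthetic_cohort_config`.
#' @return list with elements `ct` and `mri`, each a `cohort_shift_table`
#'   over the same patients and fractions.
#' @export
simulate_paired_modality_log <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  with_seed(config$seed, {
    ct <- draw_shift_matrix(config)
    mri <- ct
    n <- dim(ct)[1]
    m <- dim(ct)[2]
    for (i in seq_along(AXES)) {
      a <- AXES[i]
      mri[, , i] <- ct[, , i] + config$modality_bias[[a]] +
        stats::rnorm(n * m, 0, config$registration_noise_sd[[a]])
    }
    list(ct = shift_array_to_table(ct, "CT"),
         mri = shift_array_to_table(mri, "MRI"))
  })
}

#' Simulate repeated registrations of the same image pairs
#'
#' Each task is one image pair with a latent true alignment; each repeat
#' observes it with independent registration noise at the configured per-axis
#' SD. Feeding the result to [registration_reproducibility()] recovers that
#' SD.
#'
#' @param config a `synthetic_cohort_config` (uses `registration_noise_sd`
#'   and `seed`).
#' @param n_tasks number of registration tasks.
#' @param n_repeats repeats per task (>= 2).
#' @return a data frame with columns `task_id`, `repeat_index`, `ap_cm`,
#'   `si_cm`, `lr_cm`.
#' @export
simulate_registration_repeats <- function(config, n_tasks = 200,
                                          n_repeats = 2) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (n_tasks < 1 || n_repeats < 2) {
    stop_validation("need n_tasks >= 1 and n_repeats >= 2")
  }
  with_seed(config$seed, {
    out <- data.frame(
      task_id = rep(sprintf("T%03d", seq_len(n_tasks)), each = n_repeats),
      repeat_index = rep(seq_len(n_repeats), times = n_tasks),
      stringsAsFactors = FALSE)
    for (i in seq_along(AXES)) {
      a <- AXES[i]
      truth <- stats::rnorm(n_tasks, 0, 0.3)
      out[[SHIFT_COLS[i]]] <- rep(truth, each = n_repeats) +
        stats::rnorm(n_tasks * n_repeats, 0,
                     config$registration_noise_sd[[a]])
    }
    out
  })
}

#' Simulate paired two-modality measurements
#'
#' Draws per-patient paired MRI/CT values for every structure (volumes) or
#' metric (doses) in the config's model: the MRI value from the baseline
#' distribution, the CT value as `value_mri * (1 + delta)` with `delta`
#' normal, truncated below at -0.99 to keep values positive.
#'
#' @param config a `synthetic_cohort_config`.
#' @param quantity `"volume_cc"` or `"dose_gy"`.
#' @return a `paired_measurements` data frame.
#' @export
simulate_paired_measurements <- function(config,
                                         quantity = c("volume_cc",
                                                      "dose_gy")) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  quantity <- match.arg(quantity)
  model <- if (quantity == "volume_cc") config$volume_model else
    config$dose_model
  if (length(model) == 0) {
    stop_validation("config has no %s model entries", quantity)
  }
  n <- config$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  with_seed(config$seed, {
    rows <- lapply(names(model), function(nm) {
      m <- model[[nm]]
      base <- if (quantity == "volume_cc") {
        stats::rlnorm(n, m$meanlog, m$sdlog)
      } else {
        abs(stats::rnorm(n, m$mean, m$sd))
      }
      delta <- pmax(stats::rnorm(n, m$delta_mean, m$delta_sd), -0.99)
      data.frame(patient_id = ids, structure_or_metric = nm,
                 value_mri = base, value_ct = base * (1 + delta),
                 stringsAsFactors = FALSE)
    })
    as_paired_measurements(do.call(rbind, rows), quantity)
  })
}

#' Monte-Carlo population coverage of a spherical margin
#'
#' Estimates the fraction of 3D standard-normal systematic-error vectors
#' whose Euclidean norm is at most `radius_coefficient` — the
#' population-coverage meaning of the 2.5 coefficient in the van Herk
#' margin: a radius of 2.5 per-axis SDs encloses ~90% of an isotropic 3D
#' Gaussian (the chi distribution with 3 degrees of freedom gives the exact
#' value, `pchisq(radius^2, 3)` = 0.8999 at 2.5).
#'
#' @param n_draws number of random vectors (>= 1).
#' @param radius_coefficient sphere radius in units of the per-axis SD
#'   (>= 0).
#' @param seed optional RNG seed.
#' @return estimated coverage proportion in `[0, 1]`.
#' @examples
#' coverage_monte_carlo(1e5, 2.5, seed = 1) # ~ 0.90
#' @export
coverage_monte_carlo <- function(n_draws, radius_coefficient = 2.5,
                                 seed = NULL) {
  check_numeric(n_draws, "n_draws", min = 1)
  check_numeric(radius_coefficient, "radius_coefficient", min = 0)
  n_draws <- as.integer(n_draws)
  with_seed(seed, {
    r2 <- radius_coefficient^2
    inside <- 0
    done <- 0L
    chunk <- 1000000L
    while (done < n_draws) {
      k <- min(chunk, n_draws - done)
      z <- matrix(stats::rnorm(3L * k), ncol = 3L)
      inside <- inside + sum(rowSums(z * z) <= r2)
      done <- done + k
    }
    inside / n_draws
  })
}
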