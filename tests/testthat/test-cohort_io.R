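test_that("write/read round trip is the identity on a synthetic shift log", {
  cfg <- synthetic_cohort_config(n_patients = 50, n_fractions = 40,
                                 seed = 11L)
  log <- simulate_shift_log(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(log, path)
  back <- read_shift_table(path)
  expect_s3_class(back, "cohort_shift_table")
  expect_equal(nrow(back), 50 * 40)
  for (col in names(log)) {
    expect_equal(back[[col]], log[[col]], tolerance = 1e-12)
  }
})

test_that("shift reader rejects malformed input with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("patient_id,fraction,modality,ap_cm,si_cm",
               "1,1,CT,0.1,0.2"), path)
  expect_error(read_shift_table(path), "lr_cm", class = "schema_error")

  writeLines(c("patient_id,fraction,modality,ap_cm,si_cm,lr_cm",
               "1,1,CT,0.1,0.2,0.3",
               "1,1,CT,0.4,0.5,0.6"), path)
  expect_error(read_shift_table(path), "patient '1', fraction 1",
               class = "validation_error")

  writeLines(c("patient_id,fraction,modality,ap_cm,si_cm,lr_cm",
               "1,1,CT,abc,0.2,0.3"), path)
  expect_error(read_shift_table(path), "non-numeric",
               class = "validation_error")

  writeLines(c("patient_id,fraction,modality,ap_cm,si_cm,lr_cm",
               "1,0,CT,0.1,0.2,0.3"), path)
  expect_error(read_shift_table(path), "positive",
               class = "validation_error")
})

test_that("an empty file with a valid header yields an empty table and a
           downstream insufficient-data error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,fraction,modality,ap_cm,si_cm,lr_cm", path)
  tab <- read_shift_table(path)
  expect_equal(nrow(tab), 0)
  expect_error(summarize_patients(tab, "CT"),
               class = "insufficient_data_error")
})

test_that("millimetre inputs are normalized to cm", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units: mm",
               "patient_id,fraction,modality,ap_mm,si_mm,lr_mm",
               "1,1,CT,2,-13,5",
               "1,2,CT,4,7,0"), path)
  tab <- read_shift_table(path)
  expect_equal(tab$ap_cm, c(0.2, 0.4))
  expect_equal(tab$si_cm, c(-1.3, 0.7))
  expect_equal(tab$lr_cm, c(0.5, 0.0))
})

test_that("missing shift cells warn on read and are dropped per axis", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,fraction,modality,ap_cm,si_cm,lr_cm",
               "1,1,CT,0.1,,0.3",
               "1,2,CT,0.3,0.2,0.1",
               "1,3,CT,0.2,0.4,0.2"), path)
  expect_warning(tab <- read_shift_table(path), "1 missing")
  summ <- summarize_patients(tab, "CT")
  expect_equal(summ$ap_mean, 0.2)           # all three fractions
  expect_equal(summ$si_mean, 0.3)           # missing cell dropped
  expect_equal(summ$si_sd, sd(c(0.2, 0.4)))
})

test_that("per-patient summaries match a streaming-variance oracle and are
           order-invariant", {
  set.seed(42)
  log <- random_shift_log(6, 8)
  summ <- summarize_patients(log, "CT")
  for (id in unique(log$patient_id)) {
    v <- log$ap_cm[log$patient_id == id]
    o <- oracle_welford(v)
    row <- summ[summ$patient_id == id, ]
    expect_equal(row$ap_mean, o$mean, tolerance = 1e-12)
    expect_equal(row$ap_sd, o$sd, tolerance = 1e-12)
    expect_equal(row$n_fractions, 8)
  }
  shuffled <- as_cohort_shift_table(log[sample(nrow(log)), ])
  expect_equal(summarize_patients(shuffled, "CT"), summ)
})

test_that("summarize_patients handles two-point and constant samples", {
  df <- data.frame(patient_id = c("a", "a", "b", "b", "b"),
                   fraction = c(1, 2, 1, 2, 3), modality = "CT",
                   ap_cm = c(0.1, 0.3, 0.5, 0.5, 0.5),
                   si_cm = 0, lr_cm = 0)
  summ <- summarize_patients(as_cohort_shift_table(df), "CT")
  expect_equal(summ$ap_mean, c(0.2, 0.5))
  expect_equal(summ$ap_sd[1], 0.1414, tolerance = 1e-3)
  expect_equal(summ$ap_sd[2], 0)
})

test_that("patients with a single fraction are excluded with a warning, or
           rejected when asked", {
  df <- data.frame(patient_id = c("a", "a", "b"),
                   fraction = c(1, 2, 1), modality = "CT",
                   ap_cm = 0.1, si_cm = 0.2, lr_cm = 0.3)
  tab <- as_cohort_shift_table(df)
  expect_warning(summ <- summarize_patients(tab, "CT"), "'b' excluded")
  expect_equal(summ$patient_id, "a")
  expect_error(summarize_patients(tab, "CT", on_few_fractions = "error"),
               class = "insufficient_data_error")
})

test_that("bundled cohort fixtures have the documented shape", {
  summ <- load_table4()
  expect_equal(nrow(summ), 18)
  expect_equal(sum(summ$modality == "CT"), 9)
  expect_equal(sum(summ$modality == "MRI"), 9)
  expect_false("8" %in% summ$patient_id)  # not evaluable for localization

  vols <- load_table2()
  expect_equal(nrow(vols), 40)
  expect_setequal(unique(vols$structure_or_metric),
                  c("prostate", "seminal_vesicles", "penile_bulb", "ctv"))

  doses <- load_table3()
  expect_equal(nrow(doses), 27)
  expect_false("8" %in% doses$patient_id)  # hip prosthesis
  expect_setequal(unique(doses$structure_or_metric),
                  c("plan_max", "d99", "d95"))
})

test_that("paired-table validation enforces positivity and uniqueness", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,structure_or_metric,value_mri,value_ct",
               "1,prostate,10,-2"), path)
  expect_error(read_paired_table(path, "volume_cc"), "patient '1'",
               class = "validation_error")

  writeLines(c("patient_id,structure_or_metric,value_mri,value_ct",
               "1,prostate,10,12",
               "1,prostate,11,13"), path)
  expect_error(read_paired_table(path, "volume_cc"), "twice",
               class = "validation_error")

  # a single patient reads fine; the paired test then refuses
  writeLines(c("patient_id,structure_or_metric,value_mri,value_ct",
               "1,prostate,10,12"), path)
  tab <- read_paired_table(path, "volume_cc")
  expect_equal(nrow(tab), 1)
  expect_error(compare_paired(tab), class = "insufficient_data_error")
})

test_that("bulk density constants are as documented", {
  expect_equal(bulk_density_map(),
               c(bone = 480, soft_tissue = 0, air = -1000))
})
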