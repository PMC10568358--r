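test_that("exclusion rules drop error-code, tachycardic and unestimable records", {
  records <- dplyr::bind_rows(
    make_record("bad255", gt_hr_series = rep(255, 60), ref_hr = 255),
    make_record("bad129", gt_hr_series = rep(129, 60), ref_hr = 129),
    make_record("fast", gt_hr_series = rep(210, 60), ref_hr = 210),
    make_record("noest", hr_confident = FALSE),
    make_record("rising", gt_hr_series = seq(70, 80, length.out = 60),
                ref_hr = 75),
    make_record("ok1"),
    make_record("ok2"))
  out <- filter_samples(records, mode = "hr")
  expect_setequal(out$records$recording_id, c("rising", "ok1", "ok2"))
  expect_equal(out$exclusions$reason[out$exclusions$recording_id == "bad255"],
               "constant-255")
  expect_equal(out$exclusions$reason[out$exclusions$recording_id == "bad129"],
               "constant-129")
  expect_equal(out$exclusions$reason[out$exclusions$recording_id == "fast"],
               "hr>=200")
  expect_equal(out$exclusions$reason[out$exclusions$recording_id == "noest"],
               "hr-not-estimable")
})

test_that("HRV mode additionally applies the PPG-quality exclusions", {
  records <- dplyr::bind_rows(
    make_record("poor", ppg_poor = TRUE),
    make_record("gap", ppg_discontinuous = TRUE),
    make_record("noppg", has_gt_ppg = FALSE),
    make_record("ok"))
  hr_keep <- filter_samples(records, mode = "hr")$records$recording_id
  expect_setequal(hr_keep, c("poor", "gap", "noppg", "ok"))
  hrv <- filter_samples(records, mode = "hrv")
  expect_equal(hrv$records$recording_id, "ok")
  expect_setequal(hrv$exclusions$reason,
                  c("poor-ppg-quality", "ppg-discontinuity", "no-gt-ppg"))
})

test_that("stratification follows subgroup definitions and nests by SNR", {
  set.seed(31)
  records <- dplyr::bind_rows(lapply(1:40, function(i)
    make_record(paste0("r", i), subject_id = paste0("S", (i + 1) %/% 2),
                fitzpatrick = sample(1:6, 1),
                gender = sample(c("male", "female"), 1),
                snr_db = runif(1, -2, 15))))

  # skin tone and gender subgroups apply no SNR exclusion
  low_snr_fp1 <- make_record("lowsnr", fitzpatrick = 1L, snr_db = 2)
  both <- dplyr::bind_rows(records, low_snr_fp1)
  expect_true("lowsnr" %in%
                stratify(both, "fitzpatrick_band", c(1, 2))$recording_id)
  expect_false("lowsnr" %in% stratify(both, "snr_threshold", 10)$recording_id)
  expect_true(all(stratify(both, "fitzpatrick_band", c(5, 6))$fitzpatrick
                  %in% 5:6))

  s5 <- stratify(records, "snr_threshold", 5)$recording_id
  s8 <- stratify(records, "snr_threshold", 8)$recording_id
  s10 <- stratify(records, "snr_threshold", 10)$recording_id
  expect_true(all(s8 %in% s5))
  expect_true(all(s10 %in% s8))

  # the three Fitzpatrick bands partition the records
  bands <- c(stratify(records, "fitzpatrick_band", c(1, 2))$recording_id,
             stratify(records, "fitzpatrick_band", c(3, 4))$recording_id,
             stratify(records, "fitzpatrick_band", c(5, 6))$recording_id)
  expect_setequal(bands, records$recording_id)
  expect_equal(length(bands), nrow(records))

  expect_error(stratify(records, "snr_threshold"), "numeric")
})

test_that("agreement reproduces hand-computed MAE, ME and Bland-Altman limits", {
  a <- agreement(c(72, 70), c(70, 72))
  expect_equal(a$mae, 2)
  expect_equal(a$me, 0)

  a <- agreement(c(60, 75, 90), c(60, 75, 90))
  expect_equal(a$mae, 0)
  expect_equal(a$ba_bias, 0)
  expect_equal(a$fit_slope, 1)
  expect_equal(a$fit_intercept, 0)

  # diffs +2, -2: bias 0, SD = 2.8284, LoA = +/- 5.5437
  a <- agreement(c(12, 18), c(10, 20))
  expect_equal(a$ba_bias, 0)
  expect_equal(a$ba_loa_high, 1.96 * sqrt(8), tolerance = 1e-6)
  expect_equal(a$ba_loa_low, -1.96 * sqrt(8), tolerance = 1e-6)

  expect_error(agreement(1, 1), "at least 2")
})

test_that("MAE dominates |ME|, with equality only under one-signed errors", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    est <- runif(n, 40, 180); ref <- runif(n, 40, 180)
    a <- agreement(est, ref)
    expect_gte(a$mae + 1e-12, abs(a$me))
    # permutation invariance of paired order
    perm <- sample(n)
    expect_equal(agreement(est[perm], ref[perm])$mae, a$mae)
  }
  one_sided <- agreement(c(75, 80, 85), c(70, 72, 80))
  expect_equal(one_sided$mae, one_sided$me)
})

test_that("benchmark_run emits the full subgroup x metric table", {
  records <- dplyr::bind_rows(
    make_record("a1", subject_id = "S1", fitzpatrick = 3L),
    make_record("a2", subject_id = "S1", fitzpatrick = 3L, est_hr = 68),
    make_record("a3", subject_id = "S2", fitzpatrick = 3L, est_hr = 74))
  tab <- benchmark_run(records, metrics = "hr")
  expect_setequal(tab$group,
                  c("All samples", "SNR > 5", "SNR > 8", "SNR > 10",
                    "Fitzpatrick 1 and 2", "Fitzpatrick 3 and 4",
                    "Fitzpatrick 5 and 6", "Male", "Female"))
  fp34 <- tab[tab$group == "Fitzpatrick 3 and 4", ]
  expect_equal(fp34$n_samples, 3)
  # two recordings of S1 and one of S2: subjects counted uniquely
  expect_equal(fp34$n_subjects, 2)
  expect_equal(tab$n_samples[tab$group == "Fitzpatrick 1 and 2"], 0)
  expect_equal(tab$n_samples[tab$group == "Fitzpatrick 5 and 6"], 0)
  expect_true(is.na(tab$mae[tab$group == "Male"]))

  # truth-referenced comparison uses the generator truth columns
  tab2 <- benchmark_run(records, metrics = "hr", ref_prefix = "truth")
  expect_equal(tab2$mae[tab2$group == "All samples"],
               mean(abs(records$est_hr - records$truth_hr)))
})

test_that("report figures are written and Bland-Altman honours the SNR gate", {
  set.seed(55)
  records <- dplyr::bind_rows(lapply(1:12, function(i)
    make_record(paste0("r", i), fitzpatrick = ((i - 1) %% 6) + 1L,
                est_hr = 70 + rnorm(1, 0, 3), ref_hr = 70,
                snr_db = c(12, 4)[1 + i %% 2])))
  dir <- withr::local_tempdir()
  paths <- plot_reports(records, dir, metrics = "hr")
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 0))

  # the gated Bland-Altman uses only the SNR > 10 subset
  p <- plot_bland_altman(records, "hr", snr_min = 10)
  expect_equal(nrow(p$data), sum(records$snr_db > 10))
  # colour legend covers exactly the three skin-tone bands
  expect_length(levels(p$data$band), 3)
})
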