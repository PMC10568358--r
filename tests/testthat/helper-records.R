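# construct a minimal benchmark record row with sensible defaults, overridable
# per test
make_record <- function(recording_id = "rec", subject_id = "S1",
                        fitzpatrick = 3L, gender = "female",
                        snr_db = 8, hr_confident = TRUE,
                        est_hr = 72, ref_hr = 70,
                        gt_hr_series = rep(70, 60),
                        has_gt_ppg = TRUE, ppg_poor = FALSE,
                        ppg_discontinuous = FALSE, ...) {
  extra <- list(...)
  row <- tibble::tibble(
    recording_id = recording_id, subject_id = subject_id,
    fitzpatrick = fitzpatrick, gender = gender,
    snr_db = snr_db, hr_confident = hr_confident,
    est_hr = est_hr, est_ibi = 850, est_sdnn = 40, est_rmssd = 55,
    est_lf = 1e-3, est_hf = 1e-3,
    ref_hr = ref_hr, ref_ibi = 855, ref_sdnn = 42, ref_rmssd = 57,
    ref_lf = 1e-3, ref_hf = 1e-3,
    truth_hr = ref_hr, truth_ibi = 855, truth_sdnn = 42, truth_rmssd = 57,
    has_gt_ppg = has_gt_ppg, ppg_poor = ppg_poor,
    ppg_discontinuous = ppg_discontinuous,
    gt_hr_series = list(gt_hr_series))
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

region_box_for_test <- function(rois, nm, i) rppgbench:::region_box(rois, nm, i)

# short synthetic trace for core-pipeline tests: a single tone in all three
# channels around typical skin baselines
make_tone_trace <- function(freq_hz, fps = 30, duration_s = 60,
                            amp = c(R = 0.006, G = 0.010, B = 0.004),
                            base = c(R = 180, G = 140, B = 120)) {
  t <- (seq_len(duration_s * fps) - 1) / fps
  p <- sin(2 * pi * freq_hz * t)
  rgb_trace(base[["R"]] * (1 + amp[["R"]] * p),
            base[["G"]] * (1 + amp[["G"]] * p),
            base[["B"]] * (1 + amp[["B"]] * p),
            fps = fps)
}
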