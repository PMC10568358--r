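#' Process one recording into a benchmark record
#'
#'
#' Runs the rPPG pipeline on the recording's RGB trace, runs the identical
#' vitals path on the contact-PPG ground truth, derives the reference heart
#' rate (the mean of the ground-truth HR series, when present), applies the
#' automated PPG-quality heuristics, and -- for synthetic recordings --
#' carries the exact generating truth alongside.
#'
#' @param trace An [rgb_trace()].
#' @param gt A [ground_truth()] or `NULL`.
#' @param meta A [subject_meta()] or `NULL`.
#' @param truth Optional list of generating truth values (as stored by
#'   [gen_recording()]).
#' @param window_s POS window length (s).
#' @return A one-row [tibble::tibble()] with `est_*`, `ref_*` and `truth_*`
#'   columns, quality flags, and the ground-truth HR series as a list column.
#' @export
process_recording <- function(trace, gt = NULL, meta = NULL, truth = NULL,
                              window_s = 1.6) {
  pulse <- extract_pulse(trace, window_s = window_s)
  est <- extract_vitals(pulse$s_heart, pulse$fps)

  ref <- tibble::tibble(hr_bpm = NA_real_, hr_confident = NA, snr_db = NA_real_,
                        hr_from_ibi = NA_real_, ibi = NA_real_, sdnn = NA_real_,
                        rmssd = NA_real_, lf = NA_real_, hf = NA_real_,
                        n_beats = 0L)
  ppg_poor <- NA
  ppg_disc <- NA
  has_ppg <- !is.null(gt) && !is.null(gt$ppg) && length(gt$ppg) > 1L
  if (has_ppg) {
    ref <- tryCatch(extract_vitals(gt$ppg, gt$fs), error = function(e) ref)
    ppg_disc <- ppg_discontinuity(gt$ppg)
    ppg_poor <- is.na(ref$snr_db) || ref$snr_db < 0
  }
  ref_hr <- if (!is.null(gt) && !is.null(gt$hr) && length(gt$hr))
    mean(gt$hr) else NA_real_

  tibble::tibble(
    recording_id = trace$recording_id %||% NA_character_,
    subject_id = if (!is.null(meta)) meta$subject_id else NA_character_,
    fitzpatrick = if (!is.null(meta)) meta$fitzpatrick else NA_integer_,
    gender = if (!is.null(meta)) meta$gender else NA_character_,
    snr_db = est$snr_db, hr_confident = est$hr_confident,
    est_hr = est$hr_bpm, est_hr_ibi = est$hr_from_ibi,
    est_ibi = est$ibi, est_sdnn = est$sdnn, est_rmssd = est$rmssd,
    est_lf = est$lf, est_hf = est$hf,
    ref_hr = ref_hr, ref_ibi = ref$ibi, ref_sdnn = ref$sdnn,
    ref_rmssd = ref$rmssd, ref_lf = ref$lf, ref_hf = ref$hf,
    truth_hr = if (!is.null(truth)) truth$hr else NA_real_,
    truth_ibi = if (!is.null(truth)) truth$ibi else NA_real_,
    truth_sdnn = if (!is.null(truth)) truth$sdnn else NA_real_,
    truth_rmssd = if (!is.null(truth)) truth$rmssd else NA_real_,
    has_gt_ppg = has_ppg,
    ppg_poor = ppg_poor, ppg_discontinuous = ppg_disc,
    gt_hr_series = list(if (!is.null(gt)) gt$hr else NULL))
}

# automated stand-in for the manual GT-PPG discontinuity check: any adjacent
# sample jump larger than 10x the waveform SD
ppg_discontinuity <- function(ppg, factor = 10) {
  s <- sd(ppg)
  if (!is.finite(s) || s == 0) return(FALSE)
  any(abs(diff(ppg)) > factor * s)
}

#' Run the full pipeline over a synthetic cohort
#'
#' @param cohort A [gen_cohort()] result.
#' @param window_s POS window length (s).
#' @return A records tibble, one row per recording (see
#'   [process_recording()]).
#' @export
cohort_vitals <- function(cohort, window_s = 1.6) {
  stopifnot(inherits(cohort, "synth_cohort"))
  rows <- lapply(cohort$recordings, function(rec)
    process_recording(rec$trace, rec$gt, rec$meta, rec$truth,
                      window_s = window_s))
  dplyr::bind_rows(rows)
}
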