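#' Apply sample-exclusion rules
#'
#' Reproduces the benchmark's exclusion chain. In HR mode a record is dropped
#' when its ground-truth HR series is constant at the sensor error codes 255
#' or 129 (i.e. no usable GT HR), when the reference HR is at or above 200
#' bpm, or when no confident HR estimate was produced. HRV mode additionally
#' drops records without a GT PPG waveform, with a poor-quality GT PPG
#' (spectral SNR below 0 dB) or with a GT PPG discontinuity (an adjacent-
#' sample jump above 10x the waveform SD). Recordings with a rising heart
#' rhythm are deliberately retained in both modes.
#'
#' @param records Records tibble (see [process_recording()]).
#' @param mode `"hr"` or `"hrv"`.
#' @return List with `records` (the usable subset) and `exclusions` (tibble of
#'   `recording_id`, `reason`).
#' @export
filter_samples <- function(records, mode = c("hr", "hrv")) {
  mode <- match.arg(mode)
  reason <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    hr_series <- records$gt_hr_series[[i]]
    r <- NA_character_
    if (is_constant_at(hr_series, 255)) r <- "constant-255"
    else if (is_constant_at(hr_series, 129)) r <- "constant-129"
    else if (is.finite(records$ref_hr[i]) && records$ref_hr[i] >= 200) r <- "hr>=200"
    else if (!isTRUE(records$hr_confident[i])) r <- "hr-not-estimable"
    else if (mode == "hrv") {
      if (!isTRUE(records$has_gt_ppg[i])) r <- "no-gt-ppg"
      else if (isTRUE(records$ppg_poor[i])) r <- "poor-ppg-quality"
      else if (isTRUE(records$ppg_discontinuous[i])) r <- "ppg-discontinuity"
    }
    reason[i] <- r
  }
  keep <- is.na(reason)
  list(records = records[keep, , drop = FALSE],
       exclusions = tibble::tibble(recording_id = records$recording_id[!keep],
                                   reason = reason[!keep]))
}

is_constant_at <- function(series, value) {
  !is.null(series) && length(series) > 0L && all(series == value)
}

#' Select a benchmark subgroup
#'
#' Stratifies records by signal quality (`snr_db` strictly above a threshold),
#' Fitzpatrick skin-tone band, or gender. Skin-tone and gender subgroups apply
#' no SNR filtering.
#'
#' @param records Records tibble.
#' @param kind `"all"`, `"snr_threshold"`, `"fitzpatrick_band"` or
#'   `"gender"`.
#' @param parameter Threshold in dB, a length-2 Fitzpatrick band such as
#'   `c(1, 2)`, or `"male"`/`"female"`.
#' @return The matching subset of `records`.
#' @export
stratify <- function(records, kind = c("all", "snr_threshold",
                                       "fitzpatrick_band", "gender"),
                     parameter = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    all = records,
    snr_threshold = {
      if (!is.numeric(parameter) || length(parameter) != 1L)
        stop("stratify: snr_threshold needs a single numeric parameter",
             call. = FALSE)
      records[!is.na(records$snr_db) & records$snr_db > parameter, , drop = FALSE]
    },
    fitzpatrick_band = {
      if (!is.numeric(parameter) || length(parameter) != 2L)
        stop("stratify: fitzpatrick_band needs a length-2 parameter",
             call. = FALSE)
      records[!is.na(records$fitzpatrick) &
                records$fitzpatrick %in% parameter[1]:parameter[2], ,
              drop = FALSE]
    },
    gender = {
      parameter <- match.arg(parameter, c("male", "female"))
      records[!is.na(records$gender) & records$gender == parameter, ,
              drop = FALSE]
    })
}

#' Agreement statistics between estimates and a reference
#'
#' Mean absolute error, signed mean error (estimate minus reference),
#' Bland-Altman bias and 95% limits of agreement (bias +/- 1.96 times the
#' sample SD of the differences), and the ordinary-least-squares best-fit line
#' of estimate on reference.
#'
#' @param est,ref Equal-length numeric vectors of paired values.
#' @return A one-row [tibble::tibble()] with `n`, `mae`, `me`, `ba_bias`,
#'   `ba_loa_low`, `ba_loa_high`, `fit_slope`, `fit_intercept`.
#' @export
agreement <- function(est, ref) {
  ok <- is.finite(est) & is.finite(ref)
  est <- est[ok]; ref <- ref[ok]
  if (length(est) < 2L)
    stop("agreement: need at least 2 pairs", call. = FALSE)
  d <- est - ref
  sdd <- sd(d)
  fit <- coef(lm(est ~ ref))
  tibble::tibble(
    n = length(est),
    mae = mean(abs(d)), me = mean(d),
    ba_bias = mean(d),
    ba_loa_low = mean(d) - 1.96 * sdd, ba_loa_high = mean(d) + 1.96 * sdd,
    fit_slope = unname(fit[2]), fit_intercept = unname(fit[1]))
}

default_subgroups <- function() {
  list(
    list(label = "All samples", kind = "all", parameter = NULL),
    list(label = "SNR > 5", kind = "snr_threshold", parameter = 5),
    list(label = "SNR > 8", kind = "snr_threshold", parameter = 8),
    list(label = "SNR > 10", kind = "snr_threshold", parameter = 10),
    list(label = "Fitzpatrick 1 and 2", kind = "fitzpatrick_band", parameter = c(1, 2)),
    list(label = "Fitzpatrick 3 and 4", kind = "fitzpatrick_band", parameter = c(3, 4)),
    list(label = "Fitzpatrick 5 and 6", kind = "fitzpatrick_band", parameter = c(5, 6)),
    list(label = "Male", kind = "gender", parameter = "male"),
    list(label = "Female", kind = "gender", parameter = "female"))
}

#' Subgroup-by-metric benchmark table
#'
#' The machine twin of a subgroup evaluation table: one row per
#' (subgroup, metric) with sample and subject counts and the agreement
#' statistics of estimate versus reference. Default subgroups are all samples,
#' the three SNR thresholds (5, 8, 10 dB), the three Fitzpatrick bands and the
#' two genders. Empty subgroups yield a row with `n = 0` and `NA` statistics.
#'
#' @param records Records tibble (already filtered with [filter_samples()]).
#' @param metrics Character vector of metric names; each needs `est_<metric>`
#'   and a reference column.
#' @param subgroups List of subgroup specs (default [default_subgroups()]
#'   internally).
#' @param ref_prefix `"ref"` to compare against sensor-derived references,
#'   `"truth"` to compare against stored generator truth.
#' @return A tidy tibble with `group`, `metric`, `n_samples`, `n_subjects`
#'   and the [agreement()] columns.
#' @export
benchmark_run <- function(records, metrics = c("hr", "ibi", "sdnn", "rmssd"),
                          subgroups = NULL, ref_prefix = c("ref", "truth")) {
  ref_prefix <- match.arg(ref_prefix)
  subgroups <- subgroups %||% default_subgroups()
  rows <- list()
  k <- 0L
  for (sg in subgroups) {
    sub <- stratify(records, sg$kind, sg$parameter)
    for (m in metrics) {
      est_col <- paste0("est_", m)
      ref_col <- paste0(ref_prefix, "_", m)
      if (!est_col %in% names(records) || !ref_col %in% names(records))
        stop("benchmark_run: no columns for metric '", m, "'", call. = FALSE)
      est <- sub[[est_col]]; ref <- sub[[ref_col]]
      ok <- is.finite(est) & is.finite(ref)
      k <- k + 1L
      base <- tibble::tibble(
        group = sg$label, metric = m,
        n_samples = sum(ok),
        n_subjects = length(unique(sub$subject_id[ok])))
      stats <- if (sum(ok) >= 2L) agreement(est[ok], ref[ok]) else
        tibble::tibble(n = sum(ok), mae = NA_real_, me = NA_real_,
                       ba_bias = NA_real_, ba_loa_low = NA_real_,
                       ba_loa_high = NA_real_, fit_slope = NA_real_,
                       fit_intercept = NA_real_)
      rows[[k]] <- dplyr::bind_cols(base, stats[, setdiff(names(stats), "n")])
    }
  }
  dplyr::bind_rows(rows)
}
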