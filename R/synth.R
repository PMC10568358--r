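#' Skin-tone pulsatile amplitude multiplier
#'
#' Monotone attenuation of the pulsatile colour fraction with increasing
#' melanin: `m(FP) = 1 - 0.08 * (FP - 1)` for Fitzpatrick type 1..6, so the
#' darkest type retains 60% of the lightest type's pulsatile amplitude. The
#' magnitude keeps every group above the detection floor; this is a modelling
#' choice, not a validated skin-optics law.
#'
#' @param fitzpatrick Integer 1..6 (vectorised).
#' @return Numeric multiplier(s) in (0, 1].
#' @export
fp_amplitude <- function(fitzpatrick) {
  stopifnot(all(fitzpatrick %in% 1:6))
  1 - 0.08 * (fitzpatrick - 1)
}

# typical baseline skin RGB (8-bit) per Fitzpatrick type, light to dark
fp_baseline <- function(fitzpatrick) {
  tab <- rbind(c(235, 190, 170), c(223, 177, 156), c(200, 155, 130),
               c(170, 125, 100), c(120, 85, 65), c(85, 60, 48))
  tab[fitzpatrick, ]
}

#' Generate an RR interval series
#'
#' Produces a beat-to-beat RR series (ms) covering `duration_s` seconds under
#' one of three variability models: `iid_gaussian` (RR ~ N(60000/hr_mean,
#' sd_ms), redrawn into the 300-2000 ms physiologic range), `ar1` (an AR(1)
#' process with stationary SD `sd_ms` and coefficient `phi`), or `sinusoidal`
#' (RR(t) = mu + mod_depth * sin(2 pi mod_freq t), putting all RR power at one
#' known frequency for LF/HF checks). `rising_bpm > 0` superimposes a linear
#' heart-rate increase over the recording (an artifact case the benchmark
#' deliberately retains).
#'
#' @param duration_s Recording length in seconds.
#' @param hr_mean Mean heart rate in bpm.
#' @param model `"iid_gaussian"`, `"ar1"` or `"sinusoidal"`.
#' @param sd_ms Target RR standard deviation in ms (iid / ar1 models).
#' @param phi AR(1) coefficient.
#' @param mod_freq,mod_depth Sinusoidal modulation frequency (Hz) and depth
#'   (ms).
#' @param rising_bpm Linear heart-rate rise (bpm) over the recording.
#' @return Numeric RR series in ms.
#' @export
gen_rr <- function(duration_s, hr_mean, model = c("iid_gaussian", "ar1", "sinusoidal"),
                   sd_ms = 40, phi = 0.8, mod_freq = 0.1, mod_depth = 50,
                   rising_bpm = 0) {
  model <- match.arg(model)
  stopifnot(duration_s > 0, hr_mean > 0, sd_ms >= 0)
  mu0 <- 60000 / hr_mean
  if (model == "iid_gaussian" && sd_ms > 0) {
    trunc_frac <- stats::pnorm(300, mu0, sd_ms) + stats::pnorm(2000, mu0, sd_ms,
                                                               lower.tail = FALSE)
    if (trunc_frac > 0.5)
      stop("gen_rr: parameters truncate more than half the RR distribution",
           call. = FALSE)
  }
  total_ms <- duration_s * 1000
  mu_at <- function(t_ms) {
    # instantaneous HR rises linearly over the recording
    hr <- hr_mean + rising_bpm * pmin(t_ms / total_ms, 1)
    60000 / hr
  }
  rr <- numeric(0)
  t <- 0
  prev_dev <- 0
  while (t < total_ms) {
    mu <- mu_at(t)
    val <- switch(model,
      iid_gaussian = {
        if (sd_ms == 0) mu else {
          v <- rnorm(1, mu, sd_ms)
          while (v < 300 || v > 2000) v <- rnorm(1, mu, sd_ms)
          v
        }
      },
      ar1 = {
        prev_dev <- phi * prev_dev +
          rnorm(1, 0, sd_ms * sqrt(max(1 - phi^2, 0)))
        mu + prev_dev
      },
      sinusoidal = mu + mod_depth * sin(2 * pi * mod_freq * t / 1000)
    )
    val <- min(max(val, 300), 2000)
    rr <- c(rr, val)
    t <- t + val
  }
  rr
}

#' Synthesize a contact-PPG waveform from an RR series
#'
#' Places a two-Gaussian pulse kernel (sharp systolic peak plus a broader
#' dicrotic shoulder on its falling edge) at the cumulative RR beat times and
#' samples the sum at `fs`. The kernel widths scale with the local RR so the
#' waveform stays realistic across heart rates, and the dicrotic component is
#' a shoulder -- not a secondary local maximum -- so detected peak times land
#' on the systolic peaks to within a sample.
#'
#' @param rr Numeric RR series in ms.
#' @param fs Sampling rate in Hz (>= 10).
#' @param pad_s Seconds of signal appended after the last beat.
#' @return Numeric PPG waveform sampled at `fs`, with the generating peak
#'   times (s) attached as attribute `"peak_times"`.
#' @export
gen_ppg <- function(rr, fs, pad_s = 0.5) {
  if (fs < 10) stop("gen_ppg: sampling rate below 10 Hz", call. = FALSE)
  stopifnot(length(rr) >= 1L, all(rr > 0))
  beat_t <- cumsum(rr) / 1000            # systolic peak times, s
  rr_s <- rr / 1000
  dur <- beat_t[length(beat_t)] + pad_s
  t <- seq(0, dur, by = 1 / fs)
  x <- numeric(length(t))
  for (j in seq_along(beat_t)) {
    w <- rr_s[j]
    s1 <- 0.09 * w; s2 <- 0.13 * w
    d <- t - beat_t[j]
    near <- which(d > -4 * s1 & d < 0.22 * w + 4 * s2)
    if (!length(near)) next
    dj <- d[near]
    x[near] <- x[near] + exp(-dj^2 / (2 * s1^2)) +
      0.35 * exp(-(dj - 0.22 * w)^2 / (2 * s2^2))
  }
  attr(x, "peak_times") <- beat_t
  attr(x, "fs") <- fs
  x
}

#' Synthesize a skin-tone-dependent RGB trace
#'
#' Emulates the ROI-averaged colour series of a face video: each channel is
#' `baseline_c * (1 + a_c * m(FP) * p(t)) + drift(t) + noise`, where `p(t)` is
#' the normalized pulse waveform from [gen_ppg()], `a` holds the relative
#' pulsatile strengths (strongest in green), `m(FP)` is the skin-tone
#' attenuation from [fp_amplitude()], drift is a slow illumination trend well
#' below the pulse band, and the noise is white Gaussian per frame and
#' channel.
#'
#' @param rr Numeric RR series in ms.
#' @param fps Frame rate (Hz).
#' @param fitzpatrick Fitzpatrick type 1..6.
#' @param noise_sd Additive noise SD in 8-bit intensity units.
#' @param drift_amp Illumination drift amplitude (intensity units).
#' @param drift_freq Illumination drift frequency (Hz).
#' @param pulse_strength Named numeric: relative pulsatile fraction per
#'   channel.
#' @param recording_id Optional identifier.
#' @return An [rgb_trace()].
#' @export
gen_trace <- function(rr, fps, fitzpatrick = 3, noise_sd = 0.1,
                      drift_amp = 1.5, drift_freq = 0.05,
                      pulse_strength = c(R = 0.006, G = 0.010, B = 0.004),
                      recording_id = NULL) {
  p <- gen_ppg(rr, fps)
  p <- p - mean(p)
  pk <- max(abs(p))
  if (pk > 0) p <- p / pk
  n <- length(p)
  tt <- (seq_len(n) - 1L) / fps
  m <- fp_amplitude(fitzpatrick)
  base <- fp_baseline(fitzpatrick)
  phase <- runif(1, 0, 2 * pi)
  drift <- drift_amp * sin(2 * pi * drift_freq * tt + phase) +
    drift_amp * 0.5 * tt / max(tt)
  ch <- function(b, a) {
    v <- b * (1 + a * m * p) + drift +
      (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
    if (any(v < 0)) {
      warning("gen_trace: negative intensities clipped at 0")
      v <- pmax(v, 0)
    }
    v
  }
  rgb_trace(ch(base[1], pulse_strength[["R"]]),
            ch(base[2], pulse_strength[["G"]]),
            ch(base[3], pulse_strength[["B"]]),
            fps = fps, roi_name = "fused", recording_id = recording_id)
}

#' Render a toy face video from an RGB trace
#'
#' Builds frames whose three fixed-coordinate ROI patches carry the trace
#' colours (plus optional per-pixel noise) over a constant background, so
#' [extract_trace()] on the rendered frames recovers the trace.
#'
#' @param trace An [rgb_trace()].
#' @param width,height Frame size in pixels.
#' @param rois An [roi_set()] with static boxes, or `NULL` for a default
#'   three-patch layout.
#' @param pixel_noise_sd Per-pixel Gaussian noise SD (intensity units).
#' @param background Background intensity (0-255).
#' @return List with `video` (a [video_sequence()]) and `rois` (the
#'   [roi_set()] used).
#' @export
gen_video <- function(trace, width = 64, height = 48, rois = NULL,
                      pixel_noise_sd = 0, background = 60) {
  stopifnot(inherits(trace, "rgb_trace"))
  rois <- rois %||% roi_set(
    forehead = c(22, 42, 4, 14),
    left_cheek = c(6, 20, 22, 38),
    right_cheek = c(44, 58, 22, 38),
    source = "fixed_coordinates")
  for (nm in region_names()) {
    b <- region_box(rois, nm, 1L)
    if (b[2] > width || b[4] > height || b[1] < 0 || b[3] < 0)
      stop("gen_video: frame size too small for ROI '", nm, "'", call. = FALSE)
  }
  frames <- vector("list", trace$n_frames)
  for (i in seq_len(trace$n_frames)) {
    f <- array(background, c(height, width, 3L))
    col <- c(trace$R[i], trace$G[i], trace$B[i])
    for (nm in region_names()) {
      b <- region_box(rois, nm, i)
      rows <- (b[3] + 1L):b[4]; cols <- (b[1] + 1L):b[2]
      for (c3 in 1:3) {
        patch <- matrix(col[c3], length(rows), length(cols))
        if (pixel_noise_sd > 0)
          patch <- patch + matrix(rnorm(length(patch), 0, pixel_noise_sd),
                                  nrow(patch))
        f[rows, cols, c3] <- patch
      }
    }
    frames[[i]] <- pmin(pmax(f, 0), 255)
  }
  list(video = video_sequence(frames, fps = trace$fps,
                              recording_id = trace$recording_id),
       rois = rois)
}

#' Generate one synthetic recording with known ground truth
#'
#' Bundles a generating RR series, a skin-tone-dependent RGB trace, a
#' synchronized contact-PPG ground-truth record with a per-second reference
#' heart-rate series, subject metadata, and the exact truth values (RR series,
#' mean HR and HRV metrics computed directly from the generating RR series).
#'
#' @param recording_id,subject_id Identifiers.
#' @param fitzpatrick Fitzpatrick type 1..6.
#' @param gender `"male"` or `"female"`.
#' @param duration_s,fps Recording length (s) and video frame rate (Hz).
#' @param hr_mean Mean heart rate (bpm).
#' @param ppg_fs Ground-truth PPG sampling rate (Hz).
#' @param noise_sd Trace noise SD (intensity units).
#' @param rising_bpm Linear HR rise over the recording (bpm).
#' @param rr_model,sd_ms Passed to [gen_rr()].
#' @param ... Further arguments to [gen_rr()].
#' @return An object of class `synth_recording`: list with `trace`, `gt`,
#'   `meta` and `truth`.
#' @export
gen_recording <- function(recording_id, subject_id, fitzpatrick, gender,
                          duration_s = 60, fps = 30, hr_mean = 70, ppg_fs = 60,
                          noise_sd = 0.1, rising_bpm = 0,
                          rr_model = "iid_gaussian", sd_ms = 40, ...) {
  rr <- gen_rr(duration_s, hr_mean, model = rr_model, sd_ms = sd_ms,
               rising_bpm = rising_bpm, ...)
  trace <- gen_trace(rr, fps, fitzpatrick = fitzpatrick, noise_sd = noise_sd,
                     recording_id = recording_id)
  ppg <- gen_ppg(rr, ppg_fs)
  beat_t <- cumsum(rr) / 1000
  hr_inst <- 60000 / rr
  hr_series <- approx(beat_t, hr_inst, xout = seq(1, floor(duration_s)),
                      rule = 2)$y
  gt <- ground_truth(hr = hr_series, ppg = as.numeric(ppg), fs = ppg_fs,
                     recording_id = recording_id)
  td <- time_domain_hrv(rr)
  fd <- freq_domain_hrv(rr)
  truth <- list(rr = rr, hr = 60000 / mean(rr), ibi = td$ibi, sdnn = td$sdnn,
                rmssd = td$rmssd, lf = fd$lf, hf = fd$hf)
  structure(list(trace = trace, gt = gt,
                 meta = subject_meta(subject_id, fitzpatrick, gender),
                 truth = truth, recording_id = recording_id),
            class = "synth_recording")
}

#' Generate a synthetic cohort
#'
#' Emulates the structure of a multi-subject face-video study: `n_subjects`
#' subjects spanning all six Fitzpatrick types and both genders, each with
#' `recordings_per_subject` recordings of `duration_s` seconds at `fps`, true
#' heart rates drawn uniformly from `hr_range`, equal noise across skin-tone
#' groups, and full generating ground truth stored with every recording. All
#' randomness comes from the single `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param recordings_per_subject Recordings per subject.
#' @param duration_s,fps Recording length (s) and frame rate (Hz).
#' @param hr_range Length-2 range (bpm) for the uniform true-HR draw.
#' @param noise_sd Trace noise SD (intensity units) for every recording.
#' @param ppg_fs Ground-truth PPG sampling rate (Hz).
#' @param n_rising Number of recordings given a +10 bpm rising heart rhythm.
#' @param rr_model,sd_ms Passed to [gen_rr()].
#' @param seed Integer seed fixing all randomness (recorded in the manifest).
#' @return List of class `synth_cohort` with `manifest` (tibble) and
#'   `recordings` (list of [gen_recording()] results).
#' @export
gen_cohort <- function(n_subjects = 25, recordings_per_subject = 2,
                       duration_s = 60, fps = 30, hr_range = c(50, 150),
                       noise_sd = 0.1, ppg_fs = 60, n_rising = 0,
                       rr_model = "iid_gaussian", sd_ms = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fp <- rep(1:6, length.out = n_subjects)
  gender <- rep(c("female", "male"), length.out = n_subjects)
  recordings <- list()
  rows <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    for (r in seq_len(recordings_per_subject)) {
      k <- k + 1L
      rid <- sprintf("%s_R%02d", sid, r)
      hr <- runif(1, hr_range[1], hr_range[2])
      rising <- if (k <= n_rising) 10 else 0
      rec <- gen_recording(rid, sid, fp[s], gender[s], duration_s = duration_s,
                           fps = fps, hr_mean = hr, ppg_fs = ppg_fs,
                           noise_sd = noise_sd, rising_bpm = rising,
                           rr_model = rr_model, sd_ms = sd_ms)
      recordings[[rid]] <- rec
      rows[[k]] <- tibble::tibble(
        recording_id = rid, subject_id = sid, fitzpatrick = fp[s],
        gender = gender[s], hr_true = rec$truth$hr, rising_bpm = rising,
        noise_sd = noise_sd, duration_s = duration_s, fps = fps,
        seed = seed %||% NA_integer_)
    }
  }
  structure(list(manifest = dplyr::bind_rows(rows), recordings = recordings),
            class = "synth_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes one trace CSV and one ground-truth CSV per recording plus a
#' `manifest.csv` tying recordings to subjects, metadata and file paths.
#' Deterministic given the cohort object, so equal seeds give byte-identical
#' files.
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with path columns), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  man$trace_path <- file.path(dir, paste0(man$recording_id, "_trace.csv"))
  man$gt_path <- file.path(dir, paste0(man$recording_id, "_gt.csv"))
  for (i in seq_len(nrow(man))) {
    rec <- cohort$recordings[[man$recording_id[i]]]
    write_trace_csv(rec$trace, man$trace_path[i])
    write_ground_truth(rec$gt, man$gt_path[i])
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
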