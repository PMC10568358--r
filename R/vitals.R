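#' Welch averaged-periodogram power spectral density
#'
#' Splits the (mean-removed) signal into Hann-windowed segments with 50%
#' overlap, zero-pads each segment to `nfft`, and averages the one-sided
#' periodograms. Zero-padding interpolates the spectrum so peak frequencies
#' can be read off finely.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length (default `min(length(x), 256)`).
#' @param nfft FFT length, `>= nperseg` (default: next power of two above
#'   `nperseg`).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = NULL, nfft = NULL) {
  n <- length(x)
  x <- x - mean(x)
  nperseg <- min(n, nperseg %||% 256L)
  nfft <- max(nperseg, nfft %||% 2^ceiling(log2(nperseg)))
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  k <- seq_len(nperseg) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * k / (nperseg - 1L))
  scale <- fs * sum(w^2)
  nfreq <- floor(nfft / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, numeric(nfft - nperseg)))
    p <- (Mod(X[seq_len(nfreq)])^2) / scale
    # one-sided: double everything except DC (and Nyquist when nfft even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nfft, psd = acc / length(starts))
}

#' Detect systolic peaks in a pulse signal
#'
#' Finds local maxima, keeps those whose topographic prominence is at least
#' `prominence_factor` times the signal's standard deviation, and enforces a
#' minimum separation (default 60/180 s, i.e. no rhythm above 180 bpm) by
#' keeping the taller of any two conflicting peaks.
#'
#' @param x Numeric signal (band-passed pulse).
#' @param fs Sampling rate (Hz).
#' @param min_dist_s Minimum peak separation in seconds.
#' @param prominence_factor Prominence threshold as a multiple of `sd(x)`.
#' @return Integer vector of peak sample indices (ascending).
#' @export
detect_peaks <- function(x, fs, min_dist_s = 60 / 180, prominence_factor = 0.5) {
  n <- length(x)
  if (n < 3L) stop("detect_peaks: signal too short", call. = FALSE)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  thr <- prominence_factor * sd(x)
  keep <- cand[peak_prominence(x, cand) >= thr]
  if (length(keep) >= 2L) {
    min_dist <- round(min_dist_s * fs)
    ord <- keep[order(x[keep], decreasing = TRUE)]
    sel <- integer(0)
    for (p in ord)
      if (!length(sel) || all(abs(sel - p) >= min_dist)) sel <- c(sel, p)
    keep <- sort(sel)
  }
  if (length(keep) < 2L)
    stop("detect_peaks: fewer than 2 peaks found (no rhythm)", call. = FALSE)
  keep
}

# topographic prominence of candidate peaks: height above the higher of the
# two valley floors between the peak and the nearest higher ground (or the
# signal end) on each side
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1L) x[1:(p - 1L)] else numeric(0)
    hi <- which(left > h)
    lmin <- if (length(hi)) min(left[(max(hi) + 1L):length(left)]) else
      if (length(left)) min(left) else h
    right <- if (p < length(x)) x[(p + 1L):length(x)] else numeric(0)
    hi <- which(right > h)
    rmin <- if (length(hi)) min(right[1:(min(hi) - 1L)]) else
      if (length(right)) min(right) else h
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Refine peak locations to sub-sample precision
#'
#' Fits a parabola through each peak sample and its two neighbours and returns
#' the vertex position as a fractional sample index. This reduces the
#' quantization error of RR intervals at modest frame rates (a video frame at
#' 30 fps is 33 ms wide).
#'
#' @param x Numeric signal.
#' @param peaks Integer peak indices from [detect_peaks()].
#' @return Numeric vector of refined (fractional) peak positions.
#' @export
refine_peaks <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    if (p <= 1L || p >= n) return(as.numeric(p))
    denom <- x[p - 1L] - 2 * x[p] + x[p + 1L]
    if (denom >= 0) return(as.numeric(p))
    delta <- 0.5 * (x[p - 1L] - x[p + 1L]) / denom
    p + max(-0.5, min(0.5, delta))
  }, numeric(1))
}

#' RR (inter-beat) interval series from peak positions
#'
#' Converts consecutive peak positions to inter-peak intervals in
#' milliseconds, `RR(i) = (peak(i+1) - peak(i)) / fs * 1000`, and applies the
#' physiologic gate: intervals outside `[300, 2000]` ms (30-200 bpm) are
#' discarded as double detections or missed beats.
#'
#' @param peaks Numeric vector of peak sample positions (ascending; may be
#'   fractional from [refine_peaks()]).
#' @param fs Sampling rate (Hz).
#' @param gate_ms Length-2 physiologic gate in ms.
#' @return An object of class `rr_series`: list with `rr` (ms), `peaks`, `fs`
#'   and `n`.
#' @export
rr_intervals <- function(peaks, fs, gate_ms = c(300, 2000)) {
  if (length(peaks) < 2L)
    stop("rr_intervals: need at least 2 peaks", call. = FALSE)
  rr <- diff(peaks) / fs * 1000
  rr <- rr[rr >= gate_ms[1] & rr <= gate_ms[2]]
  if (length(rr) == 0L)
    stop("rr_intervals: all intervals outside the physiologic gate (empty RR)",
         call. = FALSE)
  structure(list(rr = rr, peaks = peaks, fs = fs, n = length(rr)),
            class = "rr_series")
}

as_rr <- function(rr) {
  if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
}

#' Time-domain HRV metrics
#'
#' Standard heart-rate-variability summaries of an RR series: IBI (mean RR),
#' SDNN (sample standard deviation of RR, divisor N-1) and RMSSD (root mean
#' square of the N-1 successive RR differences). All in milliseconds.
#'
#' @param rr An [rr_intervals()] object or a numeric RR vector in ms.
#' @return List with `ibi`, `sdnn`, `rmssd` (ms) and `n`.
#' @export
time_domain_hrv <- function(rr) {
  rr <- as_rr(rr)
  n <- length(rr)
  if (n < 2L)
    stop("time_domain_hrv: need at least 2 RR intervals", call. = FALSE)
  list(ibi = mean(rr),
       sdnn = sd(rr),
       rmssd = sqrt(mean(diff(rr)^2)),
       n = n)
}

#' Frequency-domain HRV metrics
#'
#' Interpolates the RR series (in seconds) onto an evenly sampled grid on the
#' cumulative-beat-time axis, removes the mean, estimates the power spectral
#' density with [welch_psd()] and integrates it over the LF (0.04-0.15 Hz) and
#' HF (0.15-0.4 Hz) bands. LF needs roughly 1/0.04 = 25 s of data to resolve;
#' shorter records are still computed but flagged unreliable.
#'
#' @param rr An [rr_intervals()] object or numeric RR vector in ms.
#' @param resample_fs Interpolation rate in Hz (default 4).
#' @param lf_band,hf_band Band edges in Hz.
#' @return List with `lf`, `hf` (integrated band power of the RR-in-seconds
#'   series), `lf_hf_ratio` and `lf_reliable`.
#' @export
freq_domain_hrv <- function(rr, resample_fs = 4,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)) {
  rr <- as_rr(rr)
  if (length(rr) < 4L)
    stop("freq_domain_hrv: need at least 4 RR intervals", call. = FALSE)
  rr_s <- rr / 1000
  t <- cumsum(rr_s)
  span <- t[length(t)] - t[1]
  grid <- seq(t[1], t[length(t)], by = 1 / resample_fs)
  xi <- approx(t, rr_s, xout = grid)$y
  xi <- xi - mean(xi)
  ps <- welch_psd(xi, resample_fs, nperseg = min(length(xi), 256L), nfft = 1024L)
  df <- ps$freq[2] - ps$freq[1]
  band_power <- function(b) sum(ps$psd[ps$freq >= b[1] & ps$freq < b[2]]) * df
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  list(lf = lf, hf = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else Inf,
       lf_reliable = span >= 1 / lf_band[1])
}

#' Spectral heart-rate estimate
#'
#' Estimates heart rate as 60 times the frequency of the largest Welch-PSD
#' peak within the plausible band (default 0.7-3.33 Hz, i.e. 42-200 bpm),
#' refined by parabolic interpolation of the spectral peak. The estimate is
#' confident only when the in-band maximum is a genuine local spectral peak
#' and the signal's SNR is non-negative; unconfident recordings are excluded
#' from the HR benchmark.
#'
#' @param x Numeric pulse signal (e.g. `s_heart`).
#' @param fs Sampling rate (Hz).
#' @param band Length-2 frequency band in Hz to search.
#' @param min_duration_s Minimum signal duration (default 20 s).
#' @return List with `hr_bpm` (NA when no peak), `snr_db` and `hr_confident`.
#' @export
estimate_hr <- function(x, fs, band = c(0.7, 200 / 60), min_duration_s = 20) {
  if (length(x) / fs < min_duration_s)
    stop("estimate_hr: need at least ", min_duration_s, " s of signal",
         call. = FALSE)
  nper <- min(length(x), 512L)
  ps <- welch_psd(x, fs, nperseg = nper, nfft = max(8192L, nper))
  inb <- which(ps$freq >= band[1] & ps$freq <= band[2])
  i <- inb[which.max(ps$psd[inb])]
  is_peak <- i > 1L && i < length(ps$psd) &&
    ps$psd[i] >= ps$psd[i - 1L] && ps$psd[i] >= ps$psd[i + 1L] && ps$psd[i] > 0
  if (!is_peak)
    return(list(hr_bpm = NA_real_, snr_db = NA_real_, hr_confident = FALSE))
  # parabolic interpolation of the spectral peak (log power)
  lp <- log(pmax(ps$psd[(i - 1L):(i + 1L)], .Machine$double.xmin))
  denom <- lp[1] - 2 * lp[2] + lp[3]
  delta <- if (denom < 0) max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / denom)) else 0
  f0 <- ps$freq[i] + delta * (ps$freq[2] - ps$freq[1])
  hr <- 60 * f0
  snr <- compute_snr(x, fs, hr)
  list(hr_bpm = hr, snr_db = snr, hr_confident = snr >= 0)
}

#' Spectral signal-to-noise ratio of a pulse signal
#'
#' `10 log10(P_signal / P_noise)` where the signal power is the Welch-PSD
#' power within `+/- half_width` Hz of the heart-rate fundamental and of its
#' first harmonic, and the noise power is the remaining power in the
#' `noise_band` (default 0.5-4 Hz). Capped at +60 dB when the noise power
#' vanishes (e.g. a noiseless sinusoid).
#'
#' @param x Numeric pulse signal.
#' @param fs Sampling rate (Hz).
#' @param hr_bpm Heart-rate estimate (bpm) locating the fundamental.
#' @param half_width Half-width of the signal bands in Hz (default 0.1).
#' @param noise_band Frequency range in Hz over which noise is accumulated.
#' @param cap_db Upper cap in dB.
#' @return SNR in dB.
#' @export
compute_snr <- function(x, fs, hr_bpm, half_width = 0.1,
                        noise_band = c(0.5, 4), cap_db = 60) {
  stopifnot(is.finite(hr_bpm))
  nper <- min(length(x), 512L)
  ps <- welch_psd(x, fs, nperseg = nper, nfft = max(4096L, nper))
  f0 <- hr_bpm / 60
  inb <- ps$freq >= noise_band[1] & ps$freq <= noise_band[2]
  sig <- (abs(ps$freq - f0) <= half_width) | (abs(ps$freq - 2 * f0) <= half_width)
  Ps <- sum(ps$psd[inb & sig])
  Pn <- sum(ps$psd[inb & !sig])
  if (Ps <= 0) return(-cap_db)
  if (Pn <= 0) return(cap_db)
  min(cap_db, 10 * log10(Ps / Pn))
}

#' All vital-sign estimates for one pulse signal
#'
#' The shared vitals path used for both the rPPG signal and the contact-PPG
#' ground truth: band-pass, peak detection with sub-sample refinement, RR
#' intervals with physiologic gating, time- and frequency-domain HRV, spectral
#' heart rate and SNR.
#'
#' When a confident spectral heart rate is available it also sets the minimum
#' peak spacing to 70% of the implied beat period (never below the global
#' 60/180 s floor), which suppresses inter-beat ripple peaks at slow heart
#' rates.
#'
#' @param x Numeric pulse signal (`s_heart` or a contact-PPG waveform).
#' @param fs Sampling rate (Hz).
#' @param refine Refine peak positions by parabolic interpolation
#'   (default TRUE).
#' @return A one-row [tibble::tibble()] with columns `hr_bpm`, `hr_confident`,
#'   `snr_db`, `hr_from_ibi`, `ibi`, `sdnn`, `rmssd`, `lf`, `hf`, `n_beats`.
#'   HRV columns are `NA` when beats cannot be resolved.
#' @export
extract_vitals <- function(x, fs, refine = TRUE) {
  xb <- bandpass(x, fs)
  hr <- estimate_hr(xb, fs)
  min_dist_s <- if (is.finite(hr$hr_bpm)) max(60 / 180, 0.7 * 60 / hr$hr_bpm)
    else 60 / 180
  td <- list(ibi = NA_real_, sdnn = NA_real_, rmssd = NA_real_, n = 0L)
  fd <- list(lf = NA_real_, hf = NA_real_)
  ok <- tryCatch({
    peaks <- detect_peaks(xb, fs, min_dist_s = min_dist_s)
    pos <- if (refine) refine_peaks(xb, peaks) else peaks
    rr <- rr_intervals(pos, fs)
    td <- time_domain_hrv(rr)
    fd <- tryCatch(freq_domain_hrv(rr), error = function(e) fd)
    TRUE
  }, error = function(e) FALSE)
  tibble::tibble(
    hr_bpm = hr$hr_bpm, hr_confident = hr$hr_confident, snr_db = hr$snr_db,
    hr_from_ibi = if (ok && is.finite(td$ibi)) 60000 / td$ibi else NA_real_,
    ibi = td$ibi, sdnn = td$sdnn, rmssd = td$rmssd,
    lf = fd$lf, hf = fd$hf, n_beats = if (ok) td$n + 1L else 0L)
}
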