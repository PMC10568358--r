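#' Temporal normalization of RGB channels
#'
#' Divides each colour channel by its own mean over a window, so every
#' normalized channel has mean exactly 1 within the window. This removes the
#' dependence on absolute illumination level and is the first step of the POS
#' projection.
#'
#' @param trace An [rgb_trace()].
#' @param window Integer vector of frame indices (default: the whole trace).
#' @return List with numeric vectors `Rn`, `Gn`, `Bn`.
#' @export
temporal_normalize <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "rgb_trace"))
  window <- window %||% seq_len(trace$n_frames)
  if (length(window) < 2L)
    stop("temporal_normalize: window must contain at least 2 frames", call. = FALSE)
  norm1 <- function(x) {
    m <- mean(x)
    if (m <= 0) stop("temporal_normalize: zero channel mean (degenerate input)",
                     call. = FALSE)
    x / m
  }
  list(Rn = norm1(trace$R[window]),
       Gn = norm1(trace$G[window]),
       Bn = norm1(trace$B[window]))
}

#' POS chrominance projections
#'
#' Projects temporally normalized channels onto the two chrominance axes of
#' the plane-orthogonal-to-skin method: `U = Gn - Bn` and
#' `V = Gn + Bn - 2 Rn`, elementwise.
#'
#' @param Rn,Gn,Bn Equal-length normalized channel vectors.
#' @return List with numeric vectors `U` and `V`.
#' @export
pos_project <- function(Rn, Gn, Bn) {
  n <- length(Rn)
  if (length(Gn) != n || length(Bn) != n)
    stop("pos_project: channel length mismatch (alignment error)", call. = FALSE)
  list(U = Gn - Bn, V = Gn + Bn - 2 * Rn)
}

#' Combine POS projections into a pulse segment
#'
#' For one analysis window, forms `U + alpha * V` with
#' `alpha = sd(U) / sd(V)` (population standard deviations over the window)
#' and removes the segment mean. When `sd(V) = 0` the window is degenerate --
#' a constant V carries no pulse -- and `alpha` is set to 0 so the segment is
#' just mean-removed `U`.
#'
#' @param U,V Equal-length projection vectors from one window.
#' @return Numeric zero-mean segment, with the `alpha` used attached as an
#'   attribute.
#' @export
pos_combine <- function(U, V) {
  if (length(U) != length(V))
    stop("pos_combine: U and V length mismatch (alignment error)", call. = FALSE)
  sv <- sd_pop(V)
  alpha <- if (sv > 0) sd_pop(U) / sv else 0
  seg <- U + alpha * V
  seg <- seg - mean(seg)
  attr(seg, "alpha") <- alpha
  seg
}

#' Sliding-window POS pulse extraction
#'
#' Runs the POS chain -- temporal normalization, chrominance projection,
#' alpha-weighted combination -- in a sliding window of `window_s` seconds
#' with stride one frame, and overlap-adds the zero-mean window segments into
#' a single pulse signal `s_orig` of the same length as the trace.
#'
#' @param trace An [rgb_trace()].
#' @param window_s Window length in seconds (default 1.6).
#' @return Numeric vector `s_orig`, `length(trace$R)` samples.
#' @export
pos_sliding <- function(trace, window_s = 1.6) {
  stopifnot(inherits(trace, "rgb_trace"))
  n <- trace$n_frames
  L <- max(2L, round(window_s * trace$fps))
  if (n < L)
    stop("pos_sliding: trace shorter than one window (insufficient data)",
         call. = FALSE)
  nw <- n - L + 1L
  idx <- outer(seq_len(L), seq_len(nw) - 1L, `+`)   # L x nw frame indices
  Rw <- matrix(trace$R[idx], L, nw)
  Gw <- matrix(trace$G[idx], L, nw)
  Bw <- matrix(trace$B[idx], L, nw)
  mR <- colMeans(Rw); mG <- colMeans(Gw); mB <- colMeans(Bw)
  if (any(mR <= 0) || any(mG <= 0) || any(mB <= 0))
    stop("pos_sliding: zero channel mean in a window (degenerate input)",
         call. = FALSE)
  Rn <- sweep(Rw, 2L, mR, `/`)
  Gn <- sweep(Gw, 2L, mG, `/`)
  Bn <- sweep(Bw, 2L, mB, `/`)
  U <- Gn - Bn
  V <- Gn + Bn - 2 * Rn
  sdp_col <- function(M) {
    m <- colMeans(M)
    v <- colMeans(M * M) - m * m
    sqrt(pmax(v, 0))
  }
  sU <- sdp_col(U); sV <- sdp_col(V)
  alpha <- ifelse(sV > 0, sU / sV, 0)
  S <- U + sweep(V, 2L, alpha, `*`)
  S <- sweep(S, 2L, colMeans(S), `-`)
  out <- numeric(n)
  for (l in seq_len(L)) {
    sl <- seq_len(nw) + (l - 1L)
    out[sl] <- out[sl] + S[l, ]
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass. The default 0.7-7.0 Hz
#' band keeps the heart-rate fundamental and a few harmonics while removing
#' illumination drift and high-frequency noise; the upper edge is clipped to
#' 95% of Nyquist when the sampling rate is low.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz); must exceed `2 * low`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (default 3).
#' @return Filtered numeric vector, mean removed.
#' @export
bandpass <- function(x, fs, low = 0.7, high = 7.0, order = 3L) {
  if (fs <= 2 * low)
    stop("bandpass: sampling rate ", fs, " Hz unusable for a ", low,
         " Hz lower edge", call. = FALSE)
  high <- min(high, 0.95 * fs / 2)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Single-heartbeat pulse template
#'
#' @param t Numeric vector of `2K + 1` samples for lags `-K..K`, with the
#'   systolic peak expected at lag 0.
#' @param K Half-width in samples.
#' @return An object of class `pulse_template`.
#' @export
pulse_template <- function(t, K) {
  K <- as.integer(K)
  if (length(t) != 2L * K + 1L)
    stop("pulse_template: need length 2K+1 = ", 2L * K + 1L, ", got ",
         length(t), call. = FALSE)
  structure(list(t = as.numeric(t), K = K), class = "pulse_template")
}

#' Build a heartbeat template from the pulse signal
#'
#' Band-passes `s_orig` to aid peak detection, detects systolic peaks, and
#' averages the `2K + 1`-sample portions of `s_orig` centred on each peak
#' (`K = round(half_width_s * fps)`; segments extending past the signal ends
#' are dropped). Needs at least `min_peaks` usable peaks, otherwise a
#' template-failure error is raised and the caller should fall back to the
#' band-passed signal.
#'
#' @param s_orig Pulse signal from [pos_sliding()].
#' @param fps Sampling rate (Hz).
#' @param half_width_s Template half-width in seconds (default 0.25 s, wide
#'   enough to cover a systolic peak at all plausible heart rates).
#' @param min_peaks Minimum usable peaks (default 3).
#' @return A [pulse_template()].
#' @export
build_template <- function(s_orig, fps, half_width_s = 0.25, min_peaks = 3L) {
  sb <- bandpass(s_orig, fps)
  hr <- tryCatch(estimate_hr(sb, fps), error = function(e) list(hr_bpm = NA_real_))
  min_dist_s <- if (is.finite(hr$hr_bpm)) max(60 / 180, 0.7 * 60 / hr$hr_bpm)
    else 60 / 180
  peaks <- tryCatch(detect_peaks(sb, fps, min_dist_s = min_dist_s),
                    error = function(e) integer(0))
  K <- as.integer(round(half_width_s * fps))
  n <- length(s_orig)
  peaks <- peaks[peaks - K >= 1L & peaks + K <= n]
  if (length(peaks) < min_peaks)
    stop("build_template: fewer than ", min_peaks,
         " usable peaks (template failure)", call. = FALSE)
  segs <- vapply(peaks, function(p) s_orig[(p - K):(p + K)], numeric(2L * K + 1L))
  pulse_template(rowMeans(segs), K)
}

#' Convolutional template filter
#'
#' Denoises the pulse signal by correlating it with a single-heartbeat
#' template: `s_heart[n] = (1 / (2K + 1)) * sum_{k = -K..K} s_orig[n + k] t[k]`,
#' equivalently the convolution with the time-reversed template. The signal is
#' reflection-padded so the output has the same length and sample alignment as
#' the input.
#'
#' @param s_orig Numeric pulse signal.
#' @param template A [pulse_template()].
#' @param form `"correlation"` (the `s_orig[n + k] t[k]` form) or
#'   `"convolution"` (the algebraically identical `s_orig[n - k] t[-k]` form);
#'   both give the same result and exist to make the identity checkable.
#' @return Numeric vector `s_heart`, same length as `s_orig`.
#' @export
conv_filter <- function(s_orig, template, form = c("correlation", "convolution")) {
  form <- match.arg(form)
  stopifnot(inherits(template, "pulse_template"))
  K <- template$K
  tt <- template$t
  n <- length(s_orig)
  if (length(tt) == 0L) stop("conv_filter: empty template", call. = FALSE)
  if (length(tt) > n)
    stop("conv_filter: template longer than signal", call. = FALSE)
  # reflection padding: K samples mirrored at each end
  xp <- c(rev(s_orig[2:(K + 1L)]), s_orig, rev(s_orig[(n - K):(n - 1L)]))
  y <- numeric(n)
  if (form == "correlation") {
    for (j in seq_len(2L * K + 1L))         # k = j - K - 1 in -K..K
      y <- y + xp[j:(j + n - 1L)] * tt[j]
  } else {
    for (k in -K:K)                          # y[n] += s[n - k] * t[-k]
      y <- y + xp[(1:n) - k + K] * tt[K + 1L - k]
  }
  y / (2 * K + 1)
}

#' Extract a clean pulse signal from an RGB trace
#'
#' Full rPPG core: sliding-window POS projection to `s_orig`, heartbeat
#' template construction, and convolutional template filtering to `s_heart`.
#' If too few peaks are found to build a template, `s_heart` falls back to the
#' band-passed `s_orig`.
#'
#' @param trace An [rgb_trace()].
#' @param window_s POS window length in seconds.
#' @param half_width_s Template half-width in seconds.
#' @return An object of class `rppg_signal`: list with `s_orig`, `s_heart`,
#'   `fps`, `template` (may be `NULL`) and `template_ok`.
#' @export
extract_pulse <- function(trace, window_s = 1.6, half_width_s = 0.25) {
  s_orig <- pos_sliding(trace, window_s = window_s)
  template <- tryCatch(build_template(s_orig, trace$fps, half_width_s),
                       error = function(e) NULL)
  if (is.null(template)) {
    s_heart <- bandpass(s_orig, trace$fps)
  } else {
    s_heart <- conv_filter(s_orig, template)
  }
  structure(list(s_orig = s_orig, s_heart = s_heart, fps = trace$fps,
                 template = template, template_ok = !is.null(template),
                 recording_id = trace$recording_id),
            class = "rppg_signal")
}

#' @export
print.rppg_signal <- function(x, ...) {
  cat(sprintf("<rppg_signal> %d samples @ %.6g fps, template %s\n",
              length(x$s_heart), x$fps,
              if (x$template_ok) "ok" else "failed (band-passed fallback)"))
  invisible(x)
}
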