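# Independent brute-force oracles used across test files. Each is a naive,
# loop-level reimplementation kept deliberately separate from the package's
# vectorised code paths.

# mean RR via explicit accumulation
oracle_ibi <- function(rr) {
  s <- 0
  for (v in rr) s <- s + v
  s / length(rr)
}

# sample SD of RR, divisor N - 1, via explicit loops
oracle_sdnn <- function(rr) {
  n <- length(rr)
  m <- oracle_ibi(rr)
  s <- 0
  for (i in seq_len(n)) s <- s + (rr[i] - m)^2
  sqrt(s / (n - 1))
}

# root mean square of the N - 1 successive differences, via explicit loops
oracle_rmssd <- function(rr) {
  n <- length(rr)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + (rr[i] - rr[i + 1])^2
  sqrt(s / (n - 1))
}

# double-loop template correlation with reflection padding, mirroring the
# definition s_heart[n] = (1/(2K+1)) sum_k s[n+k] t[k]
oracle_conv <- function(x, tt) {
  K <- (length(tt) - 1L) %/% 2L
  n <- length(x)
  xp <- c(rev(x[2:(K + 1L)]), x, rev(x[(n - K):(n - 1L)]))
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in -K:K) acc <- acc + xp[i + K + k] * tt[k + K + 1L]
    y[i] <- acc / (2 * K + 1)
  }
  y
}

# all-local-maxima -> prominence filter -> tallest-first spacing filter,
# written as plain loops
oracle_peaks <- function(x, fs, min_dist_s = 60 / 180, prom_factor = 0.5) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1))
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) cand <- c(cand, i)
  prom <- numeric(length(cand))
  for (j in seq_along(cand)) {
    p <- cand[j]; h <- x[p]
    lmin <- h
    if (p > 1) {
      i <- p - 1; lmin <- x[i]
      while (i >= 1 && x[i] <= h) { lmin <- min(lmin, x[i]); i <- i - 1 }
    }
    rmin <- h
    if (p < n) {
      i <- p + 1; rmin <- x[i]
      while (i <= n && x[i] <= h) { rmin <- min(rmin, x[i]); i <- i + 1 }
    }
    prom[j] <- h - max(lmin, rmin)
  }
  cand <- cand[prom >= prom_factor * sd(x)]
  min_dist <- round(min_dist_s * fs)
  kept <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    clash <- FALSE
    for (q in kept) if (abs(q - p) < min_dist) clash <- TRUE
    if (!clash) kept <- c(kept, p)
  }
  sort(kept)
}

# per-pixel double loop ROI channel means
oracle_roi_mean <- function(frame, box) {
  acc <- c(0, 0, 0); cnt <- 0
  for (y in (box[3] + 1L):box[4])
    for (xx in (box[1] + 1L):box[2]) {
      acc <- acc + frame[y, xx, ]
      cnt <- cnt + 1
    }
  acc / cnt
}

# dominant frequency by plain periodogram scan over a band
oracle_dominant_freq <- function(x, fs, band = c(0.5, 5)) {
  n <- length(x)
  X <- fft(x - mean(x))
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2 & f >= band[1] & f <= band[2]
  f[half][which.max(Mod(X[half])^2)]
}
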