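test_that("temporal normalization divides each channel by its window mean", {
  tr <- rgb_trace(R = c(1, 3), G = c(50, 50), B = c(2, 6), fps = 30)
  nz <- temporal_normalize(tr)
  expect_equal(nz$Rn, c(0.5, 1.5))
  expect_equal(nz$Gn, c(1, 1))
  expect_equal(nz$Bn, c(0.5, 1.5))

  set.seed(42)
  tr2 <- rgb_trace(runif(100, 50, 60), runif(100, 90, 110), runif(100, 20, 30),
                   fps = 30)
  nz2 <- temporal_normalize(tr2, window = 11:40)
  expect_equal(mean(nz2$Gn), 1)
  expect_equal(mean(nz2$Rn), 1)

  tr0 <- rgb_trace(rep(0, 10), rep(1, 10), rep(1, 10), fps = 30)
  expect_error(temporal_normalize(tr0), "degenerate")
})

test_that("POS projections follow the chrominance definitions", {
  # Gn = Bn makes U vanish; Rn = (Gn + Bn)/2 makes V vanish
  g <- c(1.1, 0.9, 1.0)
  uv <- pos_project(Rn = c(1, 1, 1), Gn = g, Bn = g)
  expect_equal(uv$U, c(0, 0, 0))
  b <- c(0.95, 1.05, 1.0)
  uv <- pos_project(Rn = (g + b) / 2, Gn = g, Bn = b)
  expect_equal(uv$V, c(0, 0, 0))

  # direct substitution
  uv <- pos_project(Rn = 1, Gn = 1.1, Bn = 0.9)
  expect_equal(uv$U, 0.2)
  expect_equal(uv$V, 0.0)

  expect_error(pos_project(1:3, 1:3, 1:2), "alignment")
})

test_that("pos_combine weights by the population-SD ratio and centres", {
  # degenerate window: constant V contributes nothing
  t <- seq(0, 2, by = 0.05)
  U <- sin(2 * pi * t)
  seg <- pos_combine(U, rep(0, length(U)))
  expect_equal(as.numeric(seg), U - mean(U))
  expect_equal(attr(seg, "alpha"), 0)

  # U = V gives alpha 1
  seg <- pos_combine(U, U)
  expect_equal(attr(seg, "alpha"), 1)
  expect_equal(as.numeric(seg), 2 * U - mean(2 * U))

  # hand computation: sd(U) = 1, sd(V) = 2, alpha = 0.5
  seg <- pos_combine(c(1, -1, 1, -1), c(2, -2, 2, -2))
  expect_equal(attr(seg, "alpha"), 0.5)
  expect_equal(as.numeric(seg), c(2, -2, 2, -2))

  # zero mean by construction
  set.seed(1)
  seg <- pos_combine(rnorm(48), rnorm(48))
  expect_equal(mean(seg), 0, tolerance = 1e-12)
})

test_that("sliding-window POS recovers the pulsatile frequency", {
  tr <- make_tone_trace(1.2, fps = 30, duration_s = 60)
  s <- pos_sliding(tr, window_s = 1.6)
  expect_length(s, tr$n_frames)
  f <- oracle_dominant_freq(s, 30, band = c(0.5, 5))
  expect_lt(abs(f - 1.2), 1 / 1.6)

  # constant trace maps to the zero signal
  flat <- rgb_trace(rep(100, 90), rep(80, 90), rep(60, 90), fps = 30)
  expect_equal(pos_sliding(flat), rep(0, 90))

  # trace shorter than one window
  expect_error(pos_sliding(rgb_trace(1:10, 1:10, 1:10, fps = 30)),
               "insufficient")
})

test_that("POS output is invariant to overall intensity scaling", {
  set.seed(99)
  rr <- gen_rr(30, 75, sd_ms = 30)
  tr <- gen_trace(rr, 30, fitzpatrick = 2, noise_sd = 0.05)
  for (c0 in c(0.5, 2, 7.3)) {
    scaled <- rgb_trace(tr$R * c0, tr$G * c0, tr$B * c0, fps = tr$fps)
    expect_lt(max(abs(pos_sliding(scaled) - pos_sliding(tr))), 1e-9)
  }
})

test_that("band-pass keeps the pulse band and rejects drift", {
  fs <- 30
  t <- (0:(fs * 30 - 1)) / fs
  slow <- sin(2 * pi * 0.1 * t)
  out <- bandpass(slow, fs)
  expect_lt(max(abs(out[200:600])), 0.1)   # < 10% of unit amplitude

  inband <- sin(2 * pi * 1.5 * t)
  out <- bandpass(inband, fs)
  mid <- 200:700
  expect_lt(abs(max(abs(out[mid])) - 1), 0.05)

  expect_lt(max(abs(bandpass(rep(5, 900), fs))), 1e-9)
  expect_error(bandpass(slow, fs = 1.2), "unusable")
})

test_that("heartbeat template is centred and symmetric for a pure tone", {
  fs <- 30
  t <- (0:(fs * 60 - 1)) / fs
  s <- cos(2 * pi * 1 * t)    # maxima exactly on samples
  tpl <- build_template(s, fs)
  expect_equal(tpl$K, round(0.25 * fs))
  expect_length(tpl$t, 2 * tpl$K + 1)
  expect_equal(which.max(tpl$t), tpl$K + 1)           # peak at lag 0
  expect_lt(max(abs(tpl$t - rev(tpl$t))), 1e-6)       # t[k] = t[-k]

  # fewer than three usable peaks is a template failure
  two_beats <- as.numeric(gen_ppg(c(1000, 1000), fs))
  expect_error(build_template(two_beats, fs), "template failure")
})

test_that("conv_filter matches its brute-force oracle and both printed forms", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(60:200, 1)
    K <- sample(2:8, 1)
    x <- rnorm(n)
    tt <- rnorm(2 * K + 1)
    tpl <- pulse_template(tt, K)
    got <- conv_filter(x, tpl)
    expect_equal(got, oracle_conv(x, tt), tolerance = 1e-12)
    # correlation and convolution forms are algebraically identical
    expect_equal(got, conv_filter(x, tpl, form = "convolution"),
                 tolerance = 1e-12)
  }

  # unit impulse template with K = 1 scales the signal by 1/3
  x <- rnorm(50)
  tpl <- pulse_template(c(0, 1, 0), 1)
  expect_equal(conv_filter(x, tpl), x / 3, tolerance = 1e-12)

  # matched sinusoid keeps the fundamental
  fs <- 30
  s <- sin(2 * pi * 1.3 * (0:(fs * 40 - 1)) / fs)
  tpl <- build_template(s, fs)
  sh <- conv_filter(s, tpl)
  expect_lt(abs(oracle_dominant_freq(sh, fs) - 1.3), 0.05)

  expect_error(conv_filter(rnorm(5), pulse_template(rnorm(21), 10)), "longer")
})

test_that("extract_pulse falls back to band-passed POS when no template", {
  # constant trace: zero pulse, no detectable rhythm
  tr <- rgb_trace(rep(100, 900), rep(80, 900), rep(60, 900), fps = 30)
  pu <- extract_pulse(tr)
  expect_false(pu$template_ok)
  expect_length(pu$s_heart, 900)

  set.seed(4)
  rr <- gen_rr(40, 70, sd_ms = 30)
  tr2 <- gen_trace(rr, 30, fitzpatrick = 1, noise_sd = 0.05)
  pu2 <- extract_pulse(tr2)
  expect_true(pu2$template_ok)
  expect_length(pu2$s_heart, length(pu2$s_orig))
})
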