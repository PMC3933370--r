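test_that("Hilbert envelope recovers tone amplitude and AM modulation", {
  fs <- 8000
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  A <- 0.7
  tr <- hilbert_envelope(lung_sound(A * sin(2 * pi * 100 * tt), fs))
  centre <- seq(round(0.05 * fs), round(0.95 * fs))
  expect_lt(max(abs(tr$raw_envelope[centre] - A)), 0.02 * A)

  am <- (1 + 0.5 * cos(2 * pi * 2 * tt)) * sin(2 * pi * 200 * tt)
  tr2 <- hilbert_envelope(lung_sound(am, fs))
  target <- 1 + 0.5 * cos(2 * pi * 2 * tt)
  rmse <- sqrt(mean((tr2$raw_envelope[centre] - target[centre])^2))
  expect_lt(rmse, 0.03)
})

test_that("the analytic envelope bounds the signal from above", {
  set.seed(21)
  x <- signal::filtfilt(signal::butter(4, c(100, 800) / 4000, "pass"),
                        rnorm(4000))
  s <- lung_sound(x / max(abs(x)), 8000)
  tr <- hilbert_envelope(s)
  expect_true(all(tr$raw_envelope >= abs(s$samples) - 1e-9))
})

test_that("envelope smoothing passes DC, kills fast ripple, keeps breath rates", {
  fs <- 2000
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  tr <- hilbert_envelope(lung_sound(rep(0.5, length(tt)), fs))
  tr$raw_envelope <- rep(0.5, length(tt))
  sm <- smooth_envelope(tr)
  expect_lt(max(abs(sm$smoothed_envelope - 0.5)), 1e-6 * 0.5)

  tr$raw_envelope <- 1 + 0.3 * sin(2 * pi * 0.5 * tt) + 0.3 * sin(2 * pi * 50 * tt)
  sm <- smooth_envelope(tr)
  amp_at <- function(env, f) {
    sp <- Mod(fft(env - mean(env)))[seq_len(length(env) / 2)]
    sp[round(f * 8) + 1L] # 8 s window -> bin spacing 1/8 Hz
  }
  slow_ratio <- amp_at(sm$smoothed_envelope, 0.5) / amp_at(tr$raw_envelope, 0.5)
  fast_ratio <- amp_at(sm$smoothed_envelope, 50) / amp_at(tr$raw_envelope, 50)
  expect_gt(slow_ratio, 0.95)
  expect_lt(20 * log10(fast_ratio), -40)

  expect_error(smooth_envelope(tr, cutoff_hz = 1500), "Nyquist")
})

test_that("zero-phase smoothing preserves the peak of a symmetric pulse", {
  fs <- 1000
  n <- 4000
  pulse <- exp(-((seq_len(n) - 2000)^2) / (2 * 150^2))
  tr <- structure(list(raw_envelope = pulse, smoothed_envelope = NULL,
                       sampling_rate_hz = fs), class = "envelope_trace")
  for (kind in c("iir_butterworth", "fir_sinc")) {
    sm <- smooth_envelope(tr, kind = kind)
    expect_equal(which.max(sm$smoothed_envelope), 2000L)
  }
})

test_that("transition points land on the minima of a cosine envelope", {
  fs <- 8000
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  env <- 1 - cos(2 * pi * 0.25 * tt) # minima at t = 0, 4, 8 s
  tr <- structure(list(raw_envelope = env, smoothed_envelope = NULL,
                       sampling_rate_hz = fs), class = "envelope_trace")
  tp <- find_transition_points(smooth_envelope(tr))
  interior <- tp[tp > fs & tp < 7 * fs]
  expect_length(interior, 1L)
  expect_lt(abs(interior - 4 * fs) / fs, 0.05)
})

test_that("a strictly monotone envelope yields no complete phase", {
  tr <- structure(list(raw_envelope = seq(0, 1, length.out = 4000),
                       smoothed_envelope = NULL, sampling_rate_hz = 1000),
                  class = "envelope_trace")
  expect_error(find_transition_points(smooth_envelope(tr), include_endpoints = FALSE),
               "no complete phase")
})

test_that("synthetic breath boundaries are recovered within 100 ms", {
  for (s in 1:5) {
    rec <- generate_normal(gen_config(seed = 300 + s, n_cycles = 2))
    tr <- smooth_envelope(hilbert_envelope(rec$signal))
    tp <- find_transition_points(tr)
    expect_length(tp, length(rec$true_boundaries))
    err_ms <- abs(tp - rec$true_boundaries) / rec$signal$sampling_rate_hz * 1000
    expect_lt(max(err_ms), 100)
  }
})

test_that("cycle assembly arithmetic and phase pairing are exact", {
  cyc <- assemble_cycles(c(0, 8000, 16000), 16000, 8000)
  expect_identical(nrow(cyc), 1L)
  expect_equal(cyc$start_sample, 0L)
  expect_equal(cyc$end_sample, 16000L)
  expect_equal(cyc$duration_s, 2)

  cyc2 <- assemble_cycles(c(0, 8000, 16000, 24000, 32000), 32000, 8000)
  expect_identical(nrow(cyc2), 2L)
  expect_equal(cyc2$duration_s, c(2, 2))

  expect_message(cyc3 <- assemble_cycles(c(0, 8000, 16000, 24000), 24000, 8000),
                 "unpaired")
  expect_identical(nrow(cyc3), 1L)

  expect_error(assemble_cycles(c(0, 8000), 8000, 8000), "at least 3")
})

test_that("cycles tile the span between the first and last used minima", {
  set.seed(31)
  for (k in 1:20) {
    n_tp <- sample(3:9, 1)
    tp <- sort(sample.int(100000L, n_tp))
    suppressMessages(cyc <- assemble_cycles(tp, 100001L, 8000))
    expect_true(all(cyc$start_sample[-1] == cyc$end_sample[-nrow(cyc)]))
    expect_identical(cyc$start_sample[1], tp[1])
    used <- 2L * nrow(cyc) + 1L
    expect_identical(cyc$end_sample[nrow(cyc)], tp[used])
    expect_true(all(cyc$transition_sample > cyc$start_sample &
                      cyc$transition_sample < cyc$end_sample))
  }
})

test_that("segmentation is invariant to amplitude scaling", {
  rec <- generate_normal(gen_config(seed = 77, n_cycles = 2))
  cyc1 <- segment_cycles(rec$signal)
  scaled <- rec$signal
  scaled$samples <- scaled$samples * 3.7
  cyc2 <- segment_cycles(scaled)
  expect_identical(cyc1$start_sample, cyc2$start_sample)
  expect_identical(cyc1$end_sample, cyc2$end_sample)
})
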