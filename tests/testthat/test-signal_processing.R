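test_that("residual-budget spline reproduces exact and linear inputs", {
  t <- (0:399) / 100
  sine <- sin(2 * pi * 2 * t)
  expect_equal(smooth_signal(sine, 0, fps = 100)$values, sine,
               tolerance = 1e-9)
  line <- 0.5 + 0.25 * seq_len(50)
  expect_equal(smooth_signal(line, 10, fps = 100)$values, line,
               tolerance = 1e-9)
  expect_cw_error(smooth_signal(c(1, 2, 3), 0), "length")
})

test_that("spline smoothing denoises without destroying extrema", {
  set.seed(5)
  t <- (0:999) / 100
  clean <- sin(2 * pi * 1.5 * t)
  sigma <- 0.15
  noisy <- clean + rnorm(length(t), 0, sigma)
  sm <- smooth_signal(noisy, smoothing_factor = length(t) * sigma^2, fps = 100)
  rmse <- sqrt(mean((sm$values - clean)^2))
  expect_lt(rmse, 2 * sigma)
  pk_clean <- detect_peaks(clean, fps = 100, max_bpm = 200)
  pk_sm <- detect_peaks(sm$values, fps = 100, max_bpm = 200)
  expect_equal(length(pk_sm$maxima), length(pk_clean$maxima))
  expect_equal(length(pk_sm$minima), length(pk_clean$minima))
})

test_that("default smoothing budget tracks the noise level", {
  set.seed(9)
  sigma <- 2
  x <- sin(2 * pi * (0:799) / 80) * 20 + rnorm(800, 0, sigma)
  budget <- default_smoothing_factor(x)
  # budget ~ n * sigma^2, within a factor of 2 (robust estimator)
  expect_gt(budget, 800 * sigma^2 / 2)
  expect_lt(budget, 800 * sigma^2 * 2)
})

test_that("zero-phase bandpass preserves in-band tones and kills the rest", {
  fps <- 200
  t <- (0:1999) / fps
  tone <- sin(2 * pi * 2.5 * t)
  out <- bandpass_filter(tone, fps, 0.5, 5)$values
  core <- 500:1500  # away from filter edge transients
  expect_lt(abs(max(abs(out[core])) - 1), 0.05)   # amplitude within 5%
  # zero phase: filtered tone aligns with the input at lag 0
  expect_identical(cross_correlation(tone[core], out[core],
                                     max_delay = 40)$peak_lag, 0L)

  hi <- sin(2 * pi * 20 * t)
  expect_lt(max(abs(bandpass_filter(hi, fps, 0.5, 5)$values[core])), 0.1)

  flat <- bandpass_filter(rep(3, 500), fps, 0.5, 5)$values
  expect_lt(max(abs(flat)), 1e-8)

  expect_cw_error(bandpass_filter(tone, fps, 0.5, 150), "band")

  # near-idempotence within the band
  twice <- bandpass_filter(out, fps, 0.5, 5)$values
  expect_lt(abs(max(abs(twice[core])) - max(abs(out[core]))) /
              max(abs(out[core])), 0.1)
})

test_that("peak detection counts periodic extrema and ignores flat input", {
  fps <- 200
  tone <- sin(2 * pi * 2.5 * (0:1999) / fps)
  pk <- detect_peaks(tone, fps, max_bpm = 400)
  expect_true(abs(length(pk$maxima) - 25) <= 1)
  expect_true(abs(length(pk$minima) - 25) <= 1)

  flat <- detect_peaks(rep(1, 100), fps = 30)
  expect_length(flat$maxima, 0)
  expect_length(flat$minima, 0)
})

test_that("peak detection is amplitude-scale invariant and interleaved", {
  set.seed(21)
  fps <- 50
  x <- sin(2 * pi * 1.3 * (0:499) / fps) + rnorm(500, 0, 0.2)
  base <- detect_peaks(x, fps)
  for (c in c(0.01, 3, 250)) {
    scaled <- detect_peaks(c * x, fps)
    expect_identical(scaled$maxima, base$maxima)
    expect_identical(scaled$minima, base$minima)
  }
  # strict interleaving: event types alternate when merged
  ev <- rbind(cbind(base$maxima, 1), cbind(base$minima, -1))
  ev <- ev[order(ev[, 1]), ]
  expect_true(all(diff(ev[, 2]) != 0))
  expect_true(!is.unsorted(base$maxima, strictly = TRUE))
  expect_true(!is.unsorted(base$minima, strictly = TRUE))
})

test_that("true beat minima are recovered on a synthetic clip", {
  spec <- synth_spec(seed = 3, bright = FALSE)  # darkening pulses: beats at minima
  truth <- generate_beat_times(spec)
  clip <- render_frames(spec, truth)
  sig <- extract_signal(clip, bounding_box(14, 28, 32, 24), "atrium")
  cond <- bandpass_filter(smooth_signal(normalize_signal(sig)), 200, 0.5, 5)
  pk <- detect_peaks(cond, 200)
  # interior beats only: pulses cut by the clip edges have no full trough
  beat_frames <- round(truth$atrium_beat_times * 200)
  beat_frames <- beat_frames[-c(1, length(beat_frames))]
  matched <- vapply(beat_frames, function(b) min(abs(pk$minima - b)),
                    numeric(1))
  expect_lte(max(matched), 2)  # each true beat within 2 frames of a trough
})

test_that("dominant frequency finds the strongest in-band component", {
  fps <- 200
  t <- (0:1999) / fps
  pure <- dominant_frequency(sin(2 * pi * 2.5 * t), fps, band = c(0.5, 5))
  expect_lt(abs(pure$frequency_hz - 2.5), pure$resolution_hz + 1e-12)
  mix <- sin(2 * pi * 2.5 * t) + 0.2 * sin(2 * pi * 1 * t)
  expect_lt(abs(dominant_frequency(mix, fps, c(0.5, 5))$frequency_hz - 2.5),
            fps / length(t) + 1e-12)
  expect_cw_error(dominant_frequency(sin(t), fps, band = c(1, 500)), "band")
})
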