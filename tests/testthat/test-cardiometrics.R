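test_that("bpm follows 60 over the mean inter-beat interval", {
  expect_equal(compute_bpm(c(0, 80, 160, 240), 0.005), 150)
  expect_equal(compute_bpm(c(0, 100), 0.005), 120)
  # intervals of 0.4, 0.5, 0.6 s -> mean 0.5 s -> 120 bpm
  expect_equal(compute_bpm(cumsum(c(0, 0.4, 0.5, 0.6)) / 0.001, 0.001), 120,
               tolerance = 1e-9)
  expect_cw_error(compute_bpm(c(10), 0.005), "insufficient_beats")

  # randomized sets against the brute-force 60 / mean-interval oracle
  set.seed(100)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    frames <- cumsum(c(0, sample(20:200, n - 1, replace = TRUE)))
    fd <- runif(1, 0.001, 0.02)
    oracle <- 60 / mean(diff(frames * fd))
    expect_equal(compute_bpm(frames, fd), oracle, tolerance = 1e-9)
    # time-shift invariance
    expect_equal(compute_bpm(frames + 17, fd), oracle, tolerance = 1e-9)
  }
})

test_that("round_half_up breaks ties toward +Inf", {
  expect_equal(round_half_up(117.5), 118)
  expect_equal(round_half_up(117.4), 117)
  expect_equal(round_half_up(-0.5), 0)
  expect_equal(round_half_up(c(2.5, 3.5, -1.5)), c(3, 4, -1))
  expect_cw_error(round_half_up(Inf), "domain")
})

test_that("same-chamber intervals are consecutive differences", {
  b <- beat_series("atrium", c(0, 0.5, 1.0))
  expect_equal(chamber_intervals(b)$values, c(0.5, 0.5))
  expect_equal(chamber_intervals(b)$kind, "AA")
  b2 <- beat_series("ventricle", c(0, 0.4, 1.0))
  expect_equal(chamber_intervals(b2)$values, c(0.4, 0.6))
  expect_equal(chamber_intervals(b2)$kind, "VV")
  expect_cw_error(chamber_intervals(beat_series("atrium", 1)),
                  "insufficient_beats")

  # generated jittered beats: differences match the drawn intervals exactly
  truth <- generate_beat_times(synth_spec(beat_jitter_sd_s = 0.01, seed = 8))
  iv <- chamber_intervals(beat_series("atrium", truth$atrium_beat_times))
  expect_equal(iv$values, truth$intervals)
})

test_that("cross-chamber pairing takes the earliest strictly later beat", {
  a <- beat_series("atrium", c(0, 0.5, 1.0))
  v <- beat_series("ventricle", c(0.12, 0.62, 1.12))
  cc <- cross_chamber_intervals(a, v)
  expect_equal(cc$av$values, rep(0.12, 3), tolerance = 1e-12)
  expect_equal(cc$va$values, rep(0.38, 2), tolerance = 1e-12)
  expect_equal(cc$av$kind, "AV")
  expect_equal(cc$va$kind, "VA")

  lone <- beat_series("atrium", 5)
  late_v <- beat_series("ventricle", 1)
  expect_warning(cc2 <- cross_chamber_intervals(lone, late_v),
                 class = "cardiowave_warning_empty_pairing")
  expect_length(cc2$av$values, 0)
})

test_that("Poincare sd1/sd2 match the direct formulas", {
  const <- structure(list(kind = "AA", values = rep(0.5, 10)),
                     class = "interval_series")
  p <- poincare(const)
  expect_equal(p$sd1, 0)
  expect_equal(p$sd2, 0)

  alt <- structure(list(kind = "AA", values = rep(c(0.4, 0.6), 10)),
                   class = "interval_series")
  pa <- poincare(alt)
  # oracle: population sd of successive differences / sqrt(2); sums constant
  d <- diff(alt$values) / sqrt(2)
  expect_equal(pa$sd1, sqrt(mean((d - mean(d))^2)), tolerance = 1e-12)
  expect_equal(pa$sd1, 0.2 / sqrt(2), tolerance = 1e-2)
  expect_equal(pa$sd2, 0, tolerance = 1e-12)

  expect_cw_error(poincare(structure(list(kind = "AA", values = c(1, 2)),
                                     class = "interval_series")),
                  "insufficient_beats")
})

test_that("Poincare statistics shift-invariant and scale-equivariant", {
  set.seed(13)
  v <- runif(30, 0.3, 0.5)
  iv <- structure(list(kind = "AA", values = v), class = "interval_series")
  p <- poincare(iv)
  shifted <- structure(list(kind = "AA", values = v + 0.7),
                       class = "interval_series")
  expect_equal(poincare(shifted)$sd1, p$sd1, tolerance = 1e-12)
  expect_equal(poincare(shifted)$sd2, p$sd2, tolerance = 1e-12)
  scaled <- structure(list(kind = "AA", values = 3 * v),
                      class = "interval_series")
  expect_equal(poincare(scaled)$sd1, 3 * p$sd1, tolerance = 1e-12)
  expect_equal(poincare(scaled)$sd2, 3 * p$sd2, tolerance = 1e-12)
})

test_that("beat-time jitter sigma maps to sd1 = sigma * sqrt(3)", {
  sigma <- 0.01
  spec <- synth_spec(fps = 100, duration_s = 400, mean_bpm = 150,
                     beat_jitter_sd_s = sigma, pixel_noise_sd = 0, seed = 2)
  truth <- generate_beat_times(spec)  # ~1000 beats
  p <- poincare(chamber_intervals(beat_series("atrium",
                                              truth$atrium_beat_times)))
  expect_lt(abs(p$sd1 - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.15)
})

test_that("cross-correlation matches a brute-force oracle and stays in [-1, 1]", {
  set.seed(7)
  x <- rnorm(40)
  # brute-force double loop, written independently of the implementation
  brute_r <- function(x, y, d) {
    mx <- mean(x); my <- mean(y)
    num <- den_y <- 0
    den_x <- sum((x - mx)^2)
    for (i in seq_along(x)) {
      j <- i + d
      yj <- if (j >= 1 && j <= length(y)) y[j] - my else 0
      num <- num + (x[i] - mx) * yj
      den_y <- den_y + yj^2
    }
    if (den_y == 0) 0 else num / sqrt(den_x * den_y)
  }
  cc <- cross_correlation(x, x, max_delay = 15)
  expect_equal(cc$r[cc$delays == 0], 1, tolerance = 1e-12)
  for (d in c(-15, -3, 0, 4, 15))
    expect_equal(cc$r[cc$delays == d], brute_r(x, x, d), tolerance = 1e-12)

  y <- -x
  expect_equal(cross_correlation(x, y)$r[cross_correlation(x, y)$delays == 0],
               -1, tolerance = 1e-12)

  # delayed-copy lag recovery
  for (k in 1:10) {
    z <- rnorm(60)
    zd <- c(rep(0, k), z[1:(60 - k)])  # z delayed by k samples
    expect_equal(cross_correlation(z, zd, max_delay = 20)$peak_lag, k)
  }

  expect_cw_error(cross_correlation(rep(1, 10), rnorm(10)), "zero_variance")
  expect_cw_error(cross_correlation(rnorm(5), rnorm(6)), "shape")
})

test_that("|r| <= 1 over many random series pairs", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    cc <- cross_correlation(rnorm(n), rnorm(n) * runif(1, 0.1, 10))
    expect_true(all(abs(cc$r) <= 1 + 1e-12))
  }
})

test_that("interval rescaling multiplies values and keeps kind", {
  iv <- structure(list(kind = "AA", values = c(0.4, 0.4)),
                  class = "interval_series")
  out <- rescale_intervals(iv, 6.6)
  expect_equal(out$values, c(2.64, 2.64))
  expect_equal(out$kind, "AA")
  expect_equal(rescale_intervals(iv, 1)$values, iv$values)
  expect_cw_error(rescale_intervals(iv, 0), "domain")
})

test_that("report aggregates endpoints and round-trips through CSV", {
  a <- beat_series("atrium", seq(0, 4, by = 0.4))
  v <- beat_series("ventricle", seq(0, 4, by = 0.4) + 0.1)
  rep <- build_report(a, v, fps = 200, frame_dur = 0.005)
  expect_equal(unname(rep$bpm), c(150, 150))
  expect_equal(unname(rep$bpm_rounded), c(150, 150))
  expect_equal(mean(rep$intervals$AV$values), 0.1, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".csv")
  df <- report_table(rep, path)
  back <- read_report(path)
  expect_equal(back$value, df$value, tolerance = 1e-12)
  expect_identical(back$metric, df$metric)

  flat <- beat_series("ventricle", 2)
  expect_cw_error(build_report(a, flat, fps = 200), "insufficient_beats")
})
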