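test_that("beat times follow the spec and its ground-truth relations", {
  spec <- synth_spec(mean_bpm = 150, beat_jitter_sd_s = 0, duration_s = 10,
                     av_delay_s = 0.1)
  truth <- generate_beat_times(spec)
  expect_equal(truth$atrium_beat_times, seq(0, 9.6, by = 0.4))
  expect_length(truth$atrium_beat_times, 25)
  common <- seq_along(truth$ventricle_beat_times)
  expect_equal(truth$ventricle_beat_times,
               truth$atrium_beat_times[common] + 0.1)
  expect_true(!is.unsorted(truth$atrium_beat_times, strictly = TRUE))

  expect_cw_error(synth_spec(mean_bpm = 150, pulse_width_s = 0.5), "spec")
  expect_cw_error(
    generate_beat_times(synth_spec(beat_jitter_sd_s = 0.3, seed = 4)),
    "spec")
})

test_that("generation is deterministic in spec + seed", {
  spec <- synth_spec(beat_jitter_sd_s = 0.01, seed = 7)
  t1 <- generate_beat_times(spec)
  t2 <- generate_beat_times(spec)
  expect_identical(t1$atrium_beat_times, t2$atrium_beat_times)
  c1 <- render_frames(synth_spec(duration_s = 1, seed = 7))
  c2 <- render_frames(synth_spec(duration_s = 1, seed = 7))
  expect_identical(c1$frames, c2$frames)
  c3 <- render_frames(synth_spec(duration_s = 1, seed = 8))
  expect_false(identical(c1$frames, c3$frames))
})

test_that("successive interval differences have sd sqrt(6) x jitter", {
  sigma <- 0.01
  spec <- synth_spec(fps = 50, duration_s = 400, beat_jitter_sd_s = sigma,
                     mean_bpm = 150, pixel_noise_sd = 0, seed = 31)
  truth <- generate_beat_times(spec)  # ~1000 beats
  dd <- diff(diff(truth$atrium_beat_times))
  # var(e[k+2] - 2 e[k+1] + e[k]) = 6 sigma^2
  expect_lt(abs(stats::sd(dd) - sqrt(6) * sigma) / (sqrt(6) * sigma), 0.1)
})

test_that("rendered chamber intensity follows the raised-cosine pulse", {
  spec <- synth_spec(fps = 100, duration_s = 2, pixel_noise_sd = 0, seed = 1)
  truth <- generate_beat_times(spec)
  clip <- render_frames(spec, truth)
  box <- bounding_box(22, 34, 12, 10)  # interior of the atrium ellipse
  sig <- extract_signal(clip, box, "atrium")
  beat_frame <- round(truth$atrium_beat_times[2] * spec$fps)
  mid_frame <- round(mean(truth$atrium_beat_times[2:3]) * spec$fps)
  expect_lt(abs(sig$values[beat_frame + 1] -
                  (spec$baseline_intensity + spec$pulse_amplitude)), 1)
  expect_lt(abs(sig$values[mid_frame + 1] - spec$baseline_intensity), 1)
  # background stays at baseline
  bg <- extract_signal(clip, bounding_box(0, 0, 8, 8), "atrium")
  expect_true(all(abs(bg$values - spec$baseline_intensity) < 1))
})

test_that("ROI mean series oscillates at the generator beat frequency", {
  clip <- quiet_clip()  # 100 fps, 150 bpm
  sig <- extract_signal(clip, bounding_box(14, 28, 32, 24), "atrium")
  dom <- dominant_frequency(sig$values, 100, band = c(0.5, 5))
  expect_lt(abs(dom$frequency_hz - 2.5), dom$resolution_hz + 1e-12)
})

test_that("video writer validates input and names unavailable codecs", {
  clip <- quiet_clip()
  expect_cw_error(write_video(clip, tempfile(), codec = "mp4"), "environment")
  truth <- generate_beat_times(synth_spec())
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$atrium_beat_times, truth$atrium_beat_times)
  expect_equal(back$spec$mean_bpm, 150)
})

test_that("synth_command writes a reloadable video and truth pair", {
  out <- withr::local_tempdir()
  paths <- synth_command(out, duration_s = 1, pixel_noise_sd = 0, seed = 5)
  expect_true(file.exists(paths$video))
  expect_true(file.exists(paths$truth))
  clip <- load_video(paths$video)
  expect_equal(clip$n_frames, 200)
  expect_equal(clip$fps, 200)
  # identical flags + seed run twice -> identical bytes
  out2 <- withr::local_tempdir()
  paths2 <- synth_command(out2, duration_s = 1, pixel_noise_sd = 0, seed = 5)
  expect_identical(readBin(paths$video, "raw", file.size(paths$video)),
                   readBin(paths2$video, "raw", file.size(paths2$video)))
})
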