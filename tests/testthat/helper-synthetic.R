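# Shared fixtures: small synthetic clips, memoized per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# default ROIs matching synth_spec()'s chamber geometry
synth_rois <- function() {
  list(atrium = "14,28,32,24", ventricle = "65,25,40,30")
}

# short, quiet clip for structural tests (2 s @ 100 fps, no noise)
quiet_clip <- function() {
  memo("quiet_clip", {
    spec <- synth_spec(fps = 100, duration_s = 2, pixel_noise_sd = 0, seed = 11)
    render_frames(spec)
  })
}

# the headline study condition: 10 s @ 200 fps, 150 bpm, noise sd 5
study_clip <- function() {
  memo("study_clip", render_frames(synth_spec(seed = 42)))
}

run_synth_pipeline <- function(clip, ...) {
  run_pipeline(run_config(clip, roi = synth_rois(), ...))
}

expect_cw_error <- function(expr, what) {
  expect_error(expr, class = paste0("cardiowave_error_", what))
}
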