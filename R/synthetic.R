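#' Specification of a synthetic beating-heart clip
#'
#' Describes a clip with two spatially separated pulsating ellipses (atrium
#' and ventricle), a fixed atrium-to-ventricle phase delay, quasi-periodic
#' beat times with optional i.i.d. Gaussian jitter, a raised-cosine
#' intensity pulse per beat, and additive Gaussian pixel noise. Defaults
#' emulate a 10 s, 200 fps lateral-view recording of a zebrafish larva
#' beating at 150 bpm. Identical spec + seed produce bitwise-identical
#' output.
#'
#' @param fps frames per second.
#' @param duration_s clip length in seconds.
#' @param mean_bpm mean beat rate.
#' @param beat_jitter_sd_s sd of the i.i.d. Gaussian jitter added to each
#'   beat *time* (not interval), in seconds.
#' @param av_delay_s ventricle beat lag behind the atrium, in seconds.
#' @param width,height frame size in pixels.
#' @param atrium_center,ventricle_center ellipse centers `(x, y)` in pixels
#'   (0-based).
#' @param atrium_radii,ventricle_radii ellipse semi-axes `(rx, ry)`.
#' @param baseline_intensity background grey level.
#' @param pulse_amplitude pulse height in grey levels; positive means the
#'   chamber brightens at a beat (set `bright = FALSE` for darkening
#'   optics).
#' @param pulse_width_s raised-cosine support, must be shorter than one
#'   beat period.
#' @param pixel_noise_sd additive Gaussian noise sd (grey levels).
#' @param bright logical; pulse sign (see `pulse_amplitude`).
#' @param seed integer RNG seed.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(fps = 200, duration_s = 10, mean_bpm = 150,
                       beat_jitter_sd_s = 0, av_delay_s = 0.1,
                       width = 120, height = 80,
                       atrium_center = c(30, 40), atrium_radii = c(16, 12),
                       ventricle_center = c(85, 40), ventricle_radii = c(20, 15),
                       baseline_intensity = 120, pulse_amplitude = 60,
                       pulse_width_s = 0.15, pixel_noise_sd = 5,
                       bright = TRUE, seed = 1L) {
  if (mean_bpm <= 0) cw_abort("spec", "`mean_bpm` must be positive")
  if (av_delay_s < 0) cw_abort("spec", "`av_delay_s` must be >= 0")
  if (pulse_width_s >= 60 / mean_bpm)
    cw_abort("spec",
             sprintf("`pulse_width_s` (%g) must be below the beat period (%g s)",
                     pulse_width_s, 60 / mean_bpm))
  if (baseline_intensity + abs(pulse_amplitude) > 255 ||
      baseline_intensity - (if (bright) 0 else abs(pulse_amplitude)) < 0)
    cw_abort("spec", "baseline +/- amplitude must stay inside [0, 255]")
  ellipse_ok <- function(center, radii)
    center[1] - radii[1] >= 0 && center[1] + radii[1] < width &&
      center[2] - radii[2] >= 0 && center[2] + radii[2] < height
  if (!ellipse_ok(atrium_center, atrium_radii))
    cw_abort("spec", "atrium ellipse extends outside the frame")
  if (!ellipse_ok(ventricle_center, ventricle_radii))
    cw_abort("spec", "ventricle ellipse extends outside the frame")
  structure(list(fps = fps, duration_s = duration_s, mean_bpm = mean_bpm,
                 beat_jitter_sd_s = beat_jitter_sd_s, av_delay_s = av_delay_s,
                 width = width, height = height,
                 atrium_center = atrium_center, atrium_radii = atrium_radii,
                 ventricle_center = ventricle_center,
                 ventricle_radii = ventricle_radii,
                 baseline_intensity = baseline_intensity,
                 pulse_amplitude = abs(pulse_amplitude) * (if (bright) 1 else -1),
                 pulse_width_s = pulse_width_s,
                 pixel_noise_sd = pixel_noise_sd, bright = bright,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Draw ground-truth beat times
#'
#' Atrium beats at `t_k = k * (60 / mean_bpm) + e_k` with
#' `e_k ~ N(0, beat_jitter_sd_s^2)` i.i.d., re-sorted and truncated to the
#' clip duration; ventricle beats are the atrium beats shifted by the A-V
#' delay. Jitter large enough to push two pulses within one pulse width of
#' each other is rejected, since beat identity would collapse.
#'
#' @param spec a [synth_spec].
#' @return Object of class `ground_truth` with `atrium_beat_times`,
#'   `ventricle_beat_times`, `intervals` (the drawn A-A differences), and
#'   the spec echo.
#' @export
generate_beat_times <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  period <- 60 / spec$mean_bpm
  k <- 0:ceiling(spec$duration_s / period)
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(withr_seed)
  eps <- stats::rnorm(length(k), 0, spec$beat_jitter_sd_s)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  at <- sort(k * period + eps)
  at <- at[at >= 0 & at < spec$duration_s]
  if (length(at) >= 2 && any(diff(at) <= spec$pulse_width_s))
    cw_abort("spec",
             "beat jitter collapses adjacent beats within one pulse width")
  vt <- at + spec$av_delay_s
  vt <- vt[vt < spec$duration_s]
  structure(list(atrium_beat_times = at, ventricle_beat_times = vt,
                 intervals = diff(at), spec = spec),
            class = "ground_truth")
}

# raised-cosine pulse activation at time t for a sorted vector of beat times
pulse_activation <- function(t, beat_times, width) {
  a <- numeric(length(t))
  for (b in beat_times) {
    inside <- abs(t - b) <= width / 2
    a[inside] <- a[inside] + 0.5 * (1 + cos(2 * pi * (t[inside] - b) / width))
  }
  pmin(a, 1)
}

#' Render the synthetic clip
#'
#' Each chamber ellipse's interior follows `baseline + amplitude *
#' raised-cosine(t - beat time)`; the background stays at baseline.
#' Gaussian pixel noise is added last and the result clipped to \[0, 255\].
#' Rendering is deterministic given the spec's seed.
#'
#' @param spec a [synth_spec].
#' @param truth a `ground_truth` from [generate_beat_times()]; generated
#'   when `NULL`.
#' @return A [video_clip] with `source = "synthetic"`.
#' @export
render_frames <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(truth)) truth <- generate_beat_times(spec)
  n <- floor(spec$duration_s * spec$fps)
  t <- (seq_len(n) - 1) / spec$fps
  a_act <- pulse_activation(t, truth$atrium_beat_times, spec$pulse_width_s)
  v_act <- pulse_activation(t, truth$ventricle_beat_times, spec$pulse_width_s)

  xs <- matrix(rep(0:(spec$width - 1), each = spec$height),
               spec$height, spec$width)
  ys <- matrix(rep(0:(spec$height - 1), spec$width), spec$height, spec$width)
  in_ellipse <- function(center, radii)
    ((xs - center[1]) / radii[1])^2 + ((ys - center[2]) / radii[2])^2 <= 1
  a_mask <- in_ellipse(spec$atrium_center, spec$atrium_radii)
  v_mask <- in_ellipse(spec$ventricle_center, spec$ventricle_radii)

  base <- matrix(spec$baseline_intensity, spec$height, spec$width)
  frames <- array(0, c(spec$height, spec$width, n))
  for (i in seq_len(n)) {
    f <- base
    f[a_mask] <- f[a_mask] + spec$pulse_amplitude * a_act[i]
    f[v_mask] <- f[v_mask] + spec$pulse_amplitude * v_act[i]
    frames[, , i] <- f
  }
  if (spec$pixel_noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(spec$seed + 1L)
    frames <- frames + stats::rnorm(length(frames), 0, spec$pixel_noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  frames[frames < 0] <- 0
  frames[frames > 255] <- 255
  frames <- round(frames)
  video_clip(frames, spec$fps, source = "synthetic")
}

#' Write a clip to a video file
#'
#' The lossless path encodes uncompressed 8-bit grayscale AVI, re-loadable
#' by [load_video()] with per-frame means preserved exactly. mp4 encoding
#' requires an external encoder that this package does not bundle and
#' raises an `environment` error naming the codec.
#'
#' @param clip a [video_clip] with at least one frame.
#' @param path output file path (`.avi`).
#' @param codec `"avi"` (lossless, default) or `"mp4"`.
#' @return `path`, invisibly.
#' @export
write_video <- function(clip, path, codec = c("avi", "mp4")) {
  codec <- match.arg(codec)
  stopifnot(inherits(clip, "video_clip"))
  if (clip$n_frames < 1L) cw_abort("empty_video", "cannot write a zero-length clip")
  if (codec == "mp4")
    cw_abort("environment",
             "mp4 encoder unavailable: no H.264/MPEG-4 encoder is bundled; use codec = 'avi'")
  write_avi(clip$frames, clip$fps, path)
  invisible(path)
}

#' Write the ground truth alongside a synthetic clip
#'
#' @param truth a `ground_truth`.
#' @param path JSON destination.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(atrium_beat_times = truth$atrium_beat_times,
         ventricle_beat_times = truth$ventricle_beat_times,
         intervals = truth$intervals,
         spec = unclass(truth$spec)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
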