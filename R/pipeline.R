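#' Assemble a pipeline run configuration
#'
#' Collects every knob of the analysis in one validated object. An organism
#' preset fills the filter band and heart-rate ceiling; explicit values
#' override the preset. The configuration round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param video path to an AVI file, or a [video_clip] already in memory.
#' @param roi named list / `x,y,w,h` strings with `atrium` and `ventricle`
#'   entries, or a config-file path (see [select_rois()]).
#' @param preset organism preset; see [organism_preset()].
#' @param band filter band in Hz (overrides the preset).
#' @param max_bpm physiological rate ceiling (overrides the preset).
#' @param smoothing_factor spline residual budget; `NULL` for the robust
#'   default, `NA` to skip spline smoothing.
#' @param prominence_frac peak prominence threshold (fraction of sd).
#' @param fps_override frames/second when container metadata is wrong or
#'   missing.
#' @param paper_compat logical; use 3-decimal truncated frame durations.
#' @param slowdown `NULL`, or the playback-clock rescaling factor to apply
#'   to intervals measured on slow-motion-rendered footage.
#' @param beat_anchor `"auto"` (polarity from signal skewness),
#'   `"minima"`, or `"maxima"`.
#' @param normalization `"sample"` or `"population"` sd convention.
#' @param parallel extract the two chamber signals in forked workers.
#' @param out_dir output directory for CSVs (and plots); `NULL` keeps the
#'   run in memory.
#' @param plots logical; write signal-overlay and Poincare plot images.
#' @param interactive logical; select ROIs by clicking the first frame.
#' @return Object of class `run_config`.
#' @export
run_config <- function(video, roi = NULL,
                       preset = c("zebrafish", "daphnia", "custom"),
                       band = NULL, max_bpm = NULL,
                       smoothing_factor = NULL, prominence_frac = 0.3,
                       fps_override = NULL, paper_compat = FALSE,
                       slowdown = NULL,
                       beat_anchor = c("auto", "minima", "maxima"),
                       normalization = c("sample", "population"),
                       parallel = FALSE, out_dir = NULL, plots = FALSE,
                       interactive = FALSE) {
  preset <- match.arg(preset)
  defaults <- organism_preset(preset)
  band <- if (is.null(band)) defaults$band else band
  max_bpm <- if (is.null(max_bpm)) defaults$max_bpm else max_bpm
  if (is.null(band) || is.null(max_bpm))
    cw_abort("config",
             "preset 'custom' requires explicit `band` and `max_bpm`")
  if (is.null(roi) && !interactive)
    cw_abort("config", "`roi` is required unless `interactive = TRUE`")
  structure(list(video = video, roi = roi, preset = preset, band = band,
                 max_bpm = max_bpm, smoothing_factor = smoothing_factor,
                 prominence_frac = prominence_frac,
                 fps_override = fps_override, paper_compat = paper_compat,
                 slowdown = slowdown, beat_anchor = match.arg(beat_anchor),
                 normalization = match.arg(normalization),
                 parallel = parallel, out_dir = out_dir, plots = plots,
                 interactive = interactive),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file destination (JSON).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(config$video, "video_clip"))
    cw_abort("config", "an in-memory clip cannot be serialized; pass a path")
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (sqrt(mean(x^2))^3)
}

#' Run the full cardiac-rhythm pipeline
#'
#' Executes load -> frame gate -> two-ROI extraction -> normalization ->
#' spline smoothing -> zero-phase bandpass -> beat detection -> endpoint
#' computation, and (when `out_dir` is set) writes `signals.csv`,
#' `peaks.csv`, `intervals.csv`, `crosscorr.csv`, `report.csv`, and
#' optional plot images. Every default that was applied is recorded in the
#' report's provenance so a run is reproducible from its outputs.
#'
#' Beat markers follow `beat_anchor`: troughs of the conditioned signal by
#' default for darkening optics, crests for brightening; `"auto"` picks the
#' polarity whose pulses stick out of the conditioned signal (sign of its
#' skewness), making the pipeline agnostic to the optical sign of a beat.
#'
#' @param config a [run_config].
#' @return A `cardiac_report`; intermediate signals and peak sets are
#'   attached in `attr(, "stages")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  clip <- if (inherits(config$video, "video_clip")) config$video
          else load_video(config$video, fps_override = config$fps_override)
  fps <- clip$fps
  frame_dur <- frame_duration(fps, paper_compat = config$paper_compat)

  window <- gate_frame_count(clip$n_frames)
  if (window["end"] < clip$n_frames)
    clip <- video_clip(clip$frames[, , seq_len(window["end"]), drop = FALSE],
                       fps, source = clip$source)

  rois <- select_rois(clip, roi_spec = config$roi,
                      interactive = config$interactive && is.null(config$roi))
  raw <- extract_signals(clip, rois, parallel = config$parallel)

  condition_one <- function(sig) {
    nrm <- normalize_signal(sig, convention = config$normalization)
    sm <- if (length(config$smoothing_factor) == 1 &&
              is.na(config$smoothing_factor)) {
      processed_signal(nrm$values, fps,
                       list(smoothing_factor = NA, filter_band_hz = NULL,
                            normalized = TRUE))
    } else {
      out <- smooth_signal(nrm, smoothing_factor = config$smoothing_factor,
                           fps = fps)
      out$provenance$normalized <- TRUE
      out
    }
    bandpass_filter(sm, fps, config$band[1], config$band[2])
  }
  conditioned <- lapply(raw, condition_one)

  peaks <- lapply(conditioned, detect_peaks, fps = fps,
                  max_bpm = config$max_bpm,
                  prominence_frac = config$prominence_frac)

  anchor_of <- function(sig) {
    if (config$beat_anchor != "auto") return(config$beat_anchor)
    if (skewness(sig$values) >= 0) "maxima" else "minima"
  }
  beats <- lapply(c("atrium", "ventricle"), function(ch) {
    anchor <- anchor_of(conditioned[[ch]])
    idx <- peaks[[ch]][[anchor]]
    if (length(idx) < 2L)
      cw_abort("insufficient_beats",
               sprintf("stage beat-detection, chamber %s: %d beat marker(s) found",
                       ch, length(idx)))
    beat_series(ch, idx * frame_dur)
  })
  names(beats) <- c("atrium", "ventricle")

  provenance <- list(
    source = clip$source, fps = fps, frame_dur = frame_dur,
    paper_compat = config$paper_compat,
    analyzed_frames = clip$n_frames,
    rois = lapply(rois, unclass),
    band_hz = config$band, max_bpm = config$max_bpm,
    smoothing_factor = conditioned$atrium$provenance$smoothing_factor,
    prominence_frac = config$prominence_frac,
    normalization = config$normalization,
    beat_anchor = vapply(c("atrium", "ventricle"),
                         function(ch) anchor_of(conditioned[[ch]]), ""),
    preset = config$preset, slowdown = config$slowdown
  )

  report <- build_report(beats$atrium, beats$ventricle,
                         signals = conditioned, fps = fps,
                         frame_dur = frame_dur, provenance = provenance)
  if (!is.null(config$slowdown)) {
    report$intervals <- lapply(report$intervals, rescale_intervals,
                               factor = config$slowdown)
    report$bpm <- report$bpm / config$slowdown
    report$bpm_rounded <- round_half_up(report$bpm)
  }

  if (!is.null(config$out_dir))
    write_outputs(config$out_dir, raw, conditioned, peaks, report,
                  plots = config$plots)
  attr(report, "stages") <- list(clip = clip, rois = rois, raw = raw,
                                 conditioned = conditioned, peaks = peaks,
                                 beats = beats)
  report
}

write_outputs <- function(out_dir, raw, conditioned, peaks, report, plots) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(raw$atrium$values)
  utils::write.csv(data.frame(
    frame_index = raw$atrium$frame_indices,
    time_s = raw$atrium$frame_indices * report$frame_dur,
    atrium_raw = raw$atrium$values,
    ventricle_raw = raw$ventricle$values,
    atrium_conditioned = conditioned$atrium$values,
    ventricle_conditioned = conditioned$ventricle$values
  ), file.path(out_dir, "signals.csv"), row.names = FALSE)

  peak_rows <- do.call(rbind, lapply(c("atrium", "ventricle"), function(ch) {
    p <- peaks[[ch]]
    idx <- c(p$maxima, p$minima)
    data.frame(chamber = ch, frame_index = idx,
               time_s = idx * report$frame_dur,
               value = conditioned[[ch]]$values[idx + 1L],
               is_max = c(rep(TRUE, length(p$maxima)),
                          rep(FALSE, length(p$minima))),
               is_min = c(rep(FALSE, length(p$maxima)),
                          rep(TRUE, length(p$minima))))
  }))
  peak_rows <- peak_rows[order(peak_rows$chamber, peak_rows$frame_index), ]
  utils::write.csv(peak_rows, file.path(out_dir, "peaks.csv"),
                   row.names = FALSE)

  iv_rows <- do.call(rbind, lapply(names(report$intervals), function(k) {
    v <- report$intervals[[k]]$values
    if (!length(v)) return(NULL)
    data.frame(kind = k, index = seq_along(v) - 1L, value_s = v)
  }))
  utils::write.csv(iv_rows, file.path(out_dir, "intervals.csv"),
                   row.names = FALSE)

  if (!is.null(report$crosscorr))
    utils::write.csv(data.frame(delay = report$crosscorr$profile$delays,
                                r = report$crosscorr$profile$r),
                     file.path(out_dir, "crosscorr.csv"), row.names = FALSE)

  report_table(report, file.path(out_dir, "report.csv"))

  if (plots) {
    grDevices::png(file.path(out_dir, "signals.png"), 900, 500)
    plot_signals(conditioned, report$frame_dur)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "poincare.png"), 500, 500)
    plot_poincare(report)
    grDevices::dev.off()
  }
  invisible(out_dir)
}

#' Overlay the two conditioned chamber signals
#'
#' @param conditioned named list of `processed_signal`s.
#' @param frame_dur seconds per frame for the time axis.
#' @export
plot_signals <- function(conditioned, frame_dur) {
  a <- conditioned$atrium$values
  v <- conditioned$ventricle$values
  t <- (seq_along(a) - 1) * frame_dur
  graphics::plot(t, a, type = "l", col = "blue", xlab = "time (s)",
                 ylab = "conditioned intensity",
                 ylim = range(c(a, v)),
                 main = "atrium (blue) / ventricle (red)")
  graphics::lines(t, v, col = "red")
  invisible(NULL)
}

#' Poincare scatter of same-chamber intervals
#'
#' @param report a `cardiac_report`.
#' @export
plot_poincare <- function(report) {
  aa <- report$intervals$AA$values
  vv <- report$intervals$VV$values
  lim <- range(c(aa, vv))
  graphics::plot(aa[-length(aa)], aa[-1], col = "blue", pch = 19,
                 xlim = lim, ylim = lim,
                 xlab = expression(I[n] ~ "(s)"),
                 ylab = expression(I[n + 1] ~ "(s)"),
                 main = "Poincare: atrium (blue), ventricle (red)")
  graphics::points(vv[-length(vv)], vv[-1], col = "red", pch = 19)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}

#' Generate a synthetic clip and its ground truth on disk
#'
#' Thin command wrapper over the synthetic generator: renders the clip,
#' writes a lossless AVI plus a ground-truth JSON (beat times and the full
#' spec), and returns the file paths.
#'
#' @param out_dir destination directory.
#' @param ... passed to [synth_spec()].
#' @return Named list with `video` and `truth` paths.
#' @export
synth_command <- function(out_dir, ...) {
  spec <- synth_spec(...)
  truth <- generate_beat_times(spec)
  clip <- render_frames(spec, truth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  video_path <- file.path(out_dir, "synthetic_heart.avi")
  truth_path <- file.path(out_dir, "synthetic_heart_truth.json")
  write_video(clip, video_path)
  write_ground_truth(truth, truth_path)
  list(video = video_path, truth = truth_path)
}
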