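#' Video clip container
#'
#' A `video_clip` holds a decoded grayscale frame stack together with its
#' frame rate. Frames are stored as an integer array of dimension
#' `height x width x n_frames` with intensities in \[0, 255\]; the first
#' frame plays at t = 0 and frame index `i` (0-based) at `i / fps` seconds.
#'
#' @param frames numeric or integer array `height x width x n_frames`, or a
#'   single matrix (one frame). Values must lie in \[0, 255\].
#' @param fps frames per second (> 0).
#' @param source character tag recording where the frames came from
#'   (a file path, or `"synthetic"`).
#' @return An object of class `video_clip` with fields `frames`, `fps`,
#'   `width`, `height`, `n_frames`, `source`.
#' @examples
#' clip <- video_clip(array(128L, c(8, 8, 3)), fps = 30)
#' clip$n_frames
#' @export
video_clip <- function(frames, fps, source = "in-memory") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    cw_abort("frames", "`frames` must be a height x width x n_frames array")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    cw_abort("fps", "`fps` must be a single positive number")
  rng <- range(frames)
  if (anyNA(frames) || rng[1] < 0 || rng[2] > 255)
    cw_abort("frames", "frame intensities must lie in [0, 255] with no NA")
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames, fps = as.numeric(fps),
         width = dim(frames)[2], height = dim(frames)[1],
         n_frames = dim(frames)[3], source = source),
    class = "video_clip"
  )
}

#' @export
print.video_clip <- function(x, ...) {
  cat(sprintf("<video_clip> %dx%d px, %d frames @ %g fps (%.2f s) from %s\n",
              x$width, x$height, x$n_frames, x$fps, x$n_frames / x$fps,
              x$source))
  invisible(x)
}

#' Load a heart video
#'
#' Decodes a video file into a grayscale [video_clip]. Uncompressed 8-bit
#' AVI (the classic interchange format for microscopy heart videos, and the
#' format written by [write_video()]) is decoded natively. Compressed
#' containers (mp4) need an external decoder which this package does not
#' bundle; such files raise an `unsupported_container` error asking the user
#' to transcode to uncompressed AVI first.
#'
#' @param path path to an `.avi` file.
#' @param fps_override optional frames/second; replaces (or supplies, when
#'   missing) the container's frame-rate metadata.
#' @return A [video_clip]; RGB/palette frames are converted with
#'   [to_grayscale()] weights at read time.
#' @seealso [write_video()], [resample()]
#' @export
load_video <- function(path, fps_override = NULL) {
  if (!file.exists(path))
    cw_abort("missing_file", sprintf("video file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mp4", "m4v", "mov"))
    cw_abort("unsupported_container",
             sprintf(paste0("cannot decode compressed container '%s': no ",
                            "mp4 decoder is bundled; transcode to ",
                            "uncompressed AVI (e.g. `ffmpeg -i in.mp4 ",
                            "-vcodec rawvideo -pix_fmt gray out.avi`)"),
                     path))
  avi <- read_avi(path)
  fps <- if (!is.null(fps_override)) {
    if (fps_override <= 0) cw_abort("fps", "`fps_override` must be > 0")
    fps_override
  } else avi$fps
  if (is.null(fps) || !is.finite(fps) || fps <= 0)
    cw_abort("metadata",
             sprintf(paste0("no usable fps metadata in %s; pass ",
                            "`fps_override` with the acquisition rate"), path))
  if (dim(avi$frames)[3] < 1L)
    cw_abort("empty_video", sprintf("no decodable frames in %s", path))
  video_clip(avi$frames, fps, source = path)
}

#' Convert a color frame to grayscale
#'
#' Applies ITU-R BT.601 luminance weights (0.299 R + 0.587 G + 0.114 B),
#' the de-facto convention of mainstream video decoders, rounding to the
#' nearest integer grey level. Already-grayscale frames pass through
#' unchanged.
#'
#' @param frame a `height x width` matrix (returned as-is) or a
#'   `height x width x 3` RGB array with channel values in \[0, 255\].
#' @return An integer `height x width` matrix in \[0, 255\].
#' @examples
#' to_grayscale(array(c(255, 0, 0), c(1, 1, 3)))  # pure red -> 76
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) {
    storage.mode(frame) <- "integer"
    return(frame)
  }
  d <- dim(frame)
  if (length(d) == 3L && d[3] == 1L) {
    out <- frame[, , 1L]
    storage.mode(out) <- "integer"
    return(out)
  }
  if (length(d) != 3L || d[3] != 3L)
    cw_abort("frames", "`frame` must be a matrix or an RGB array (3 channels)")
  y <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
  matrix(as.integer(round(y)), d[1], d[2])
}

#' Seconds per frame
#'
#' The exact frame duration is `1 / fps`. In `paper_compat` mode the value
#' is truncated (not rounded) to three decimal places, reproducing the
#' constants used in the original workflow this pipeline automates:
#' 200 fps -> 0.005 s and 60 fps -> 0.016 s (note 1/60 = 0.01666..., so
#' 0.016 is a truncation). The truncated constants bias bpm by about 0.4%
#' at 60 fps, which is why exact mode is the default.
#'
#' @param fps frames per second (> 0).
#' @param paper_compat logical; truncate to 3 decimals.
#' @return Seconds per frame.
#' @examples
#' frame_duration(200, paper_compat = TRUE)  # 0.005
#' frame_duration(60, paper_compat = TRUE)   # 0.016
#' @export
frame_duration <- function(fps, paper_compat = FALSE) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    cw_abort("fps", "`fps` must be a single positive number")
  if (paper_compat) trunc(1000 / fps) / 1000 else 1 / fps
}

#' Slow-motion rescaling factor
#'
#' When footage acquired at `acquisition_fps` is re-rendered for playback at
#' `playback_fps`, intervals measured against the playback clock must be
#' divided by this factor (equivalently, slow-clock intervals multiplied by
#' it) to recover real time. The ratio is truncated to one decimal place:
#' 200/30 = 6.67 becomes the conventional 6.6-fold slowdown.
#'
#' @param acquisition_fps camera frame rate (> 0).
#' @param playback_fps rendering frame rate (> 0).
#' @return Dimensionless multiplier, truncated to one decimal.
#' @examples
#' slowdown_factor(200, 30)  # 6.6
#' @export
slowdown_factor <- function(acquisition_fps, playback_fps) {
  if (!is.numeric(acquisition_fps) || acquisition_fps <= 0 ||
      !is.numeric(playback_fps) || playback_fps <= 0)
    cw_abort("fps", "both frame rates must be positive")
  trunc(10 * acquisition_fps / playback_fps) / 10
}

#' Resample a clip to a lower frame rate
#'
#' For each output timestamp `k / new_fps` (k = 0, 1, ...) the source frame
#' with the nearest timestamp is selected (no interpolation). Only
#' downsampling is supported; the output has `floor(duration * new_fps)`
#' frames so total duration is preserved within one output-frame period.
#'
#' @param clip a [video_clip].
#' @param new_fps target rate, `0 < new_fps <= clip$fps`.
#' @return A [video_clip] at `new_fps`.
#' @export
resample <- function(clip, new_fps) {
  stopifnot(inherits(clip, "video_clip"))
  if (!is.numeric(new_fps) || new_fps <= 0)
    cw_abort("fps", "`new_fps` must be positive")
  if (new_fps > clip$fps)
    cw_abort("upsampling",
             sprintf("upsampling not supported: new_fps %g > clip fps %g",
                     new_fps, clip$fps))
  duration <- clip$n_frames / clip$fps
  n_out <- floor(duration * new_fps)
  t_out <- (seq_len(n_out) - 1) / new_fps
  src <- pmin(clip$n_frames, pmax(1L, as.integer(round(t_out * clip$fps)) + 1L))
  video_clip(clip$frames[, , src, drop = FALSE], new_fps,
             source = paste0(clip$source, " @", new_fps, "fps"))
}
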