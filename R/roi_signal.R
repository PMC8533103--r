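#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner of
#' the frame; the box covers the half-open range `[x, x + w) x [y, y + h)`.
#'
#' @param x,y top-left corner in pixels (0-based).
#' @param w,h extent in pixels (>= 1).
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x, y, w, h) {
  vals <- c(x = x, y = y, w = w, h = h)
  if (anyNA(vals) || any(vals != round(vals)))
    cw_abort("bounds", "box coordinates must be whole numbers")
  if (x < 0 || y < 0 || w < 1 || h < 1)
    cw_abort("bounds",
             sprintf("invalid box x=%g y=%g w=%g h=%g (need x,y >= 0; w,h >= 1)",
                     x, y, w, h))
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> x=%d y=%d w=%d h=%d\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

chamber_labels <- c("atrium", "ventricle")

check_box_in_frame <- function(box, clip, label = NULL) {
  if (box$x + box$w > clip$width || box$y + box$h > clip$height)
    cw_abort("bounds",
             sprintf(paste0("%sbox x=%d y=%d w=%d h=%d extends past the ",
                            "%dx%d frame"),
                     if (is.null(label)) "" else paste0(label, " "),
                     box$x, box$y, box$w, box$h, clip$width, clip$height))
  invisible(box)
}

parse_box_entry <- function(entry) {
  if (inherits(entry, "bounding_box")) return(entry)
  if (is.character(entry)) entry <- as.numeric(strsplit(entry, ",")[[1]])
  if (!is.numeric(entry) || length(entry) != 4L)
    cw_abort("config", "ROI entries must be 'x,y,w,h' or a bounding_box")
  bounding_box(entry[1], entry[2], entry[3], entry[4])
}

#' Select atrium and ventricle ROIs
#'
#' Resolves the two chamber boxes either from a configuration (a named list
#' or a `key=value` config file with `atrium` and `ventricle` entries of the
#' form `x,y,w,h`) or interactively by clicking two corners per chamber on
#' the first frame. Interactive clicks may also be supplied programmatically
#' through `clicks`, which makes the interactive path scriptable; both modes
#' go through identical validation so they yield identical downstream
#' results for identical coordinates.
#'
#' @param clip a [video_clip].
#' @param roi_spec named list/character vector with `atrium` and `ventricle`
#'   entries, a path to a config file, or `NULL` for interactive mode.
#' @param interactive logical; draw the first frame and read two rectangles.
#' @param clicks optional 4x2 matrix of (x, y) corner clicks (atrium corner
#'   pair then ventricle corner pair) standing in for mouse input.
#' @return Named list `list(atrium = , ventricle = )` of [bounding_box]es.
#' @export
select_rois <- function(clip, roi_spec = NULL, interactive = FALSE,
                        clicks = NULL) {
  stopifnot(inherits(clip, "video_clip"))
  if (interactive || !is.null(clicks)) {
    pts <- if (!is.null(clicks)) {
      as.matrix(clicks)
    } else {
      graphics::image(t(clip$frames[clip$height:1, , 1]), col = grDevices::gray.colors(256),
                      axes = FALSE, main = "click 2 corners: atrium, then ventricle")
      loc <- graphics::locator(4L)
      cbind(loc$x * (clip$width - 1), loc$y * (clip$height - 1))
    }
    if (is.null(pts) || nrow(pts) != 4L)
      cw_abort("config", "interactive selection needs 4 corner clicks")
    corner_box <- function(p1, p2) {
      x0 <- floor(min(p1[1], p2[1])); y0 <- floor(min(p1[2], p2[2]))
      bounding_box(x0, y0, max(1, ceiling(abs(p2[1] - p1[1]))),
                   max(1, ceiling(abs(p2[2] - p1[2]))))
    }
    boxes <- list(atrium = corner_box(pts[1, ], pts[2, ]),
                  ventricle = corner_box(pts[3, ], pts[4, ]))
  } else {
    if (is.character(roi_spec) && length(roi_spec) == 1L &&
        file.exists(roi_spec) && !grepl(",", roi_spec))
      roi_spec <- read_config_file(roi_spec)
    roi_spec <- as.list(roi_spec)
    missing <- setdiff(chamber_labels, names(roi_spec))
    if (length(missing))
      cw_abort("config",
               sprintf("missing ROI entr%s for: %s",
                       if (length(missing) > 1) "ies" else "y",
                       paste(missing, collapse = ", ")))
    boxes <- lapply(roi_spec[chamber_labels], parse_box_entry)
  }
  for (lab in chamber_labels) check_box_in_frame(boxes[[lab]], clip, lab)
  boxes
}

read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines) & grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
                  trimws(vapply(kv, `[[`, "", 1L)))
}

#' Extract the per-frame mean-intensity signal of an ROI
#'
#' The raw photoplethysmographic signal: for every frame, the arithmetic
#' mean of the grayscale pixels inside the box. Frame indices in the result
#' are 0-based, with frame `i` at time `i / fps` seconds.
#'
#' @param clip a [video_clip].
#' @param box a [bounding_box] inside the frame.
#' @param label `"atrium"` or `"ventricle"`.
#' @return An object of class `roi_signal` with fields `label`, `values`,
#'   `fps`, `frame_indices`.
#' @export
extract_signal <- function(clip, box, label = c("atrium", "ventricle")) {
  stopifnot(inherits(clip, "video_clip"))
  label <- match.arg(label)
  box <- check_box_in_frame(parse_box_entry(box), clip)
  rows <- (box$y + 1L):(box$y + box$h)
  cols <- (box$x + 1L):(box$x + box$w)
  sub <- clip$frames[rows, cols, , drop = FALSE]
  values <- colMeans(matrix(sub, nrow = box$w * box$h, ncol = clip$n_frames))
  roi_signal(label, values, clip$fps)
}

roi_signal <- function(label, values, fps, frame_indices = NULL) {
  if (is.null(frame_indices)) frame_indices <- seq_along(values) - 1L
  structure(list(label = label, values = as.numeric(values), fps = fps,
                 frame_indices = as.integer(frame_indices)),
            class = "roi_signal")
}

#' @export
print.roi_signal <- function(x, ...) {
  cat(sprintf("<roi_signal> %s: %d frames @ %g fps, mean %.2f (range %.1f-%.1f)\n",
              x$label, length(x$values), x$fps, mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Extract both chamber signals, optionally in parallel
#'
#' The two ROIs are independent, so they can be reduced concurrently
#' (forked workers); results are guaranteed identical to sequential
#' extraction because each worker runs the same deterministic reduction.
#'
#' @param clip a [video_clip].
#' @param rois named list from [select_rois()].
#' @param parallel logical; fork one worker per chamber (POSIX only; falls
#'   back to serial elsewhere).
#' @return Named list of `roi_signal`s.
#' @export
extract_signals <- function(clip, rois, parallel = FALSE) {
  labs <- chamber_labels
  extract_one <- function(lab) extract_signal(clip, rois[[lab]], lab)
  out <- if (parallel && .Platform$OS.type == "unix") {
    parallel::mclapply(labs, extract_one, mc.cores = 2L)
  } else {
    lapply(labs, extract_one)
  }
  stats::setNames(out, labs)
}

#' Standardize a signal to zero mean and unit variance
#'
#' @param signal an `roi_signal` or numeric vector.
#' @param convention `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return Same shape as the input with standardized values.
#' @export
normalize_signal <- function(signal, convention = c("sample", "population")) {
  convention <- match.arg(convention)
  v <- if (inherits(signal, "roi_signal")) signal$values else as.numeric(signal)
  if (length(v) < 2L)
    cw_abort("length", "need at least 2 samples to normalize")
  s <- stats::sd(v)
  if (convention == "population") s <- s * sqrt((length(v) - 1) / length(v))
  if (!is.finite(s) || s == 0)
    cw_abort("flat_signal",
             "no cardiac motion detected in ROI (constant intensity)")
  out <- (v - mean(v)) / s
  if (inherits(signal, "roi_signal")) {
    signal$values <- out
    signal
  } else out
}

#' Frame-count gate
#'
#' Clips shorter than 10 frames are rejected outright; clips longer than
#' 2000 frames are analyzed on their first 2000 frames only (with a
#' warning), which keeps long recordings usable while bounding the window
#' the detector sees.
#'
#' @param n_frames total decoded frames.
#' @return Integer vector `c(start = 0, end = )`, a half-open 0-based frame
#'   window.
#' @export
gate_frame_count <- function(n_frames) {
  if (n_frames < 10)
    cw_abort("too_few_frames",
             sprintf("clip has %d frames; at least 10 are required", n_frames))
  if (n_frames > 2000) {
    cw_warn("frame_gate",
            sprintf("clip has %d frames; analysis window clipped to the first 2000",
                    n_frames))
    return(c(start = 0L, end = 2000L))
  }
  c(start = 0L, end = as.integer(n_frames))
}
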