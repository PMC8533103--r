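#' Organism presets
#'
#' Default analysis band and physiological heart-rate ceiling per organism.
#' Zebrafish larvae beat at roughly 2-3 Hz; Daphnia hearts run an order of
#' magnitude faster, so they need a separate scale.
#'
#' @param preset `"zebrafish"`, `"daphnia"`, or `"custom"` (no defaults).
#' @return List with `band` (Hz, length 2) and `max_bpm`.
#' @export
organism_preset <- function(preset = c("zebrafish", "daphnia", "custom")) {
  switch(match.arg(preset),
         zebrafish = list(band = c(0.5, 5), max_bpm = 400),
         daphnia   = list(band = c(2, 15),  max_bpm = 900),
         custom    = list(band = NULL, max_bpm = NULL))
}

as_values <- function(signal) {
  if (inherits(signal, c("roi_signal", "processed_signal"))) signal$values
  else as.numeric(signal)
}

processed_signal <- function(values, fps, provenance) {
  stopifnot(!is.null(provenance))
  structure(list(values = as.numeric(values), fps = fps,
                 provenance = provenance),
            class = "processed_signal")
}

#' @export
print.processed_signal <- function(x, ...) {
  cat(sprintf("<processed_signal> %d samples @ %g fps; %s\n",
              length(x$values), x$fps,
              paste(names(x$provenance), vapply(x$provenance, function(p)
                paste(format(unlist(p)), collapse = "-"), ""),
                sep = "=", collapse = ", ")))
  invisible(x)
}

#' Default spline residual budget
#'
#' Robust estimate of the total squared noise in a series: the noise sd is
#' taken as `median(|successive differences|) / sqrt(2)` (successive
#' differences of white noise have sd `sqrt(2)` times the noise sd), and the
#' budget is `n` times its square, i.e. the residual sum of squares a spline
#' tracking the noiseless signal would leave behind.
#'
#' @param x numeric series.
#' @return Non-negative scalar budget.
#' @export
default_smoothing_factor <- function(x) {
  x <- as_values(x)
  length(x) * (stats::median(abs(diff(x))) / sqrt(2))^2
}

#' Smooth a series with a residual-budget cubic spline
#'
#' Fits a smoothing cubic spline to (frame index, value) pairs whose
#' roughness penalty is chosen so the residual sum of squares matches
#' `smoothing_factor` (a total squared-residual budget, as in classical
#' smoothing-spline parameterizations). `smoothing_factor = 0` returns the
#' input samples unchanged (the interpolating spline evaluated at its own
#' knots). The penalty is located by bisection on the spline's smoothing
#' parameter, under which the residual sum of squares is monotone.
#'
#' @param signal numeric series or `roi_signal` (length >= 4).
#' @param smoothing_factor non-negative residual budget; `NULL` uses
#'   [default_smoothing_factor()].
#' @param fps frames per second, for provenance (taken from the signal when
#'   it carries one).
#' @return A `processed_signal` the same length as the input.
#' @export
smooth_signal <- function(signal, smoothing_factor = NULL, fps = NULL) {
  v <- as_values(signal)
  if (is.null(fps) && is.list(signal)) fps <- signal$fps
  if (length(v) < 4L)
    cw_abort("length", "spline smoothing needs at least 4 samples")
  if (is.null(smoothing_factor)) smoothing_factor <- default_smoothing_factor(v)
  if (smoothing_factor < 0)
    cw_abort("domain", "`smoothing_factor` must be non-negative")
  idx <- seq_along(v)
  # infinite-penalty limit of the cubic smoothing spline: the least-squares
  # straight line (its residual is the largest any penalty can leave)
  lin <- stats::lm.fit(cbind(1, idx), v)$fitted.values
  rss_lin <- sum((lin - v)^2)
  if (smoothing_factor == 0 || stats::var(v) == 0) {
    out <- v
  } else if (rss_lin <= smoothing_factor) {
    out <- lin
  } else {
    rss_at <- function(spar) {
      fit <- stats::smooth.spline(idx, v, spar = spar, cv = NA,
                                  all.knots = TRUE)
      sum((stats::predict(fit, idx)$y - v)^2)
    }
    lo <- -1.5; hi <- 2
    if (rss_at(hi) <= smoothing_factor) {
      spar <- hi
    } else if (rss_at(lo) >= smoothing_factor) {
      spar <- lo
    } else {
      for (k in 1:40) {
        mid <- (lo + hi) / 2
        if (rss_at(mid) > smoothing_factor) hi <- mid else lo <- mid
        if (hi - lo < 1e-4) break
      }
      spar <- (lo + hi) / 2
    }
    fit <- stats::smooth.spline(idx, v, spar = spar, cv = NA,
                                all.knots = TRUE)
    out <- stats::predict(fit, idx)$y
  }
  processed_signal(out, fps,
                   provenance = list(smoothing_factor = smoothing_factor,
                                     filter_band_hz = NULL,
                                     normalized = FALSE))
}

#' Zero-phase Butterworth bandpass filter
#'
#' A 2nd-order Butterworth bandpass applied forward and backward
#' (`filtfilt`), so the phase response is exactly zero and beat times are
#' not shifted. The passband should bracket the physiological beat
#' frequency; DC (the baseline intensity) is removed.
#'
#' @param signal numeric series, `roi_signal`, or `processed_signal`.
#' @param fps sampling rate in frames per second.
#' @param low_hz,high_hz band edges, `0 < low_hz < high_hz < fps / 2`.
#' @return A `processed_signal` with near-zero mean.
#' @export
bandpass_filter <- function(signal, fps = NULL, low_hz, high_hz) {
  v <- as_values(signal)
  if (is.null(fps) && is.list(signal)) fps <- signal$fps
  if (is.null(fps)) cw_abort("fps", "`fps` is required for filtering")
  nyq <- fps / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    cw_abort("band",
             sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                     low_hz, high_hz, nyq))
  prov <- if (inherits(signal, "processed_signal")) signal$provenance
          else list(smoothing_factor = NULL, normalized = FALSE)
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- signal::filtfilt(bf, v - mean(v))
  prov$filter_band_hz <- c(low_hz, high_hz)
  processed_signal(out, fps, prov)
}

# all strict local maxima of v (plateau centers), no thresholding
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  candidates <- which(diff(sign(diff(v))) < 0) + 1L
  candidates[v[candidates] > v[pmax(1L, candidates - 1L)] |
               v[candidates] > v[pmin(n, candidates + 1L)]]
}

# topographic prominence of each peak index in v
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    left <- if (p > 1L) {
      higher <- which(v[seq_len(p - 1L)] > v[p])
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(v[lo:p])
    } else v[p]
    right <- if (p < length(v)) {
      seg <- v[(p + 1L):length(v)]
      higher <- which(seg > v[p])
      hi <- if (length(higher)) min(higher) - 1L else length(seg)
      min(seg[seq_len(hi)], v[p])
    } else v[p]
    v[p] - max(left, right)
  }, numeric(1))
}

# greedy minimum-spacing enforcement, highest peaks first
enforce_spacing <- function(peaks, heights, min_dist) {
  if (length(peaks) <= 1L || min_dist <= 1) return(sort(peaks))
  ord <- order(heights, decreasing = TRUE)
  keep <- logical(length(peaks))
  kept <- numeric(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - peaks[i]) >= min_dist)) {
      keep[i] <- TRUE
      kept <- c(kept, peaks[i])
    }
  }
  sort(peaks[keep])
}

#' Detect beat maxima and minima
#'
#' Local extrema filtered by topographic prominence (at least
#' `prominence_frac` times the signal's standard deviation, making
#' detection invariant to amplitude scaling) and by a refractory spacing of
#' `fps * 60 / max_bpm` frames (no physiological rhythm can beat faster
#' than `max_bpm`). Minima are detected as maxima of the negated signal.
#' A final cleanup enforces strict alternation: of two same-type neighbors
#' the lesser extremum is dropped.
#'
#' @param signal numeric series or `processed_signal` (length >= 3).
#' @param fps sampling rate.
#' @param max_bpm physiological ceiling; see [organism_preset()].
#' @param prominence_frac prominence threshold as a fraction of sd.
#' @return An object of class `peak_set`: `maxima`, `minima` (0-based frame
#'   indices, strictly increasing), their times in seconds, and `fps`.
#' @export
detect_peaks <- function(signal, fps = NULL, max_bpm = 400,
                         prominence_frac = 0.3) {
  v <- as_values(signal)
  if (is.null(fps) && is.list(signal)) fps <- signal$fps
  if (is.null(fps)) cw_abort("fps", "`fps` is required for peak spacing")
  if (length(v) < 3L)
    cw_abort("length", "peak detection needs at least 3 samples")
  s <- stats::sd(v)
  min_dist <- fps * 60 / max_bpm

  side <- function(u) {
    pk <- local_maxima(u)
    if (!length(pk) || s == 0) return(integer(0))
    pk <- pk[peak_prominence(u, pk) >= prominence_frac * s]
    enforce_spacing(pk, u[pk], min_dist)
  }
  maxima <- side(v)
  minima <- side(-v)

  # interleave: in any same-type run keep the most extreme event
  ev <- data.frame(i = c(maxima, minima),
                   type = c(rep(1, length(maxima)), rep(-1, length(minima))))
  ev <- ev[order(ev$i), , drop = FALSE]
  if (nrow(ev) > 1L) {
    keep <- rep(TRUE, nrow(ev))
    run_best <- 1L
    for (k in seq_len(nrow(ev))[-1]) {
      if (ev$type[k] == ev$type[run_best]) {
        better <- (ev$type[k] == 1 && v[ev$i[k]] > v[ev$i[run_best]]) ||
          (ev$type[k] == -1 && v[ev$i[k]] < v[ev$i[run_best]])
        if (better) {
          keep[run_best] <- FALSE; run_best <- k
        } else keep[k] <- FALSE
      } else run_best <- k
    }
    ev <- ev[keep, , drop = FALSE]
  }
  maxima <- ev$i[ev$type == 1]
  minima <- ev$i[ev$type == -1]

  structure(list(maxima = as.integer(maxima - 1L),
                 minima = as.integer(minima - 1L),
                 maxima_times = (maxima - 1) / fps,
                 minima_times = (minima - 1) / fps,
                 fps = fps),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d maxima, %d minima @ %g fps\n",
              length(x$maxima), length(x$minima), x$fps))
  invisible(x)
}

#' Dominant frequency by discrete Fourier transform
#'
#' Frequency of the largest spectral magnitude inside `band`, an
#' independent cross-check of the beat rate obtained from inter-beat
#' intervals. The spectral resolution `fps / length` is returned alongside:
#' the estimate cannot be more precise than one bin.
#'
#' @param signal numeric series or `processed_signal`.
#' @param fps sampling rate.
#' @param band numeric length-2 frequency window in Hz (within Nyquist).
#' @return List with `frequency_hz`, `resolution_hz`.
#' @export
dominant_frequency <- function(signal, fps = NULL, band = c(0.5, 5)) {
  v <- as_values(signal)
  if (is.null(fps) && is.list(signal)) fps <- signal$fps
  n <- length(v)
  nyq <- fps / 2
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= nyq))
    cw_abort("band",
             sprintf("band [%g, %g] Hz must lie within [0, Nyquist = %g]",
                     band[1], band[2], nyq))
  spec <- Mod(stats::fft(v - mean(v))[seq_len(n %/% 2 + 1L)])
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * fps / n
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(in_band))
    cw_abort("band", "no spectral bins inside the requested band")
  best <- in_band[which.max(spec[in_band])]
  list(frequency_hz = freqs[best], resolution_hz = fps / n)
}
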