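#' Beat series
#'
#' Beat times in seconds for one chamber, derived from detected extrema
#' (frame index times the frame duration, optionally rescaled through a
#' slow-motion factor). At least two beats are required for any interval
#' statistic.
#'
#' @param label `"atrium"` or `"ventricle"`.
#' @param beat_times strictly increasing times in seconds.
#' @return Object of class `beat_series`.
#' @export
beat_series <- function(label = c("atrium", "ventricle"), beat_times) {
  label <- match.arg(label)
  beat_times <- as.numeric(beat_times)
  if (is.unsorted(beat_times, strictly = TRUE))
    cw_abort("beats", "`beat_times` must be strictly increasing")
  structure(list(label = label, beat_times = beat_times),
            class = "beat_series")
}

#' Heart rate from beat minima
#'
#' `bpm = 60 / mean inter-beat interval`: the mean is taken over the
#' `length(minima) - 1` consecutive frame differences, each converted to
#' seconds through `frame_dur`. Invariant to shifting all indices by a
#' constant.
#'
#' @param minima_frames beat marker frame indices (the signal troughs, or
#'   crests for bright-pulse optics), at least 2, increasing.
#' @param frame_dur seconds per frame (see [frame_duration()]).
#' @return Beats per minute.
#' @examples
#' compute_bpm(c(0, 80, 160, 240), 0.005)  # 150
#' @export
compute_bpm <- function(minima_frames, frame_dur) {
  if (length(minima_frames) < 2L)
    cw_abort("insufficient_beats",
             sprintf("need at least 2 beat markers, got %d",
                     length(minima_frames)))
  60 / mean(diff(as.numeric(minima_frames)) * frame_dur)
}

#' Round half away from zero toward +Inf
#'
#' Nearest-integer rounding where exact .5 fractions go toward positive
#' infinity (so 117.5 -> 118 and -0.5 -> 0), unlike base R's banker's
#' rounding. Used for the reported integer bpm.
#'
#' @param x finite numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  if (any(!is.finite(x)))
    cw_abort("domain", "`x` must be finite")
  floor(x + 0.5)
}

interval_series <- function(kind, values) {
  kind <- match.arg(kind, c("AA", "VV", "AV", "VA"))
  values <- as.numeric(values)
  if (any(values <= 0))
    cw_abort("intervals", sprintf("%s intervals must all be positive", kind))
  structure(list(kind = kind, values = values), class = "interval_series")
}

#' Same-chamber beat intervals (A-A or V-V)
#'
#' Consecutive differences of the chamber's beat times; the interval kind
#' follows the chamber label.
#'
#' @param beats a [beat_series] with >= 2 beats.
#' @return An `interval_series` of kind `"AA"` or `"VV"` with
#'   `length(beats) - 1` values.
#' @export
chamber_intervals <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  if (length(beats$beat_times) < 2L)
    cw_abort("insufficient_beats",
             sprintf("%s has %d beat(s); need at least 2 for intervals",
                     beats$label, length(beats$beat_times)))
  interval_series(if (beats$label == "atrium") "AA" else "VV",
                  diff(beats$beat_times))
}

#' Cross-chamber intervals (A-V and V-A)
#'
#' For every atrium beat, the delay to the earliest ventricle beat strictly
#' after it (A-V), and symmetrically for V-A. Beats with no later
#' counterpart are dropped, so all values are positive; if the two series do
#' not interleave at all the result is empty, with a warning.
#'
#' @param atrium,ventricle [beat_series] objects.
#' @return List with `av` and `va` `interval_series`.
#' @export
cross_chamber_intervals <- function(atrium, ventricle) {
  stopifnot(inherits(atrium, "beat_series"), inherits(ventricle, "beat_series"))
  pair_next <- function(from, to) {
    vals <- vapply(from, function(t) {
      later <- to[to > t]
      if (length(later)) later[1] - t else NA_real_
    }, numeric(1))
    vals[!is.na(vals)]
  }
  av <- pair_next(atrium$beat_times, ventricle$beat_times)
  va <- pair_next(ventricle$beat_times, atrium$beat_times)
  if (!length(av) || !length(va))
    cw_warn("empty_pairing",
            "no overlapping atrium/ventricle beats; cross-chamber intervals empty")
  list(av = structure(list(kind = "AV", values = av), class = "interval_series"),
       va = structure(list(kind = "VA", values = va), class = "interval_series"))
}

#' Poincare short- and long-term variability
#'
#' On the scatter of each interval against the next, `sd1` is the spread
#' perpendicular to the identity line (short-term, beat-to-beat
#' variability) and `sd2` the spread along it (long-term variability):
#' `sd1 = sd((I[n+1] - I[n]) / sqrt(2))`, `sd2 = sd((I[n+1] + I[n]) /
#' sqrt(2))`, with the population (1/n) standard deviation. Both are zero
#' for a perfectly regular rhythm.
#'
#' @param intervals an `interval_series` with >= 3 values.
#' @return Object of class `poincare_stats` with `sd1`, `sd2` in seconds.
#' @export
poincare <- function(intervals) {
  v <- if (inherits(intervals, "interval_series")) intervals$values
       else as.numeric(intervals)
  if (length(v) < 3L)
    cw_abort("insufficient_beats",
             sprintf("Poincare statistics need >= 3 intervals, got %d",
                     length(v)))
  pop_sd <- function(z) sqrt(mean((z - mean(z))^2))
  i1 <- v[-length(v)]
  i2 <- v[-1]
  structure(list(sd1 = pop_sd((i2 - i1) / sqrt(2)),
                 sd2 = pop_sd((i2 + i1) / sqrt(2))),
            class = "poincare_stats")
}

#' Lagged normalized cross-correlation of two equal-length series
#'
#' For each integer delay `d` in `[-max_delay, max_delay]`,
#' `r(d) = sum((x[i] - mx) * (y[i + d] - my)) / sqrt(sum((x[i] - mx)^2) *
#' sum((y[i + d] - my)^2))`, where out-of-range `y` terms are treated as
#' zero after mean-centering (both sums in the numerator and the shifted
#' sum in the denominator run over the same index window), which keeps
#' every `r` in \[-1, 1\] by Cauchy-Schwarz. At the peak, `y` lags `x` by
#' `d` samples: a copy of `x` delayed by `k` frames peaks at `d = k`, and
#' the ventricle signal against the atrium signal peaks near the A-V delay.
#'
#' @param x,y equal-length non-constant numeric series.
#' @param max_delay largest |lag| in samples; default `length(x) - 1` (the
#'   full profile, `2N - 1` values).
#' @return Object of class `cross_corr`: `delays`, `r`, `peak_lag`,
#'   `peak_r`.
#' @export
cross_correlation <- function(x, y, max_delay = NULL) {
  x <- as_values(x); y <- as_values(y)
  if (length(x) != length(y))
    cw_abort("shape", sprintf("series lengths differ: %d vs %d",
                              length(x), length(y)))
  n <- length(x)
  if (n < 2L) cw_abort("length", "need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    cw_abort("zero_variance", "cross-correlation undefined for constant series")
  if (is.null(max_delay)) max_delay <- n - 1L
  max_delay <- min(as.integer(max_delay), n - 1L)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sum(xc^2)
  delays <- (-max_delay):max_delay
  r <- vapply(delays, function(d) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    ys <- numeric(n)
    ys[ok] <- yc[j[ok]]
    den <- sqrt(sx * sum(ys^2))
    if (den == 0) 0 else sum(xc * ys) / den
  }, numeric(1))
  peak <- which.max(r)
  ties <- which(r == r[peak])
  peak <- ties[which.min(abs(delays[ties]))]
  structure(list(delays = delays, r = r,
                 peak_lag = delays[peak], peak_r = r[peak]),
            class = "cross_corr")
}

#' Rescale intervals through a slow-motion factor
#'
#' Intervals measured against the playback clock of a slow-motion rendering
#' are multiplied by the [slowdown_factor()] to recover real time (use
#' `1 / factor` for the inverse direction).
#'
#' @param intervals an `interval_series`.
#' @param factor positive multiplier.
#' @return An `interval_series` of the same kind.
#' @export
rescale_intervals <- function(intervals, factor) {
  stopifnot(inherits(intervals, "interval_series"))
  if (!is.numeric(factor) || factor <= 0)
    cw_abort("domain", "`factor` must be positive")
  intervals$values <- intervals$values * factor
  intervals
}

interval_summary <- function(iv) {
  if (!length(iv$values)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
  c(mean = mean(iv$values),
    sd = if (length(iv$values) > 1) stats::sd(iv$values) else 0,
    n = length(iv$values))
}

#' Aggregate the full cardiac report
#'
#' Combines both chambers' beat series and conditioned signals into the
#' endpoint set: per-chamber bpm (exact and half-up-rounded), mean +/- sd of
#' the A-A, V-V, A-V, V-A interval series, Poincare sd1/sd2 per chamber,
#' the atrium-ventricle cross-correlation peak and its lag, and full
#' provenance of every conditioning choice.
#'
#' @param atrium,ventricle [beat_series] objects (>= 2 beats each; >= 4 for
#'   Poincare statistics).
#' @param signals optional named list of the two conditioned
#'   `processed_signal`s, used for the cross-correlation diagnostic.
#' @param fps frames per second of the analyzed clip.
#' @param frame_dur seconds per frame used for bpm.
#' @param provenance list recording ROIs, band, smoothing, compat flags.
#' @param max_lag_s largest cross-correlation lag to scan, in seconds.
#' @return Object of class `cardiac_report`.
#' @export
build_report <- function(atrium, ventricle, signals = NULL, fps,
                         frame_dur = 1 / fps, provenance = list(),
                         max_lag_s = 2) {
  for (b in list(atrium, ventricle)) {
    if (length(b$beat_times) < 2L)
      cw_abort("insufficient_beats",
               sprintf("chamber '%s' has %d beat(s); cannot compute rate",
                       b$label, length(b$beat_times)))
  }
  bpm <- c(atrium = 60 / mean(diff(atrium$beat_times)),
           ventricle = 60 / mean(diff(ventricle$beat_times)))
  aa <- chamber_intervals(atrium)
  vv <- chamber_intervals(ventricle)
  cross <- cross_chamber_intervals(atrium, ventricle)
  poin <- list(
    atrium = if (length(aa$values) >= 3) poincare(aa) else NULL,
    ventricle = if (length(vv$values) >= 3) poincare(vv) else NULL
  )
  xcorr <- NULL
  if (!is.null(signals)) {
    xcorr <- cross_correlation(signals$atrium, signals$ventricle,
                               max_delay = ceiling(max_lag_s * fps))
  }
  structure(list(
    bpm = bpm,
    bpm_rounded = round_half_up(bpm),
    intervals = list(AA = aa, VV = vv, AV = cross$av, VA = cross$va),
    poincare = poin,
    crosscorr = if (!is.null(xcorr))
      list(peak_r = xcorr$peak_r, peak_lag = xcorr$peak_lag,
           peak_lag_s = xcorr$peak_lag * frame_dur, profile = xcorr),
    fps = fps, frame_dur = frame_dur,
    provenance = provenance
  ), class = "cardiac_report")
}

#' @export
print.cardiac_report <- function(x, ...) {
  cat("<cardiac_report>\n")
  cat(sprintf("  heart rate: atrium %.1f bpm (%d), ventricle %.1f bpm (%d)\n",
              x$bpm["atrium"], as.integer(x$bpm_rounded["atrium"]),
              x$bpm["ventricle"], as.integer(x$bpm_rounded["ventricle"])))
  for (k in names(x$intervals)) {
    s <- interval_summary(x$intervals[[k]])
    cat(sprintf("  %s interval: %.4f +/- %.4f s (n = %d)\n",
                k, s["mean"], s["sd"], as.integer(s["n"])))
  }
  for (ch in names(x$poincare)) {
    p <- x$poincare[[ch]]
    if (!is.null(p))
      cat(sprintf("  %s Poincare: sd1 = %.4f s, sd2 = %.4f s\n",
                  ch, p$sd1, p$sd2))
  }
  if (!is.null(x$crosscorr))
    cat(sprintf("  atrium-ventricle crosscorr: peak r = %.3f at lag %d (%.3f s)\n",
                x$crosscorr$peak_r, x$crosscorr$peak_lag,
                x$crosscorr$peak_lag_s))
  invisible(x)
}

#' Serialize a cardiac report to a metric table
#'
#' One row per scalar metric (`metric`, `chamber`, `value`, `units`,
#' `value_rounded`), at full precision; [read_report()] restores the
#' numeric content.
#'
#' @param report a `cardiac_report`.
#' @param path optional CSV destination.
#' @return The data frame, invisibly when written to `path`.
#' @export
report_table <- function(report, path = NULL) {
  rows <- list()
  add <- function(metric, chamber, value, units, rounded = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, chamber = chamber, value = value, units = units,
      value_rounded = rounded, stringsAsFactors = FALSE)
  }
  for (ch in c("atrium", "ventricle"))
    add("bpm", ch, report$bpm[[ch]], "beats/min", report$bpm_rounded[[ch]])
  for (k in names(report$intervals)) {
    s <- interval_summary(report$intervals[[k]])
    ch <- switch(k, AA = "atrium", VV = "ventricle", "both")
    add(paste0("interval_", k, "_mean"), ch, s[["mean"]], "s")
    add(paste0("interval_", k, "_sd"), ch, s[["sd"]], "s")
  }
  for (ch in names(report$poincare)) {
    p <- report$poincare[[ch]]
    if (!is.null(p)) {
      add("poincare_sd1", ch, p$sd1, "s")
      add("poincare_sd2", ch, p$sd2, "s")
    }
  }
  if (!is.null(report$crosscorr)) {
    add("crosscorr_peak_r", "both", report$crosscorr$peak_r, "unitless")
    add("crosscorr_peak_lag", "both", report$crosscorr$peak_lag_s, "s")
  }
  add("fps", "both", report$fps, "frames/s")
  add("frame_duration", "both", report$frame_dur, "s")
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Read back a serialized report table
#'
#' @param path CSV written by [report_table()].
#' @return Data frame with the same columns and values.
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
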