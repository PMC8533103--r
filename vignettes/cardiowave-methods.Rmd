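---
title: "Video-based cardiac rhythm measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-based cardiac rhythm measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiowave)
```

## The measurement model

A beating chamber of a transparent animal modulates the light reaching the
camera: as the atrium or ventricle fills and contracts, the mean grey level
of a box of pixels over the chamber oscillates at the beat frequency. The
pipeline treats that mean-intensity series as a photoplethysmographic
signal. Each frame is a 2-D intensity raster `f(x, y)` in [0, 255]; colour
input is collapsed with BT.601 luminance weights (0.299 R + 0.587 G +
0.114 B), the convention of mainstream video decoders, because chamber
motion is a brightness phenomenon and separate colour channels carry no
extra rhythm information at these optics.

Timebase: frame `i` (0-based) occurs at `i / fps` seconds. The exact frame
duration `1/fps` drives all default computations. An opt-in
`paper_compat` mode truncates the duration to three decimals
(200 fps → 0.005 s, 60 fps → 0.016 s), reproducing the constants of the
classic manual workflow; truncation biases bpm by ≈ 0.4 % at 60 fps, which
is why it is not the default. Similarly, footage re-rendered for slow-motion
playback (200 fps shown at 30 fps) is conventionally rescaled through the
factor `trunc(200/30 × 10)/10 = 6.6`; `rescale_intervals()` applies it in
either direction.

## Signal conditioning

Each ROI series is processed as: standardize → smoothing spline → zero-phase
bandpass → extrema detection. The order puts the spline (which removes
pixel-noise roughness) before the filter (which removes baseline drift and
out-of-band energy); both are linear, so the order mainly affects edge
transients, and it is configurable.

**Standardization** uses the sample (n−1) standard deviation by default —
the safer convention for short series — with the population convention
available. A constant series means the box saw no cardiac motion and is a
hard error naming the chamber, not a silent zero.

**Smoothing spline.** The smoother is the classical cubic smoothing spline
with a knot at every sample, parameterized by a *residual budget*: the
roughness penalty is chosen (by bisection, under which the residual sum of
squares is monotone) so that the RSS equals the budget. Budget 0 returns
the samples unchanged; a budget beyond the residual of the least-squares
line returns that line, the infinite-penalty limit. The default budget is
`n · (median |Δx| / √2)²`, a robust estimate of the total squared pixel
noise: successive differences of white noise have √2 times the noise sd,
and the median makes the estimate insensitive to the (sparse) beat slopes.
No smoothing is ever allowed to change the number of beat extrema on clean
signals, which the tests enforce.

**Bandpass.** A 2nd-order Butterworth bandpass run forward and backward
(`filtfilt`), hence exactly zero phase: beat times are not displaced, at
the cost of edge transients of a few characteristic periods. In-band
attenuation at the zebrafish defaults (0.5–5 Hz at 200 fps) is ≈ 1 % for a
2.5 Hz tone; a 20 Hz tone is attenuated > 99 %. Organism presets:
zebrafish 0.5–5 Hz with a 400 bpm ceiling; daphnia 2–15 Hz with 900 bpm,
because the water-flea heart beats an order of magnitude faster and the
zebrafish scale simply does not cover it. Explicit `band`/`max_bpm` values
override a preset.

**Peak detection.** Local extrema are filtered by topographic prominence
(threshold `prominence_frac × sd`, default 0.3, which makes detection
invariant to amplitude rescaling) and by a refractory spacing of
`fps × 60 / max_bpm` frames. Minima are maxima of the negated signal. A
final pass enforces strict interleaving — between two consecutive maxima
there must be a minimum and vice versa — by dropping the lesser of two
same-type neighbours. Beats are anchored on signal troughs for optics in
which contraction darkens the chamber; since the optical sign varies with
illumination and mounting, the default anchor is `"auto"`: the sign of the
conditioned signal's skewness decides whether pulses point up (anchor on
crests) or down (anchor on troughs). Rate and same-chamber intervals are
insensitive to that choice; the A-V delay is not, which is why the anchor
is recorded in the report provenance.

## Endpoints

With beat times `t_k` (marker frame × frame duration):

- `bpm = 60 / mean(t_{k+1} − t_k)`, the mean over the `K − 1` consecutive
  differences of `K` markers. Reported both exactly and rounded half-up
  (ties toward +∞: 117.5 → 118, −0.5 → 0).
- A-A and V-V intervals are the consecutive differences per chamber. A-V
  pairs each atrium beat with the earliest strictly later ventricle beat
  (V-A symmetrically); beats without a later partner are dropped. This
  pairing is deterministic under jitter and matches the alternating
  atrium/ventricle activation sequence of a two-chambered heart.
- Poincaré `sd1`/`sd2` use the successive difference/sum formulation with
  the population sd. For i.i.d. Gaussian jitter of sd σ on beat *times*,
  interval differences have variance 6σ², so `sd1 = σ√3` in expectation —
  the closed form the recovery tests check against.
- The cross-correlation profile `r(d)` is computed for lags −D…D with both
  series mean-centred once and out-of-range terms zeroed, so |r| ≤ 1 by
  Cauchy–Schwarz and a copy of `x` delayed by `k` frames peaks exactly at
  `d = k`. It is a *diagnostic* of chamber coupling (peak lag ≈ A-V delay);
  it does not feed the bpm computation. The default lag window in reports
  is ±2 s, wide enough for any physiological A-V delay while keeping the
  global peak at the true delay rather than at a period-shifted alias
  (zero-padding shrinks `r` as overlap shrinks, so nearer lags win ties).

**Frame gate.** Clips under 10 frames are rejected; clips over 2000 frames
are analyzed on their first 2000 frames with a warning. The gate keeps the
detector's window bounded while leaving long recordings usable; it is the
package's reading of the frame-count exclusion rule of the manual
workflow, whose phrasing is ambiguous between frames and peak counts.

## The synthetic generator

`synth_spec()` renders what the camera would see, not heart anatomy: two
spatially separated ellipses whose interior intensity follows
`baseline + amplitude × raised-cosine` pulses centred at the beat times,
on a uniform background, with additive Gaussian pixel noise clipped to
[0, 255]. Choices that matter:

- **Raised-cosine pulses** (compact support) rather than a sinusoid, so
  each beat has a well-defined ground-truth *time* for marker-alignment
  tests.
- **Jitter on beat times, not intervals** (`t_k = k·period + ε_k`,
  `ε_k ~ N(0, σ²)` i.i.d.), giving the closed-form `sd1 = σ√3` used as an
  oracle.
- **Ventricle = atrium + delay**, a fixed activation offset.
- Defaults are the reference acquisition condition: 200 fps, 10 s, 150 bpm,
  0.1 s A-V delay, pulse width 0.15 s, baseline 120, amplitude 60, pixel
  noise sd 5, 120×80 px frames. Identical spec + seed give bitwise
  identical frames.

What it does *not* emulate — and what passing tests therefore do not
certify about real videos: moving/deforming chamber boundaries, blood-cell
texture, illumination drift, body motion (real larvae are immobilized in
methylcellulose), compression artefacts, and ROI misplacement. The
generator validates the measurement chain, not the optics.

Problem sizes used by the test and acceptance runs were chosen to exercise
the stated conditions at desk scale: the 200 fps/10 s/150 bpm reference
clip (2000 frames); a 300 fps, 600 bpm clip for the ultrafast regime; and
a 30 fps × 45 s clip (1350 frames, ~112 beats) for regularity recovery, a
frame rate at which ~112 beats fit inside the 2000-frame gate.

## Video I/O

Uncompressed 8-bit grayscale AVI (RIFF `DIB` frames) is read and written
natively — the interchange format microscopy tool chains have used for
years — and the writer/reader round trip is bit-exact, which the tests
verify. Compressed containers (mp4) require an external decoder that the
package deliberately does not bundle; `load_video()` raises a structured
error telling the user to transcode. `resample()` implements nearest-frame
downsampling (e.g. 200 → 30 fps) and refuses to upsample.

## Numerical and degenerate-input policy

- Frame indices are 0-based half-open everywhere public; R's 1-based
  indexing is internal only.
- Truncations (not roundings) reproduce the compatibility constants 0.016
  and 6.6; rounding would give 0.017 and 6.7.
- Cross-correlation ties are broken toward the smallest |lag|.
- Flat signals: error in normalization, empty peak set in detection,
  zero-variance error in cross-correlation — each stage states its own
  failure rather than propagating NaNs.
- Fewer than 2 beat markers in a chamber is an error naming the chamber;
  Poincaré statistics additionally need ≥ 3 intervals.
- Spline bisection runs ≤ 40 iterations to a spar interval of 1e-4, ample
  since RSS varies smoothly in spar.

## Known limitations

Static rectangular ROIs only (no tracking or automatic chamber
segmentation); no frequency-domain HRV or arrhythmia classification; no
variable-frame-rate containers; mp4 requires external transcoding. The
A-V delay from interval pairing assumes each atrium beat is followed by
one ventricle beat — 2:1 conduction block would need manual inspection of
the interval CSVs.
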