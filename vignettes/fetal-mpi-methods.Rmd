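---
title: "Methods: automated fetal LV cardiac time intervals and MPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated fetal LV cardiac time intervals and MPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalMPI)
```

## The measurement model

A merged inflow/outflow pulsed-Doppler recording of the fetal left ventricle
shows, per cardiac cycle and in this order: the filling phase FT (positive
inflow lobe containing the E and the dominant A wave), the isovolumetric
contraction gap IVCT, the ejection phase ET (negative outflow lobe), and the
isovolumetric relaxation gap IVRT. The two myocardial performance indices
are per-cycle ratios of these durations:

$$\mathrm{TI} = \frac{\mathrm{IVCT} + \mathrm{IVRT}}{\mathrm{ET}}, \qquad
  \mathrm{KI} = \frac{\mathrm{IVCT} + \mathrm{IVRT}}{\mathrm{FT}}.$$

Both are dimensionless and, for fixed interval *fractions* of the cycle,
independent of heart rate — the property the recovery tests exploit.

The pipeline (`analyze_envelope()`, or `run_pipeline()` from a file) is:
envelope → zero-phase low-pass → AMPD A-wave detection → landmark search →
intervals → indices. Each stage is described below with its assumptions and
tunable parameters.

## Envelope extraction

A trace image is binarized (Otsu's threshold by default; any fixed threshold
may be supplied), the drawn zero-velocity baseline is found as the row with
the longest horizontal foreground run (ties go to the upper row; a run
shorter than half the width flags low confidence), and each pixel column is
reduced to the extreme foreground pixel: topmost above the baseline
(positive velocity) or bottommost below it (negative), whichever excursion
is larger, ties to the positive side. Baseline pixels themselves are not
signal. This per-column rule is equivalent to contour tracing for
single-blob traces and much simpler; it assumes the display renders a filled
column from the baseline to the envelope, the common spectral-display mode.
Calibration (ms per column, cm/s per row) must be supplied; it is never
inferred from the image.

All indices in the package are 1-based, following R convention; landmark
*times* are reported in milliseconds and are unaffected by the convention.

## Zero-phase Butterworth filtering

The analog Butterworth low-pass magnitude is
$|H(\omega)| = (1 + (\omega/\omega_0)^{2n})^{-1/2}$, with squared gain
exactly 1/2 at the cut-off (−3 dB). The digital filter is designed by
bilinear transform at the signal's sampling rate (`signal::butter`) and
applied forward and backward (`signal::filtfilt`) so that the effective
amplitude response is $|H(f)|^2$ and the phase response is zero — a causal
single pass would delay every landmark and bias every interval. Edge
transients are controlled by odd-reflection padding, and the mean is removed
before filtering and restored afterwards, so constant signals pass through
exactly.

**Default: cut-off 50 Hz, order 4, at dt = 1 ms.** The envelope's lobe
content at fetal heart rates sits below roughly 15 Hz, so any cut-off in the
tens of hertz preserves morphology while removing pixel jitter. The choice
of 50 Hz rather than a more aggressive 25 Hz is deliberate: interval
boundaries live in the low-amplitude flanks of the lobes, and on the
package's own fixtures a 25 Hz zero-phase filter smears lobe corners enough
to displace boundary estimates by several samples (biasing TI beyond the
0.02 recovery band the package tests), while 50 Hz keeps the displacement
within about one sample and still stabilises peak detection under noise.

## AMPD peak detection

The local-maxima scalogram has entries $m_{k,i} = 0$ when sample $i$
strictly exceeds both neighbours at clearance $k$ ($x_i > x_{i-k}$ and
$x_i > x_{i+k}$, both in range), and an arbitrary value $r + 1$, $r \sim
U(0,1)$, otherwise, for $k = 1..L$ with $L = \lceil N/2 \rceil - 1$.
Boundary columns whose $k$-distant neighbour falls outside the signal are
never maxima at that scale; plateau samples are excluded by the strict
inequality. The row sums $\gamma_k$ are minimal at the scale $\lambda$ where
local maxima are most abundant, and peaks are the columns of the
$\lambda$-truncated matrix whose standard deviation $\sigma_i$ is exactly
zero — equivalently, the all-zero columns.

Two numerical choices matter:

- **λ is taken from the zero-pattern, not the random fill.** The argmin of
  the literal random row sums is a random variable whenever two scales'
  local-maxima counts nearly tie, which would make the peak set depend on
  the fill seed. The package uses the argmin of the per-row non-zero count
  (identical to the argmin of the row sums for any constant fill), ties to
  the smallest scale (favouring sharper peaks). Detection is then a pure
  function of the signal: amplitude-scale invariant and seed invariant.
- **σ = 0 is tested combinatorially** (all entries zero), never with a
  float tolerance.

`detect_peaks()` implements exactly this, streaming over scales in linear
memory. `compute_lms()` / `ampd_summary()` expose the full matrix, γ, λ and
σ for inspection.

**Edge handling (`detect_a_waves()`).** Under the boundary convention, a
sample closer than λ to either end of the signal can never be scored as a
peak, so a trace that starts at a cycle boundary loses its first A wave
(λ is roughly half a cycle). Because a Doppler envelope is anchored at the
zero-velocity baseline, the envelope-aware wrapper pads the signal with
baseline zeros on both sides (half the signal length per side) before
computing the scalogram and maps the indices back — padding a
baseline-anchored signal with baseline creates no spurious maxima at
relevant scales. Two guards make this robust:

- **Scale cap (`max_scale_ms = 350`).** Scales beyond half the longest
  plausible fetal cycle (600 ms at 100 bpm) carry no information about peak
  spacing; at very large clearances any sample on the upper half of a lobe
  trivially dominates far-away samples (or the padding), and this secondary
  γ minimum can capture λ and collapse detection onto the single tallest
  peak. The cap excludes those scales. Signals from outside the fetal
  heart-rate range (marked bradycardia) would need a larger cap.
- **Relative amplitude screen (`min_rel_height = 0.25`).** Successive A
  waves of one trace have similar amplitude; a detected "peak" below a
  quarter of the median peak height is a noise bump or filter-ringing
  ripple on an otherwise flat stretch (which can dominate its surroundings
  at every scale) and is discarded. The threshold is relative, preserving
  scale invariance.

`detect_peaks()` itself remains the faithful scalogram criterion for
signals that are not baseline-anchored envelopes.

## Landmark search

Anchored at each A peak (interior cycles only — IVRT needs the previous
cycle's ejection end, so the first and last cycles are discarded):

- **E peak**: the tallest positive strict local maximum within
  `window_frac` (default 0.45) of the median A-peak spacing to the left of
  A, subject to a valley check — the minimum between the candidate and the
  A peak must fall below half the candidate's height. The check rejects
  noise wiggles riding on the A lobe itself, which can exceed the true E
  peak in amplitude.
- **Lobe edges** (FT start/end, ET start/end, previous ET end): walking
  outward from inside the lobe, the flank is located where the rectified
  signal falls to 15% of the lobe peak; the local slope is fitted by least
  squares over nearby flank samples and extrapolated to the zero crossing.
  On a clean half-sine flank the extrapolation is exact to well under a
  sample; after low-pass filtering the 15% crossing sits outside the
  smeared corner region, so the estimate stays unbiased — a plain
  baseline-tolerance crossing would be biased inward on wide lobes and
  outward on filtered ones. A 5% baseline tolerance
  (`baseline_tol_frac`) is retained for scanning into the negative lobes
  and for click detection.
- **Valve clicks**, when present as narrow spikes at lobe boundaries, snap
  the boundary to the click sample (a spike above four times the baseline
  tolerance just inside the estimated boundary).

A cycle whose seven landmarks violate the ordering
prev ET end < FT start < E < A < FT end < ET start < ET end is dropped with
a warning rather than failing the waveform; `compute_intervals()`
additionally rejects non-positive intervals ("degenerate cycle"). Interval
times are kept in ms at full precision; rounding happens only in printing.

## Synthetic study conditions

`generate_envelope()` emulates the waveform class the pipeline targets: per
cycle a half-sine E lobe then a half-sine A lobe (splitting the FT window
evenly, E/A amplitude ratio < 1), a baseline IVCT gap, a negative half-sine
ejection lobe, and a baseline IVRT gap; optional single-sample positive
valve clicks at the four lobe boundaries; white Gaussian noise added last.
Half-sines (rather than, say, Gaussians) make every lobe boundary an exact
zero crossing, so ground-truth landmark times are exact by construction.
Defaults — 140 bpm, fractions IVCT 0.08 / ET 0.35 / IVRT 0.10 / FT 0.47,
E/A 0.7, A wave 45 cm/s, ejection 60 cm/s, dt 1 ms — are physiologically
plausible mid-gestation values. The recovery battery perturbs heart rate
over 110–160 bpm and the fractions by ±20%, clean and at 5%-of-A-wave
noise.

What the generator does **not** model: spectral broadening and speckle of a
real spectrogram, baseline drift, E/A lobe fusion at high heart rates,
dropout, and clicks below the baseline (clicks are rendered as positive
spikes only). Passing the recovery tests therefore demonstrates correctness
of the measurement chain on well-formed envelopes, not robustness to every
clinical artefact.

## Reliability statistics

`icc_2_1()` is the Shrout–Fleiss two-way random-effects,
absolute-agreement, single-measure intraclass correlation, computed from
the two-way ANOVA mean squares, with the standard F-based confidence
interval (Satterthwaite degrees of freedom). At perfect agreement the
error and session mean squares vanish and the F interval is indeterminate;
the package reports the collapsed interval [1, 1]. The tests cross-check
the implementation against mean squares from `stats::aov` and against an
independent statistics library.

## Known limitations

- Merged or heavily fused E/A lobes (very high heart rates) are out of
  scope; the valley check will drop such cycles rather than mis-measure.
- The AMPD scale cap assumes fetal heart rates (≥ ~100 bpm).
- Image calibration must be supplied; there is no axis-tick OCR or DICOM
  support.
- The envelope extractor assumes a single filled trace per column; it does
  not despeckle.
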