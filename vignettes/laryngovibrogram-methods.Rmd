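---
title: "Laryngovibrogram construction and vibratory measures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laryngovibrogram construction and vibratory measures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laryngovibro)
```

## Input model

The package operates on segmented high-speed videoendoscopy: a stack of
per-frame label masks with values 0 (background), 1 (glottis), 2 (right
vocal fold), 3 (left vocal fold), plus a frame rate. Masks are stored as a
multipage 8-bit TIFF with a JSON sidecar (`fps`, `dorsal_at_top`);
orientation is normalized so that the dorsal side is at row 1. Segmentation
itself (typically a neural network) is out of scope — the pipeline starts
at label masks.

## Landmarks and vibrational axes

Per frame, the posterior point of each fold is its most dorsal pixel
8-adjacent to the opposite fold or to the glottis; the anterior commissure
`A` is the most ventral fold–fold contact pixel (ties averaged columnwise,
with a fallback to glottis adjacency when the folds never touch). A single
compiled pass over the stack collects these landmarks together with the
glottal area waveform (GAW, glottis pixel count per frame) and per-frame
bounding boxes; `detect_endpoints()` is the plain-R reference implementation
that the compiled path is tested against.

Raw landmarks jump with segmentation noise, so they are stabilized by
sliding-window coordinate-wise medians (window 150 frames, overlap 25 at
4000 fps, i.e. ~37 ms windows), assigned to window centers and linearly
interpolated — and linearly *extrapolated* beyond the first and last center,
since clamping would flatten slow drifts (such as pre-phonatory adduction)
at the sequence ends. Within any window where the GAW reaches zero, complete
closure is assumed and both posterior points are replaced by the midpoint of
their medians; consequently a sustained, fully closing phonation has a
single posterior point and an opening angle of exactly zero.

The vibrational axis of each fold runs from its posterior point to `A` and
has length `L_{r,l}(t)`. All deflections are measured against this axis and
normalized by its length, which makes the representation dimensionless and
invariant under uniform scaling and rigid rotation — camera zoom and
endoscope roll do not change the LVG.

## LVG assembly

Fold contours are traced per frame (marching squares at level 0.5 on the
label indicator, cropped to the mask bounding box). The medial edge is the
contour arc between the vertices nearest to `P` and `A` that runs closer to
the glottal midline. For each edge point the distance to the axis is the
closed-form point-to-segment distance (the minimum over the continuous axis
parameter `κ ∈ [0, 1]`, not a discretized search); its sign is the side of
the axis the point falls on (positive lateral). The signed distances,
divided by the axis length, are resampled by cumulative arc length to
`n = 256` equidistant positions from posterior to anterior. Left fold rows
1–256 and right fold rows 257–512, one column per frame, form the LVG matrix.

`lvg_geometry()` exposes the intermediate per-frame edge/landmark geometry,
so that coordinate transformations can be applied analytically and the
invariance verified without re-rasterizing masks (rasterization at a
different scale changes pixel quantization, which is a property of the
imaging, not of the representation).

## Measures

A trajectory is one LVG row — the deflection at a fixed relative position
`p` over time, evaluated by default at the medial `p = 0.5`. Cycles are
delimited at trajectory minima: candidate minima come from a lightly
smoothed copy (moving average of about a quarter period) with a prominence
threshold of 10 % of the peak-to-peak range, and each boundary is then
refined on the **raw** series by a least-squares **cubic** over a fixed
window of `max(3, fps / (8 f0))` samples on each side of the raw argmin,
taking the fit's local minimum nearest the window center. Fitting the raw
series matters: refining on the smoothed series systematically shrinks
period differences, because smoothing mixes adjacent cycles exactly where
the period changes. The cubic term matters too: the flanks left and right
of a minimum have unequal curvature whenever the adjacent cycles differ,
which adds an odd `t·|t|`-like component to the local shape; a
quadratic-only fit aliases that component onto its linear term and pulls
the vertex toward the shallower flank, again shrinking period differences,
while the cubic basis absorbs most of it. The window must stay local (a
wider window reintroduces cycle mixing) but wide enough to see both rising
flanks around closure; since deflections are quantized at one pixel per
axis length (`1/L` per sample), the closure region is flat over roughly
`(T/2π)·sqrt(2/(L·a))` frames for cycle amplitude `a`, which bounds the
resolvable period perturbation at low amplitude and low frequency (for
`L = 160` px the estimator is validated for amplitudes ≥ 0.045 and F0 ≥ 135
Hz at 4000 fps; outside that region jitter estimates degrade gracefully but
are not covered by the acceptance tests).

Per complete cycle `j` (partial leading/trailing cycles are discarded), the
amplitude `A_j` is the raw peak-to-peak deflection between consecutive
boundaries and the period `T_j` the boundary spacing. The measures are:

- RND: `100 · A_j` (% of axis length), per cycle and averaged;
- shimmer: `100 · mean|ΔA_j| / mean(A_j)`;
- jitter: `100 · mean|ΔT_j| / mean(T_j)`; because every boundary of a
  single-position segmentation rests on one quantized trajectory,
  `consensus_cycles()` additionally averages the refined boundaries of the
  trajectories at `p ∈ {0.3, …, 0.7}` on both folds (matched to a reference
  segmentation of the summed unsigned medial deflection, with per-trajectory
  constant offsets removed so lateral phase shifts do not bias the average);
  period-based measures are substantially more accurate on the consensus
  boundaries;
- Q_RND: cycles are segmented *jointly* on the summed unsigned deflection of
  both folds so that the quotient `min/max` compares the same oscillation
  cycle on both sides, then averaged (cycles where both sides are zero are
  skipped and counted);
- ΔΘ̄: instantaneous phases from a complex Morlet wavelet
  (`ω₀ = 6`) evaluated at the scale matching the estimated F0, applied to
  the mean-removed trajectory in the Fourier domain; a Hilbert-transform
  backend is provided as a cross-check. The per-position phase differences
  are averaged on the unit circle (circular mean), and the profile is
  aggregated both over the glottal opening range (positions whose maximal
  inter-fold gap exceeds 1 % of axis length) and over the whole LVG.

F0 is estimated from the zero-padded periodogram of the mean-removed
series inside 50–500 Hz, requiring the peak to exceed ten times the median
in-band power, with log-parabolic interpolation of the peak bin.

Aggregation order is cycles-first: all perturbation measures are computed
from per-cycle quantities of one recording, then averaged; nothing is
averaged across positions before cycle segmentation.

## Voice onset

The oscillation start is detected on the band-passed (50–500 Hz, 2nd-order
Butterworth, zero-phase) GAW via the magnitude of its analytic signal: the
first run of 20 frames above 10 % of the sustained-phase median envelope,
required to be preceded by a 20-frame quiet run (which also rejects the
zero-phase filter's edge transient). The opening angle `Γ(t)` between the
two axes, hinged at `A`, is regressed by ordinary least squares over the
1000 frames (250 ms at 4000 fps) before the oscillation start; its slope γ
(degrees/s, negative = adduction) quantifies pre-phonatory adduction.
Onset cycles are GAW cycles from the oscillation start until the first
cycle whose minimum reaches full closure (configurable tolerance for leaky
closure); sequences that never close are flagged open-ended. Because the
envelope threshold reacts to the growing oscillation slightly before the
nominal start, the detected start can precede the true one by a few tens of
frames; the regression window is shortened (with a warning) when it would
run out of frames.

## Synthetic generator

`generate_sequence()` rasterizes parametric kinematics on a 256 × 256
canvas at 4000 fps: straight axes at columns symmetric about the exact
half-integer midline (which makes healthy sequences *exactly* mirror
symmetric after rasterization), axis rows 48–208 (length 160 px), fold
width 48 px. Medial edges are the axis plus a half-sine spatial mode
`sin(πp)` with per-cycle amplitudes `a_j` and fractional periods `T_j`
drawn per cycle (uniform relative perturbations `amp_jitter`,
`period_jitter`), per-side amplitude scaling, lateral phase offset, bowing,
a shared lateral overshoot, an optional polyp (Gaussian dorsal shoulder
with a ventral plateau high enough to block ventral opening), and an
optional onset phase (pre-phonatory wedge with linearly shrinking opening
angle at slope `rate`, then oscillation with a residual gap decaying over
the configured number of open cycles). The manifest records the exact
fractional cycle boundaries, periods, and per-side amplitudes of all
complete cycles plus every imposed scalar, so pipeline estimates can be
compared to analytic ground truth. Scope: the generator produces idealized
kinematics (no segmentation noise beyond optional Gaussian edge
perturbation, no mucosal wave, no anterior–posterior phase propagation);
it validates the measurement chain, not segmentation robustness.

Infeasible specifications (folds leaving the canvas, F0 at or above
Nyquist) are rejected at `synth_spec()` time.

## Numerical choices and limitations

- All geometry is computed in continuous (row, column) coordinates; pixel
  quantization enters only through mask rasterization.
- Deflection resampling uses linear interpolation over cumulative arc
  length; with 256 positions per fold the resampling error is well below
  the 10⁻³ invariance tolerance used in the tests.
- Exact identities (shimmer 0, jitter 0, Q_RND 1, ΔΘ̄ 0) hold bitwise for
  strictly periodic inputs because identical cycles produce identical
  refined boundaries; they are tested as exact, not approximate.
- The PVG baseline splits the glottis contour at the glottal symmetry axis
  (most dorsal/most ventral contour vertices, median-smoothed) and is only
  defined while the glottis is visible; closed frames give zero columns.
- Measures assume a dominant oscillation in 50–500 Hz at frame rates high
  enough to sample each cycle with ≥ 8 frames; aperiodic phonation
  (segmentation returns `J = 0`) yields `NA` measures rather than errors.
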