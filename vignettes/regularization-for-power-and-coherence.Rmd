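---
title: "How much regularization for MNE power versus coherence mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How much regularization for MNE power versus coherence mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mnecoh)
```

This vignette is the package's account of its model, its synthetic-data
generator, and the design decisions behind both.  It states no numbers that
`analysis/03_run_study.R`, the test suite or `scripts/acceptance.R` do not
themselves compute.

## The estimation problem

MEG sensor data follow the linear forward model `M = L S + N`.  With many
more source vertices than channels the lead field `L` is not invertible,
and the minimum-norm estimate regularizes the inversion:

$$\hat S = \arg\min_S \|Q^{-1/2}(M - LS)\|^2 + \gamma\,\|R^{-1/2}S\|^2$$

whose solution is applied through the operator
$W = R L^\top (L R L^\top + \gamma Q)^{-1}$.  We use the classical MNE:
`R = I` (IID sources), `Q` estimated from the very noise realization added
to each simulation, and a scalar weight $\gamma$ (the composite Tikhonov
coefficient multiplying `Q`; it plays the role usually written $\lambda^2$).
`make_inverse_operator()` computes `W` by a symmetric solve, never an
explicit inverse, and rejects $\gamma = 0$ on rank-deficient systems.  One
operator is built per simulation cell and grid weight and applied to the
whole series at once.

Two detection tasks are scored from $\hat S$, both on the 9–14 Hz alpha
band with the same Welch parameters:

* **power mapping** — per-vertex band-averaged Welch autospectrum; ground
  truth is the union of both simulated patches;
* **coherence mapping** — band-averaged magnitude-squared coherence of
  every vertex against the reconstructed series at the first patch's
  growth centre; ground truth is the *second* patch only, and the whole
  reference patch is excluded from scoring (its own vertices would be
  trivially coherent with the seed).

Maps are scored with the exact-threshold ROC: the threshold sweeps every
distinct evaluable map value, true/false positive fractions follow the
usual definitions restricted to evaluable vertices, and the AUC is the
trapezoidal area — equal to the normalized Mann–Whitney statistic, which
the tests verify against brute-force pair counting and `pROC`.  The "best"
weight for an analysis is the grid weight with the highest mean AUC;
exact ties break toward the larger weight and are flagged, as is an
argmax on a grid endpoint.

## Geometry: why the source surface is folded

The forward model is the closed-form single-sphere (Sarvas) solution with
the orientation constraint (one dipole per vertex, oriented along the
outward surface normal).  A mathematically important property of that
model is that radial dipoles are externally silent.  On a *perfect*
sphere concentric with the conductor every constrained dipole is radial,
so the entire lead field would vanish — a degenerate geometry that no
real cortex exhibits, because cortex is folded.  The package therefore
keeps `build_sphere_source_space()` (a textbook icosphere, used by the
geometry tests) but runs the study on `build_cortical_source_space()`: an
icosphere whose radius is modulated by a fixed smooth angular pattern
(default amplitude 0.12 of the radius, angular order 6, three skewed-axis
sinusoids; no randomness), with vertex normals recomputed from the mesh.
This gives dipoles tangential components almost everywhere (median normal
tilt about 12°, `analysis/01_geometry_forward.R` reports the exact
distribution), emulating folding at the desk scale without a real
segmented surface.  Near the isolated extrema of the folding pattern a
few vertices remain nearly silent; since a silent vertex is an artifact
of the synthetic surface rather than a feature of cortical sampling,
location pairs are drawn only from vertices whose lead-field column norm
reaches 20% of the median (`min_gain_fraction`), which excludes ~3% of
vertices.

Default dimensions follow adult-head proportions: sources on a nominal
8 cm shell, conductor radius 9 cm, 100 radial magnetometers
quasi-uniformly (Fibonacci lattice) on the upper half of a 12 cm shell.
Axial gradiometers with a 5 cm baseline are available
(`sensor_type = "axial_gradiometer"`); detection metrics, not absolute
field values, are the object of study, so the simpler magnetometer is the
default.  Patches grow from a seed vertex by breadth-first rings over
mesh edges (ties within a ring broken by Euclidean distance to the seed),
one vertex at a time until the accumulated barycentric vertex area
(one-third of incident triangle areas) reaches the target — so the patch
is a minimal covering set and growth is monotone in the target area.
Patch areas 0 (point-like), 2, 4 and 8 cm² are supported; on the
642-vertex surface a vertex owns ~1.2 cm², so the desk-scale study uses
{0, 2, 4} cm² to keep patch and point sources clearly distinct.

## The synthetic generator

Each source pair carries frequency-jittered alpha oscillators, 7000
samples at 600 Hz (the explicit sample count; the nominal duration is
~11.7 s): instantaneous frequency is 12 Hz plus Gaussian noise smoothed
by a 50-sample moving average and rescaled to a prescribed standard
deviation (`jitter_scale`), and the series is `cos` of the integrated
phase, normalized to zero mean and unit RMS.  Coherence below 1 arises
from the independent phase wander of the two oscillators.

The coupling loop fixes the first series and redraws the second until the
band-averaged Welch magnitude-squared coherence — measured with the *same*
Welch parameters as the analysis, so generator and analysis agree by
construction — lands within ±0.02 of the target.  Two design points
matter here:

* **The first series' jitter bounds what is reachable.**  The pair's
  coherence is capped by the first oscillator's own phase wander; with a
  0.5 Hz jitter that cap sits near 0.1–0.25 for typical realizations and
  the 0.4 target is unreachable.  The default `jitter_scale` is therefore
  0.1 Hz, under which single draws span roughly 0.04–0.5 and all three
  study targets (0.1, 0.2, 0.4) are reachable.  At 0.1 Hz essentially all
  oscillator power lies inside 9–14 Hz (the spectral-concentration test
  checks ≥95% even at 0.5 Hz).
* **The second series' jitter is steered, not annealed blindly.**  A fixed
  shrink-on-failure schedule either overshoots the narrow ±0.02 window or
  stalls below it.  The loop instead updates the second series' jitter
  scale multiplicatively, `scale * exp(1.5 * (achieved - target))`,
  bounded to [0.01, 3] Hz: draws then centre themselves on the target and
  all targets converge in tens of iterations (the calibration script
  reports the iteration counts).  `max_iterations = 2000` is a safety
  net; exhaustion raises an error carrying the best achieved value.

Patch activity places the identical series on every member vertex with
unit dipole moment.  Sensor noise is i.i.d. Gaussian, rescaled so that
`20*log10(||M_clean||_F / ||N||_F)` equals the requested SNR *exactly*;
the 20-log convention is used because the SNR is defined on amplitude
(Frobenius-norm) ratios.  The noise covariance `Q` is the empirical
channel covariance of the realized noise (7000 samples for 100 channels),
ridge-stabilized by `1e-12 * tr(Q)/n` before solving.

What the generator does *not* emulate: colored or brain-like background
activity (the noise is white), additional non-interacting sources,
epoched/trial structure, realistic cortical geometry and CTF coil
layouts, and inter-subject variability.  Passing tests therefore show
that the inverse/spectral/scoring pipeline behaves as designed under
these idealized conditions, not that the specific optimal weights carry
over numerically to any real recording.

## The regularization grid and its scale

The study grid is 7 decade-spaced nominal weights, `1e-11 … 1e-5`.
Absolute Tikhonov weights are only meaningful relative to the units of
the lead field, the source amplitudes and the noise; published absolute
values depend on toolbox-internal scalings that are not part of the
model.  The package therefore separates the *nominal* grid from the
*effective* weight by a single constant, `lambda_scale` (default `1e8`):
the solved system is `L Lᵀ + nominal * lambda_scale * Q`.  The constant
was fixed once by range inspection on a pilot subset — sweeping effective
weights over many decades and placing the grid so that both detection
optima and the L-curve corner are interior grid points — which is also
how the original range was chosen.  Every scale-free conclusion (the
decade *gap* between optima, the position of the L-curve corner relative
to them, all AUC comparisons) is independent of this constant.

The L-curve (`lcurve_select()`) records, per weight, the whitened
residual norm `||Q^{-1/2}(M - L Ŝ)||_F` and the solution norm `||Ŝ||_F`,
computed from the data's channel second-moment matrix so the cost does
not grow with series length.  The corner is the interior grid point of
maximum three-point circumscribed-circle curvature of the log–log
polyline; collinear curves raise a corner-undefined error suggesting a
wider grid, and grids of fewer than 3 points are rejected.

## Spectral estimation choices

Welch defaults: 600-sample (1 s) Hann segments, 50% overlap — 22 segments
of a 7000-sample series, 1 Hz resolution — with one-sided density
scaling.  Band statistics average the bins whose centres lie in
[9, 14] Hz (arithmetic mean, not peak: a mean is a stabler detection
statistic across 6 bins than a maximum).  Coherence uses
segment-averaged cross- and autospectra; per-bin values are clipped to
[0, 1] against float round-off.  Inside `run_study()` the maps are
computed in the frequency domain: the sensor segment FFTs are formed once
per cell and multiplied by each inverse operator (FFT and `W` are both
linear, so this equals mapping `apply_inverse()` output — a test asserts
the equality), which avoids materializing 642 × 7000 source series for
every cell × weight.

## Statistics

Comparisons between regularization choices are paired two-tailed t-tests
across configurations (each configuration contributes an AUC under both
weights, so pairing is the natural design; zero-variance differences are
a degenerate-test error).  No multiple-testing correction is applied.
Aggregation reports mean AUC per weight, overall and broken down by SNR,
patch area and coupling, each with its own argmax weight.

## Determinism and problem sizes

Every random draw derives from `master_seed` by counter-based mixing
(`derive_seed()`), so any cell is reproducible in isolation and the whole
study is bit-reproducible (a test runs a small study twice and compares
tables byte for byte).  The shipped configuration — 600 cells × 7 weights
× 2 analyses on a 642-vertex source space with 100 channels — runs in
about two minutes on one core; the test suite, including one full study,
in under three.  The full-scale design (600 pairs × 4 areas × 3
couplings × 3 SNRs = 21,600 cells on a 15k-vertex surface) is expressible
through `study_config()` but is enumerated rather than executed in the
tests.

## Known limitations

* The folded-sphere surface emulates orientation diversity but not the
  depth profile, sulcal opposition, or area distribution of real cortex;
  normal tilts max out near 25°, well short of sulcal walls.
* White sensor noise makes `Q` nearly diagonal; correlated brain noise
  would interact with the whitening and could shift optima.
* The coherence seed is the reconstructed series at the true reference
  vertex; in real data the seed location itself is uncertain.
* Only magnitude-squared coherence is scored; phase-based or
  leakage-insensitive coupling metrics would respond differently to
  regularization-induced smoothing.
* The nominal-to-effective weight mapping is a package constant; absolute
  nominal weights should not be transferred to other forward models.
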