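---
title: "Rank vector entropy and scalar beamformer mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank vector entropy and scalar beamformer mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rventropy)
```

## The measure and its assumptions

Rank vector entropy treats a sampled signal as a symbol stream. A window
of `W` samples, spaced `xi = ceiling(fs / (2 * fc))` apart, is reduced to
the permutation describing the relative order of its values ("rank
vector"), one of `factorial(W)` ordinal states. Because only the ordering
is kept, the measure is exactly invariant to positive-affine amplitude
transforms — no embedding-space partitions, no amplitude compression, no
assumption about the signal's dynamic range. The implicit assumptions are
(i) the signal is uniformly sampled and band-limited at `fc`, so the lag
rule captures its information content without oversampling, and (ii)
values are continuous, so exact ties are rare (ties are resolved
deterministically, see below).

Symbol occurrences accumulate in a leaky-integrator histogram: at every
sample all counts are multiplied by `alpha = exp(-1 / (tau * fs))`, then
the observed symbol's count is incremented by one. The normalized Shannon
entropy of the histogram, `h = -sum(p * log2(p)) / log2(factorial(W))`,
is emitted per sample, giving a time-resolved entropy bounded in [0, 1].
With `tau = Inf` (`alpha = 1`) the result is the cumulative entropy of
the whole series.

## Tunable parameters

* `W` (window length, unitless; default 5). The state count is `W!`:
  `W = 3` gives only 6 states (coarse), `W = 7` gives 5040 (requires very
  long records to populate). `W = 5` (120 states) is the practical
  compromise and the only value we validate extensively.
* `fc` (lowpass corner, Hz; default Nyquist). Sets the lag
  `xi = ceiling(fs / (2 * fc))`, tying the ordinal-pattern span to the
  signal bandwidth rather than leaving the lag as a free tuning knob.
  Narrowing `fc` lowers complexity by construction, so `fc` should match
  the acquisition bandwidth of interest (100–150 Hz for 600 Hz MEG).
* `tau` (integrator decay, s; default `3 * factorial(W) / fs`, i.e. a 1/e
  time of three times the state count in samples — 0.6 s at `W = 5`,
  600 Hz). `tau` trades temporal locality against histogram population.
  Provided `tau` comfortably exceeds the state-filling time, it rescales
  the *amplitude* of entropy fluctuations (shorter `tau`, larger
  fluctuations) without changing their waveform; the test suite checks
  correlation > 0.95 between `tau` and `2 * tau` series for a slow
  complexity modulation. For fast modulations (periods within an order of
  magnitude of `tau`) the integrator lag does shift the waveform — the
  invariance claim applies to fluctuations slow relative to `tau`.

## Numerical and convention choices

* **Rank direction.** Rank 1 is the *largest* value (fixed by the worked
  example (4.07, −3.12, 3.95, 8.51, −1.21) → (2, 5, 3, 1, 4)). Not
  configurable: either direction yields identical entropy, but symbol
  streams must be reproducible.
* **Ties.** Stable descending order: the earlier sample gets the smaller
  rank. A constant (fully tied) window therefore maps to the identity
  permutation and produces a valid low-entropy stream, not an error.
* **Symbol indexing.** 1-based position in the ascending lexicographic
  order of permutations, computed via the Lehmer code in O(W²) per
  window and verified against explicit enumeration in the tests.
* **Window step.** One raw sample per emitted value, even though samples
  within a window are `xi` apart; consecutive windows overlap and the
  entropy series retains the input sample rate.
* **Alignment.** `h(k)` is timestamped at the trailing (most recent)
  sample of its window — a causal convention; no claim is made about the
  latency of entropy features at finer than window-span resolution.
* **Initialization and lead-in.** Counts start at 1.0, so probabilities
  are strictly positive and the entropy starts at its maximum. The first
  `3 * tau` seconds are flagged (`lead_in_mask`) but returned: dropping is
  left to the analyst.
* **Positive-probability guard.** With unit initialization the `p > 0`
  guard in the entropy sum is vacuous until counts decay below machine
  precision (~255 000 silent samples at 600 Hz, `tau = 0.6`); the guard is
  implemented for that regime.

## Scalar beamformer

Source series are estimated per voxel by the scalar minimum-variance
beamformer `w = C^-1 B / (B' C^-1 B)` (unit gain `w'B = 1`), with the
forward solution from a current dipole in a homogeneously conducting
sphere (closed form; radial dipoles are silent, so the lead field has
rank 2). The dipole orientation is chosen to maximize the output SNR
`(u' L'C^-1 L u) / (u' L'C^-2 L u)` on the tangential subspace — the
generalized eigenvector of the pair `(L'C^-1 L, L'C^-2 L)` with the
largest ratio. Conventions differ in the literature on whether this is
phrased as a maximum or minimum eigenvalue of the transposed pair; we
fixed the convention by brute-force 1-D search over tangential
orientations maximizing the scalar SNR `(w'Cw) / (sigma2 w'w)`, which the
eigen route matches to < 0.1 degree in the tests. Further choices:

* **Diagonal loading** (default fraction 5e-3 of the mean diagonal in
  `lcmv_beamform()`, 0 in `compute_covariance()`): the orientation
  eigensystem involves `C^-2`, so a well-conditioned covariance matters
  more than usual.
* **Mean removal** before the covariance (per channel), matching standard
  practice.
* **Sign conventions.** The orientation's largest-magnitude component is
  made positive; entropy and power are sign-invariant, reproducibility is
  not.
* **Degenerate (white) covariance**: every tangential orientation has the
  same SNR; the leading right-singular vector of `L` is returned so the
  result is deterministic.
* **Sphere center voxel** has a zero lead field; it is skipped (zero
  weights, zero power) rather than raised as an error, since regular
  grids legitimately contain it.
* **Localization** uses the noise-normalized power map (pseudo-Z,
  `power / noise` in the fit). Raw minimum-variance power `w'Cw` is
  depth-biased — weights grow wherever lead-field gain is small, so the
  raw map peaks at poorly seen deep voxels — whereas the noise estimate
  `sigma2 * w'w` grows identically, and their ratio images the source.
  Both maps are retained in the fit and written by the CLI.
* The orientation pencil is solved by Cholesky whitening of `L'C^-2 L`
  followed by a symmetric eigendecomposition. Forming the matrix quotient
  directly and taking a non-symmetric eigendecomposition is unstable
  precisely in the regime that matters (a dominant source makes the two
  matrices nearly proportional), and can return an orientation far from
  the SNR optimum.

The head model is the homogeneous sphere only — the main fidelity gap
relative to realistic single-shell or BEM models; sensors are point
magnetometers (no gradiometer geometry or synthetic gradiometry).

## Band-power comparison

`hilbert_envelope_power()` provides the conventional comparison signal:
zero-phase 4th-order Butterworth bandpass, squared magnitude of the
analytic signal (computed via the standard FFT construction), then a
zero-phase lowpass at the band's upper corner. The smoothing corner is
exposed (`smooth_fc`) because "smoothed envelope" conventions vary; the
band's upper corner is the default. The first and last `3 / low` seconds
are flagged as edge-affected.

## Event-locked statistics

Epochs are cut at the nearest sample to each marker; incomplete epochs
are dropped and counted. Averages are computed on the entropy series
(never the entropy of an averaged signal — averaging first would destroy
the single-trial ordinal structure the measure quantifies). The
per-latency baseline statistic is a one-sample t across trials after
subtracting each trial's own baseline mean (per-trial rather than grand
baseline: it removes slow inter-trial entropy drift and matches the
"relative to a selected baseline" analysis). Two-condition
segment contrasts integrate the series over ±0.25 s segments
(trapezoidal rule) and use Welch's t-test, robust to unequal variance;
p-values are univariate, with no multiplicity correction by default.
Task-free analysis uses deviation from the statistical mode, estimated as
the midpoint of the maximal 0.005-wide histogram bin over [0, 1] (ties to
the lower bin) — the mode, unlike the mean, is insensitive to the
asymmetric transient dips that are the signal of interest.

## What the synthetic generator emulates — and what it does not

`simulate_meg()` builds sessions from scripted dipole sources
(oscillation / broadband noise / 1-f noise / silence / Gaussian-windowed
sinusoid transients) forward-projected through the sphere model onto a
quasi-uniform radial helmet (Fibonacci lattice, 275 sensors at 0.12 m by
default) with iid Gaussian sensor noise. The evoked protocol
(`evoked_protocol()`) mimics a desk-scale oddball session: 40 trials at
1.0–1.5 s inter-stimulus intervals, an 8 Hz transient of SD 0.08 s and
40 nA·m peak over a 10 nA·m RMS broadband background, 2e-14 T sensor
noise — amplitudes in the range of strong evoked cortical responses, and
a max-channel amplitude SNR near 11.

Passing tests on these data show the algorithm chain is correct and
self-consistent; they do not show field performance on real MEG, which
adds correlated environmental noise, non-spherical head geometry,
extended and correlated sources, head movement, and amplitude
distributions far from Gaussian. In particular, localization validation
places the source on the 5 mm grid lattice; at high SNR the
minimum-variance filter suppresses off-lattice sources at mismatched
voxels (signal cancellation), which blurs peak localization on coarse
grids — a known beamformer property, mitigated by loading and finer
grids.

Problem sizes used in validation — 60 s sessions at 600 Hz, 275 sensors,
one ~17 000-voxel 5 mm grid fit, and twenty 50 s evoked sessions analyzed
at two voxels each — were chosen to exercise the full pipeline at
realistic dimensionality.

## Known limitations

* The sub-window span acts as a highpass on entropy sensitivity:
  wavelengths longer than `(W - 1) * xi / fs` seconds contribute less to
  the entropy. No compensation is applied; choose `fc` (hence `xi`)
  accordingly.
* Entropy values within the lead-in reflect the initialization, not the
  signal.
* The emitted series is oversampled by construction (one value per raw
  sample); neighboring values share `W - 1` of `W` window samples and a
  near-identical histogram. Statistics across latencies should not treat
  them as independent.
* Time-series files are delimited text with a JSON sidecar carrying the
  sample rate (never guessed); volumetric output is NIfTI-1 with the grid
  affine in mm.
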