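---
title: "Early-stage EEG preprocessing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-stage EEG preprocessing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`eegpipe` implements the early, "non-committal" stage of EEG
preprocessing: remove power-line interference without committing the
output to any high-pass filter, detect channels whose signal is not
EEG (bad contacts, railed amplifiers, swapped or dead electrodes),
re-reference robustly to an estimate of the true average reference,
and interpolate the bad channels — while keeping a complete record of
what was done so downstream users can undo or re-do any of it.  It
deliberately does **not** touch subject-generated artifacts (blinks,
muscle) or bad epochs: those are downstream concerns that depend on
the analysis.

## Line-noise removal by multitaper harmonic regression

Mains interference is modeled as a deterministic sinusoid of unknown,
slowly varying amplitude and phase, embedded in locally white
background noise.  In each 4-s window (slide 1 s) the signal is
projected onto K = 7 Slepian tapers (time-bandwidth product
TBW·W/2 = 4, i.e. a 2 Hz taper bandwidth) and the complex amplitude
of a sinusoid at frequency f is estimated by frequency-domain
regression on the taper eigencoefficients.  The Thomson F statistic —
the ratio of the explained (coherent) power to the residual background
power — has an F(2, 2K−2) null distribution; a window is treated as
contaminated when p < 0.01.  Because the true line frequency drifts,
each candidate (60 Hz and harmonics below Nyquist by default) is
scanned over ±2 Hz on the FFT grid of the 4×-zero-padded window
(resolution fs/4N) and the frequency maximizing F is used.
Significant fits are reconstructed in the time domain, stitched across
overlapping windows with complementary sigmoid weights
w(t) = 1/(1+exp(−t'/tau)) (t' the offset from the overlap midpoint,
tau = 100 samples), subtracted, and the process repeats (max 10
iterations).

Two numerical choices deserve emphasis:

* **Scan multiplicity.**  The scan maximizes F over ~16 effectively
  independent (Rayleigh-spaced) frequencies, so an uncorrected
  "p < 0.01 at the maximum" rule fires in roughly 15% of line-free
  windows — removal would then perturb clean data and the iteration
  would never converge.  The significance decision therefore applies
  a Sidak correction for the effective number of independent scan
  frequencies (`scan_correction = TRUE`).  The fixed-frequency F-test
  itself is uncorrected and its type-I error is verified by
  simulation to match the nominal 0.01.
* **Stopping.**  A candidate frequency is retired once it is
  insignificant in ≥ 99% of windows, or once an iteration fails to
  reduce the number of significant windows (background has been
  reached; further iterations would only chase sampling noise).

### Order of operations: drift

Multitaper estimation assumes local stationarity.  Raw EEG drifts by
thousands of microvolts, and under a strong trend the F-test cannot
separate the line from the smeared low-frequency background — the
peak simply survives.  The pipeline therefore estimates noise on a
temporary 1 Hz high-passed copy and subtracts the *captured noise*
from the original, unfiltered signal.  The emitted data retains its
drift; a later high-pass of the output is numerically
indistinguishable (relative RMS < 1e-3) from filtering first and
removing line noise second.  All arithmetic is double precision
throughout; single-precision input is up-cast with a warning, because
round-off destroys exactly this commutativity.

## Noisy-channel detection

All criteria operate on a temporary 1 Hz high-passed copy and use the
robust z-score (median and 0.7413·IQR in place of mean and SD;
quantiles are linear-interpolation type 7 — fixed because different
quantile conventions move the 0.7413·IQR and the 98th percentile).

* **Unusable:** any non-finite sample (`bad-by-NaN`); overall robust
  SD of zero or more than 1% of 1-s windows exactly constant
  (`bad-by-NoData`).  Unusable channels are excluded from all further
  statistics and interpolated throughout.
* **Deviation:** robust z of the per-channel robust SD, |z| > 5.
  Windowed amplitude z-scores (against the overall median/robust SD)
  are retained for reporting.
* **Correlation / dropout:** on the 50 Hz low-passed copy, the
  per-window "maximum absolute correlation" is the 98th percentile of
  |Pearson r| with all other channels in 1-s windows; a channel is
  bad when it falls below 0.4 in strictly more than 1% of windows.
  Constant or numerically tiny windows raise dropout flags
  (`bad-by-dropout` above 1%).  Correlations involving a constant
  window are defined as 0 to keep NaNs out of the percentiles.
* **Noisiness:** MAD of the >50 Hz residual over MAD of the 50 Hz
  low-passed component, robust z across channels > 5.
* **Low SNR:** channels failing both correlation and noisiness are
  promoted to unusable: after referencing such channels would mostly
  contain the (subtracted) mean and could evade re-detection.
* **RANSAC predictability:** each remaining channel is predicted from
  50 random subsets of 25% of the good channels via spherical-spline
  interpolation; the per-sample median across subsets is the
  prediction, and a channel is bad when Pearson r(prediction, actual)
  < 0.75 in more than 40% of 5-s windows.  The window length default
  is 5 s (4 s is also defensible; the parameter is exposed).
  Subsets are drawn uniformly without replacement, seeded from the
  pipeline seed, making the whole result reproducible.

Comparisons are strict (">" not ">=") at every threshold.

## Spherical-spline interpolation

The interpolation kernel is the surface-spline series
g(x) = (1/4π) Σₙ (2n+1)/(nᵐ(n+1)ᵐ) Pₙ(x) with stiffness m = 4 and
Legendre truncation at degree 7.  The spline system is solved with a
constant term and a small diagonal loading of 1e-6 relative to the
kernel diagonal — enough to stabilize near-coincident electrodes
while reproducing the field at source electrodes to well under 0.1%
(the system's condition number on a 32-channel cap is ~1e7, so larger
absolute loadings visibly bias the estimates).  Constant fields are
reproduced exactly via the constant term.  Electrode positions are
projected onto the unit sphere **without** re-centering at the
electrode centroid: coordinates are head-centered by convention, and
the centroid of a hemispheric cap lies far above the head center —
centering would warp angular distances (the vertex-to-C3 distance
would appear as ~71° instead of 36°) and corrupt the kernel.

## Two-phase robust referencing

Phase 1 estimates the true mean the signal would have if no channels
were bad: starting from the per-sample channel median, detect bad
channels on the referenced copy, accumulate them, re-estimate the
reference as the mean of the signal with all accumulated bad channels
interpolated, and repeat until the set stabilizes (cap: 4 iterations;
one pass suffices for most data — iteration exists because extreme
channels can skew even the initial robust statistics).  Phase 2
"forgets" the accumulated list, re-detects relative to the phase-1
reference, interpolates (unusable channels from phase 1 are always
interpolated), subtracts the residual channel mean and folds it back
into the stored reference signal, so the final output has numerically
zero channel mean at every sample.  With no detectable bad channels
the procedure reduces exactly to ordinary average referencing.
Channels still flagged after interpolation are reported as
`still_bad`, never silently dropped.  The full reference signal is
stored so users can re-reference any other way.

The recording's mean is re-interpolated from the line-noise-cleaned
signal (not the raw one): the pipeline order implies detection and
referencing always see line-cleaned data.

## Reporting

The windowed arrays behind every criterion (amplitude z, max
correlation, noisiness z, RANSAC correlation, dropout flags) are
retained at three stages — original, after referencing before
interpolation, final — and all summary measures are pure functions of
these arrays: the mean (and the mean of per-channel medians) of the
max window correlation, the overall median of the robust window
deviations D, the robust deviation ratio robust_sd(D)/median(D), the
interpolated fraction, and the correlation between ordinary and
robust reference.  Three issue heuristics flag datasets needing human
eyes: referencing failed to move the per-channel-median max
correlation closer to [0.80, 0.91] (distance-to-interval rule; the
phrase "mean of the median max channel correlation" is read as
per-channel median over windows, then mean over channels — the grand
mean is also stored); the post-referencing mean max correlation
exceeds 0.91 with median above 0.95 (residual common-mode noise); or
more than 25% of reference channels were interpolated.

The result container is hierarchical JSON (one group per stage,
arrays as named datasets); numeric arrays are serialized as `%.17g`
strings and round-trip bit-exactly.  An HDF5 container would be the
natural alternative; JSON was chosen because it needs no compiled
dependency and the layouts are isomorphic.

## The synthetic world: what it emulates, and what it does not

The generator produces the base sessions of the detection benchmark:
32 channels (a Quik-Cap-style 10-10 layout including FCz/CPz), 5
minutes at 200 Hz.  Its components:

* **Sources.** 100 dipolar sources on the upper hemisphere with
  random orientations and broad distance-decay kernels (Gaussian in
  chord distance, width 1.2).  Dipolarity matters: all-positive
  mixing kernels produce a dominant common mode, and subtracting the
  channel mean then leaves noise-floor-dominated residuals on
  whichever channels happen to sit near the grand average — real
  scalp fields are signed.  Many sources matter too: with few
  sources, per-window correlations fluctuate wildly because 1-s
  windows of 1/f processes have few effective degrees of freedom.
  Source spectra are ~1/f above 1 Hz and roll off quickly above
  40 Hz, leaving the >50 Hz band to the amplifier floor, as in real
  recordings.
* **Reference-centering.** Source topographies are centered across
  the montage (scalp potential is defined only up to a reference);
  the clean truth therefore lives in average-reference space and no
  channel is structurally cancelled by referencing.
* **Gains and floor.** Mixing rows are unit-norm (scaling a weight
  vector changes no correlation) with an explicit log-normal channel
  gain (σ = 0.05) and an amplifier noise floor of 2 µV (σ = 0.03
  across channels), i.e. a well-maintained research cap.  The tight
  spreads are deliberate: the robust-z criteria compare each channel
  with the cross-channel distribution, and for log-normal spreads the
  tail z-score *grows* with the spread, so a sloppier cap would
  produce occasional spurious z > 5 events on clean data.
* **Drift and line.** Per-channel linear drift with slopes uniform in
  [−1, 8] µV/sample (the scale real unfiltered recordings show) and
  a 60 Hz line (5 µV, per-channel log-normal gain σ = 0.1) with slow
  shared amplitude (±30%, 0.05 Hz) and phase (±0.8 rad, 0.03 Hz)
  wander.

Injections implement the four bad-channel types: Gaussian noise at
8× the channel SD; attenuation to one tenth *with the amplifier floor
left intact* (a pure rescale is invisible to every correlation- or
ratio-based criterion — the physics of a weak connection is that the
scalp signal attenuates and the amplifier noise does not); a full
temporal shuffle; and pairs replaced by amplitude-normalized copies
of the highest-robust-SD channel of a different session.

What a green benchmark does **not** establish: the generator contains
no blinks, muscle bursts, electrode pops, non-stationary transformer
noise or inter-channel impedance coupling, and its spatial covariance
is a smooth stationary stand-in, not an estimate of any real
headset's covariance.  Detection rates on this world are therefore
evidence that the battery implements its definitions correctly and
meets the published rates *on the published benchmark design*, not a
performance claim for arbitrary real recordings.

## Tunable parameters (defaults)

| parameter | default | meaning |
|---|---|---|
| line frequencies | 60 Hz + harmonics < Nyquist | candidate mains lines |
| W / slide / TBW | 4 s / 1 s / 2 Hz | multitaper windowing |
| p threshold | 0.01 | F-test significance |
| scan half-width | 2 Hz | line-frequency search range |
| tau | 100 samples | stitching sigmoid constant |
| detection high-pass | 1 Hz | temporary trend removal |
| deviation / noisiness z | 5 | robust z cutoffs |
| correlation threshold / fraction | 0.4 / 1% | low-correlation rule |
| LF/HF split | 50 Hz | noisiness bands |
| RANSAC subset / draws / r / fraction / window | 25% / 50 / 0.75 / 40% / 5 s | predictability rule |
| spline m / degree / loading | 4 / 7 / 1e-6 (relative) | interpolation kernel |
| phase-1 cap | 4 | robust-reference iterations |
| abort fraction | 75% | bad-channel abort threshold |

## Known limitations

* Recordings shorter than ~30 s leave too few windows for the
  fraction-based criteria to be meaningful; the RANSAC fraction in
  particular quantizes coarsely.
* The RANSAC predictor assumes a reasonable scalp coverage; detection
  on low-density or forehead-only headsets should be interpreted with
  caution, and fewer than ~12 usable channels makes the subset
  machinery degenerate (it then skips, with a flag).
* The line-noise stage models the interference as locally sinusoidal;
  broadband transformer-type artifacts are out of its reach by design
  and are left to the bad-channel machinery.
* Bad epochs and subject artifacts are out of scope; the windowed
  statistics stored in the container are intended to help downstream
  epoch screening.
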