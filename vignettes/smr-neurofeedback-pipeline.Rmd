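---
title: "Models and methods of the SMR neurofeedback pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the SMR neurofeedback pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrpipe)
```

`smrpipe` implements, as verifiable code, the computation chain of a
closed-loop sensorimotor-rhythm (SMR) neurofeedback study: the online
feedback loop that turns mu/alpha-band desynchronization into a virtual
finger posture, the offline spectral and time–frequency quantification,
somatosensory evoked potential (SEP) component measurement, the behavioral
speed–accuracy trade-off, and the inferential statistics tying them
together. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical decisions taken where the design was open.

## The feedback signal model

The online chain reduces multichannel EEG to a scalar every 100 ms:

1. **Spatial filter.** A large Laplacian centered on C3 — the center
   electrode minus the mean of its next-nearest neighbors (F3, P3, T7, Cz
   by default). This is a spatial high-pass: it suppresses broad common
   activity and sharpens the focal sensorimotor rhythm. The neighbor set is
   configurable; the default is the standard choice for the extended 10-20
   layout.
2. **Temporal filters.** The latest 5-s buffer is filtered forward and
   backward (zero phase) with a third-order Butterworth band-pass (3–70 Hz)
   and band-stop notch (50 ± 2 Hz). The full buffer is re-filtered at every
   tick with no state carry-over; this reproduces the online behavior
   exactly, at a per-tick recomputation cost that is irrelevant offline.
3. **Spectral estimate.** The final 1 s of the filtered buffer is Hanning
   windowed and Fourier transformed. A 1-s window gives integer-frequency
   bins, so the alpha band is exactly bins 8–13.
4. **Normalization.** `ERSP(f,t) = 100 (P(f,t) − Ref(f)) / Ref(f)`, with
   `Ref` the mean power over the current trial's rest-period samples
   (within-trial normalization; the reference resets every trial). A rest
   tick is one whose full 1-s window lies inside the rest period, so no
   task activity leaks into the reference. During replay the reference
   accumulates causally: a tick only ever uses samples up to its own time,
   so truncating a recording never changes earlier trace values.
5. **Reduction, smoothing, mapping.** The scalar SMR is either the
   alpha-band mean ERSP (pre-calibration) or the ERSP at the calibrated
   frequency of interest (FOI) — the default once calibrated, since the
   feedback used the FOI bin. It is smoothed over the most recent
   `min(10, available)` raw values and mapped to a frame index 1–20:
   SMR ≤ 25th percentile → frame 20 (fully abducted finger),
   SMR ≥ 75th percentile → frame 1, affine in between, rounded half-up and
   clipped. The two percentile anchors define the paradigm; the affine
   interpolation and the half-up rounding between them are this package's
   documented choices (both configurable). FOI calibration takes
   the argmin over alpha bins of the trial- and task-period-averaged ERSP;
   ties break to the lowest frequency, and a flat (all non-negative)
   profile returns the argmin with a warning.

## The synthetic EEG generator

The generator builds the signal the analyses assume: an aperiodic
1/f background plus a narrow-band alpha oscillator whose power drops by a
factor `1 − erd_depth` during the task period.

* **Background.** Per channel, independent Gaussian noise spectrally shaped
  to a one-sided PSD of `10^offset / f^exponent` µV²/Hz, plus white
  amplifier noise of 0.2 µV RMS (typical input-referred noise of research
  EEG amplifiers; a larger value would put an un-physical white floor above
  the 1/f background at high frequencies).
* **Oscillator.** An amplitude-modulated sinusoid at the individual alpha
  frequency (default 10 Hz, 5 µV on C3, neighbor gain 0.3). Its frequency
  is modulated by a slow mean-reverting (AR(1), time constant 0.5 s)
  deviation giving the spectral line a near-Gaussian width of 0.5 Hz FWHM,
  and its phase runs continuously across trials: real alpha has a finite
  coherence time, and this matters computationally — a line with zero width
  is a spectral spike whose window-leakage skirts are not Gaussian (they
  corrupt spectral parameterization), while per-trial phase resets would
  splatter broadband power into the background. Setting
  `alpha_linewidth = 0` restores an analytically exact pure tone (with
  independent phase per trial) for closed-form checks. A Lorentzian
  phase-diffusion line was considered and rejected: its power-law tails are
  far heavier than real alpha lines and blanket steep aperiodic spectra.
* **ERD.** During the task the oscillator amplitude is scaled by
  `sqrt(1 − erd_depth)`, entered through a 200-ms linear onset ramp (an
  instantaneous step would be both unphysical and spectrally disruptive).
  Ready and blank periods carry rest-like statistics.
* **Trial structure.** 5 s rest, 1 s ready, 6 s task, 5 s blank — 17 s per
  trial, 20 trials per block by default; the event table marks each period
  onset.

What the generator does *not* emulate: eye and muscle artifacts, channel
cross-correlation of the background beyond the shared oscillator,
electrode drift, or any head-model forward projection. Passing recovery
tests therefore demonstrates that the *pipeline arithmetic* is correct at
realistic SNR, not that the pipeline is artifact-robust.

Cortical source estimation is out of scope by design: the analyses operate
on the Laplacian channel trace, and every offline entry point also accepts
a plain numeric series, so externally computed source time series (e.g.
M1/S1 traces from an inverse solution) can be supplied directly.

## Offline spectra and their parameterization

Offline time–frequency maps use the same filters and 1-s Hanning spectra as
the online path at 0.1-s resolution, with one deviation: the continuous
trace is filtered once (zero phase) rather than per tick, which is
equivalent away from buffer edges and orders of magnitude faster.
Per-trial rest baselining makes the mean map exactly zero over the baseline
window by construction. Two estimator properties are worth knowing:
percent change with a reference estimated from the handful of effectively
independent rest windows in a 5-s period is slightly positively biased
(Jensen), visibly so at background-dominated bins of null sessions; and at
bins adjacent to the alpha line, window leakage carries genuine ERD, so
single-bin attribution of ERD is only exact for an on-bin line.

The spectrum parameterizer models `log10 PSD` as
`offset − exponent·log10 f` plus Gaussian peaks and proceeds iteratively:
robust initial aperiodic fit (refit on the lower half of residuals so peaks
cannot pull the slope), iterative peak extraction from the flattened
spectrum with half-height bandwidth guesses, joint Levenberg–Marquardt
refinement of all peaks, removal of redundant overlapping Gaussians
(centers closer than 0.75 of their summed SDs; the taller survives), an
aperiodic refit on the peak-subtracted spectrum that masks each peak's
neighborhood (2 bandwidths, capped at 4 Hz — line-shape mismatch in the
wings must not tilt the slope), and one final peak refinement. Defaults:
fit range 2–40 Hz, at most 6 peaks, minimum peak height 0.1 log10 units,
detection threshold 2 SD of the flattened residual, bandwidth bounds
0.5–8 Hz. The parameterization is scale-equivariant — scaling the PSD by k
shifts the offset by `log10 k` and nothing else. The IAF is the center of
the tallest peak inside 8–13 Hz; when no alpha peak exists the result is an
explicit `NA` so the caller decides the fallback. On generator sessions at
default SNR, exponent and IAF recover with about 1% typical relative error
over exponents 0.5–2.5 and IAFs 8.5–12.5 (worst observed draw ~5%). That
verification grid co-varies the offset with the exponent
(`offset = exponent − 1.5`, anchoring the aperiodic level at 10 Hz), which
keeps in-band SNR at its default-typical value at every grid point and
mirrors the offset–exponent correlation seen across real participants.

## SEP quantification

Traces are band-limited to 3–500 Hz with fourth-order zero-phase
Butterworth filters after mean removal, epoched into 600-ms windows with
the stimulus at the center sample, averaged across epochs, and the average
is z-scored by the mean and SD of its own pre-stimulus half. The stated
processing order (average, then z-score) is the default; the per-epoch
z-scoring order is also exposed. Components are the most negative extremum
within ±3 ms of the nominal latency — N9 at 9 ms on EPi–EPc, N13 at 13 ms
on C2S–Fz, N20 at 20 ms on CPc–Fz (centers configurable; the convention
fixes them at the component names). Ties break to the earlier latency;
a monotone segment returns its endpoint.

The generator superposes negative Gaussian deflections (default: N9 3 µV /
3 ms FWHM, N13 2 µV / 3.5 ms, N20 2.5 µV / 2.5 ms) on white noise of 8 µV
RMS — single-sweep SEP SNR is genuinely below one, which is exactly why
a thousand sweeps are averaged. Two second-order effects surfaced during
verification and shape the tests: zero-phase high-pass filtering of an
evoked deflection spreads a small non-causal undershoot into the
pre-stimulus window, giving the averaged baseline SD a coherent floor
(~0.01–0.02 µV) independent of sweep count; and the extremum search adds
the averaged-noise value at the selected sample to each amplitude. Both are
inherent properties of this estimator, not bugs. Consequently the
`z ∝ sqrt(n)` averaging-gain law is verified on the mean ratio over six
independent sessions, where it holds within a few percent at
n ∈ {100, 400, 1000}.

## Speed–accuracy trade-off

Success of each timed typing trial is Bernoulli with
`p = a·exp(−b·x) + c` over time limits x ∈ {2, 4, 6} s; word lengths track
80–100% of the simulated typing capacity (`cpm/60 × x` characters, bounds
`[ceil(0.8·cap), floor(cap)]`, floor-clamped at one character, widened with
a warning if rounding empties the interval), and presented words are drawn
from a small bundled frequency-ranked list (a synthetic stand-in for a
basic-vocabulary list). The fit is bounded nonlinear least squares
(a ∈ [0, 1.5], b ∈ [0, 10], c ∈ [0, 1]) with multi-start over
b₀ ∈ {0.1, 0.5, 1, 2}: three points and three parameters make the problem
fragile, and the multi-start plus bounds make it reproducible. Noiseless
3-point data are interpolated exactly; with exactly three points the
residual is zero whenever a valid parameterization exists. `b` is only
weakly identified when the curve is near-flat over the observed x — at
`(a, b, c) = (0.9, 0.8, 0.05)` a single 5 × 30-word session estimates b
with a sampling SD around 0.4, dropping to ~0.16 near b = 0.5 — so b
estimates near the zero boundary are flagged, and group-level designs
should budget for this noise floor (see below).

## Statistics

The mixed 2×2 ANOVA is an explicit sums-of-squares decomposition (between
stratum: group against subjects-within-groups; within stratum: time and the
interaction against the subject × time residual; all tested effects on
(1, N−2) degrees of freedom), verified against `stats::aov` to 1e-8 on
random balanced and unbalanced designs. Both classical η² (SS/SS_total, the
default display) and partial η² are reported, since the two conventions
differ and published values are often ambiguous. The aligned rank transform
aligns each effect (cell-mean residual plus the effect's own estimate),
ranks with mid-ranks, and re-runs the same ANOVA, keeping only the aligned
effect's row. t tests delegate to `stats::t.test` (classical pooled
variance for two samples) and add Cohen's d — pooled-SD for two samples,
mean-difference over SD-of-differences (d_z) for paired data, a convention
flagged in the output because published d conventions vary. Identical
paired samples return t = 0, p = 1 by convention; zero-variance input with
a real shift is an error. The JZS Bayes factor uses the default Cauchy
prior (scale 1/√2) computed by numerical integration over the
inverse-gamma mixing variable, returned as log BF₁₀, and is cross-checked
against an independent Gauss–Kronrod quadrature.

The time–frequency cluster test computes pixelwise t maps (one-sample
against zero, or two-sample), thresholds at a pixel-level p, forms
sign-consistent 4-connected components scored by mass (sum of |t|), builds
the null from sign-flip or label permutations of the maximum cluster mass,
and applies Benjamini–Hochberg FDR across cluster p values. The mass
statistic with a permutation null is the standard construction where only
the correction ("cluster-level FDR") is specified; the pixel threshold and
connectivity are parameters.

## The two-group study and its power design

`generate_group_dataset()` builds a verum/sham pre-post study:
per-subject baselines (integer IAF 9–12, matching the 1-Hz online bins; ERD
depth ~N(0.30, 0.05); N20 amplitude ~N(2.0, 0.3) µV; saturation speed
~N(0.35, 0.06)) and verum-only training deltas (ERD +0.15, N20 +0.8 µV,
b +0.35 by default). Endpoints are extracted by the full pipeline: the
block ERSP at the IAF identified by spectral parameterization of the
pre-training spectrum (the offline endpoint is anchored at the
parameterized IAF, which is near-exact on the generator, rather than at the
noisier time–frequency argmin used for online calibration), the z-scored
N20 amplitude, and the fitted b.

Problem sizes are deliberately scaled: 6 EEG trials and 150 SEP stimuli per
session, 10 subjects per group, but 150 words per behavior block — the last
because the saturation-speed fit's measured noise floor (change-score SD
~0.17 at 150 words/block) sets the detectable effect; with the default
delta the standardized interaction effect is ~1.7, so the configured effect
is detected with high power while the zero-effect configuration stays at
the null rate. These sizes are the package's verification operating point,
stated here so users know what the end-to-end test does and does not
demonstrate.

## Numerical conventions and degenerate inputs

0-based sample thinking never leaks out: all sample indices are 1-based,
user-facing times are seconds. ERSP requires strictly positive reference
power (a non-positive reference bin is a degenerate-calibration error);
frame mapping requires p25 < p75; epochs without full pre/post windows are
dropped with a message; zero pre-stimulus SD, empty rest periods, missing
channels and missing montages raise the errors or partial-result warnings
described on each function's help page. EDF output quantizes to 16 bits
with per-channel physical scaling (the header stores limited-precision
ASCII bounds; scaling uses the stored values, so a round trip is exact to
about one digital step). Every generator is bit-reproducible from its seed,
and the generators restore the caller's RNG state.

## Known limitations

Channel-level analysis stands in for source estimation; the sham arm is
modeled only as feedback decoupled from the displayed recording (no yoked
participant pairing); no artifact rejection is applied anywhere by default
(SEP epoch thresholding exists but is off, since the emulated processing
described none); the specparam-style parameterizer is a simplified
re-implementation (no knee parameter, Gaussian peaks only); and the
behavioral model treats words as exchangeable given length — no
keystroke-level timing, word-frequency or learning effects.
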