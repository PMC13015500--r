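---
title: "Modeling fixation-locked neural responses to semantic novelty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fixation-locked neural responses to semantic novelty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixnov)
```

## The scientific problem

During natural vision, primates sample scenes through brief fixations
separated by saccades. Each fixation delivers a new foveal image patch, and
the semantic relation between consecutive patches — how *novel* the new
foveal content is — may modulate the neural response locked to each
fixation. `fixnov` implements the full analysis chain needed to ask that
question quantitatively:

1. detect saccades and fixation onsets from raw gaze traces;
2. extract 5° foveal patches and a battery of low- and mid-level visual
   features, plus **semantic novelty**, the cosine distance between
   embeddings of the pre- and post-saccadic patches;
3. preprocess scalp-like potentials or intracranial broadband
   high-frequency amplitude (BHA);
4. fit banded ridge temporal response function (TRF) encoding models with a
   fixed feature hierarchy; and
5. test the resulting improvements in prediction accuracy (Δr) and TRF
   weights.

Because real recordings are large and proprietary, the package ships a
seeded synthetic-data generator that emulates the statistical structure of
free-viewing experiments with *known ground truth*; every stage of the
pipeline is validated against that truth.

## The encoding model

Let $y_c(t)$ be the neural signal of channel $c$ and let each feature band
$b$ contribute a regressor $x_b(t)$: a train of pulses at saccade or
fixation onsets, either unit height (event bands), scaled by a feature
value (linear bands), or expanded into a cubic B-spline basis of the
feature value (nonlinear bands; 5 basis functions with interior knots at
feature quantiles). The model is a lagged linear convolution

$$\hat y_c(t) = \sum_b \sum_{\tau = \tau_{\min}}^{\tau_{\max}}
  w_{bc}(\tau)\, x_b(t - \tau),$$

with lags spanning $-0.2$ to $0.6$ s at 100 Hz for scalp-style analyses
(81 lags, inclusive endpoints) and $-0.5$ to $1.0$ s for intracranial BHA.
The weights $w_{bc}(\tau)$ are the temporal response functions.

**Banded ridge.** Each band gets its own penalty:
$\min_w \|y - Xw\|^2 + \sum_b \lambda_b \|w_b\|^2$, solved exactly by
scaling band $b$'s columns by $1/\sqrt{\lambda_b}$, solving a unit-penalty
ridge via Cholesky, and unscaling. With equal penalties this reproduces the
single-penalty ridge $(X^\top X + \lambda I)^{-1} X^\top y$ to machine
precision, which the test suite asserts at $10^{-8}$.

**Sequential penalty search.** Bands enter in a fixed hierarchy order
(saccade onset, fixation onset, amplitude, luminance, Δluminance, spectrum
slope, Δslope, optic flow, novelty). Each band's λ is swept over a
logarithmic grid while previously frozen penalties stay fixed; the value
maximizing mean cross-validated Pearson r is frozen. Ties go to the
smallest grid value. This ordering deliberately credits any shared variance
to the band added *first*, so a positive Δr for novelty — the last band —
cannot be explained by the earlier features. The test suite verifies the
ordering property directly: for two correlated synthetic features, the
second-added feature never receives more Δr than it would if added first
(sign test over 50 seeds).

**Cross-validation.** Leave-one-trial-out over contiguous trials (movie
chapters) or 5-fold over trials. Within each fold the design columns are
centered and scaled, and the response centered, using *training-fold
statistics only*; an oracle test reproduces the package's fold-level r from
an explicit refit to confirm that held-out data never leaks into training
statistics. Δr for band $k$ is the fold-level held-out r of the hierarchy
through $k$ minus that through $k-1$; by construction the stage r values
telescope.

## The synthetic generator as the study conditions

The generator's defaults describe the simulated experiment used throughout
the tests:

* **Events.** Fixation durations are gamma(shape 6, scale 0.05 s): mean
  300 ms, with durations under 110 ms rare (~2.5%), matching typical
  inter-saccade statistics; a hard floor of 80 ms is enforced by redrawing.
  Saccade amplitudes follow a right-skewed Beta(1.8, 3.5) over 1–12°, and
  saccade durations follow the main-sequence approximation
  2.2 ms/deg + 21 ms, so a 5° saccade peaks near 300°/s under the
  raised-cosine (minimum-jerk-like) velocity profile.
* **Gaze.** 500 Hz positions with 0.02° additive noise; blink-like invalid
  windows of 100–300 ms at Poisson times (0.05 Hz), exercising the 83 ms
  data-quality exclusion rule.
* **Features.** Novelty has a Beta(2.2, 2.8) marginal scaled to the cosine
  range [0, 2] and is tied to saccade amplitude through a Gaussian copula
  with target Pearson correlation 0.4 — emulating the strong
  amplitude–novelty dependence seen in free viewing. Other features are
  independent draws.
* **Neural signal.** Each channel's clean signal is the sum over bands of
  the event/feature pulse train convolved with a known per-channel TRF
  (damped oscillations with band-specific latency and polarity); only a
  designated channel subset carries the novelty band. Scalp mode adds
  1/f Gaussian noise synthesized in the frequency domain; BHA mode
  amplitude-modulates a multi-tone 70–150 Hz carrier before white noise.
  Where a test states an SNR, it is the RMS of the clean convolved signal
  over the RMS of the added noise.

What the generator does *not* emulate: photorealistic stimuli,
microsaccades, smooth pursuit, head movement, non-stationary noise, and
channel cross-correlation. Passing tests therefore demonstrate algorithmic
correctness and calibration under realistic event and spectral statistics,
not performance on any particular real dataset.

## Event detection

Two detectors mirror the two tracker families:

* **Threshold detector** (EyeLink-style): a saccade is a contiguous run of
  angular velocity above 30°/s containing at least one sample with
  |acceleration| above 8000°/s². Velocity is estimated over a 5-sample
  centered window before thresholding — raw sample-to-sample differences at
  500 Hz amplify position noise to ~10⁴ °/s² acceleration, drowning both
  thresholds. A per-sample conjunction of both thresholds would also split
  every saccade at its velocity peak, where acceleration crosses zero, so
  the run-plus-acceleration-evidence rule is used.
* **Dispersion detector** (Tobii-style): gaze is smoothed with a 21-sample
  (20th-order) running median — shrinking centered windows at the edges —
  and samples with velocity above mean + 2 SD (over valid samples of the
  whole recording) are marked; a morphological closing with a flat 5-sample
  kernel merges post-saccadic overshoot corrections. Fixation onset is the
  first post-onset sample whose velocity falls below the 70th percentile
  (linear-interpolation percentile, strict `<`) of velocities within
  −33 ms to +120 ms of saccade onset.

Exclusion rules drop saccades within 83 ms of low-quality samples and
saccades whose preceding fixation lasted under 110 ms (strict). Both rules
operate on the listed event sequence, which makes the operation idempotent.
Saccade amplitude is the Euclidean norm of the gaze change between onset
and offset.

## Patch features

All images are `[0, 1]` arrays indexed row (y) × column (x); "grayscale"
means the CIE L\* channel (D65 white point) rescaled to `[0, 1]`. The
battery comprises luminance/color statistics (L\*a\*b\* moments with
population skewness and excess kurtosis, zero for constant patches; HSV
saturation; hue diversity as 16-bin hue entropy over pixels with
saturation > 0.1), contrast and energy measures, the amplitude-spectrum
slope, texture/shape descriptors (LBP energy, Scharr/Sobel edge density at
the Otsu threshold, Hough line and circle counts at fixed documented
parameters, 32-level 4-direction symmetric GLCM statistics, blob statistics
at the mean-gray threshold), and Itti–Koch-style center–surround saliency
values sampled at the fixated location (intensity, red–green, and
blue–yellow opponency at 6 scale pairs each, plus Gabor orientation energy
summarized per orientation and per scale pair — 28 values; the exact scale
pairs are c ∈ {2,3,4}, s = c + {3,4}).

The **spectrum slope** radially averages the 2-D Fourier magnitude into 8
log-spaced bins over 0.1–10 cycles/degree (9 geometric edges, half-open
bins, DC excluded, bin centers at geometric means) and returns the negative
OLS slope of log magnitude against log frequency. Bins that are empty
because the patch is too small for the lowest frequencies are dropped with
a warning; fewer than three surviving bins is an error. On synthetic
textures with amplitude spectrum exactly $f^{-\alpha}$ the estimator
recovers α within ±0.1 for α ∈ {0.5, 1.0, 1.5}.

**Novelty** is `1 − cos(e_prev, e_curr)` between embeddings of consecutive
patches after resizing to 224×224 with cubic spline interpolation. The
default encoder is a deterministic random projection: block-average to
32×32, center, project through a fixed-seed Gaussian matrix to 128
dimensions, tanh. It is not a trained network, but it preserves
patch-similarity structure, which is all the validation requires:
independent texture redraws score reliably higher novelty than jittered
duplicates. Any callable with the same interface (for example a pretrained
contrastive-learning encoder) can be plugged in.

## Neural preprocessing

Scalp: zero-phase 4th-order Butterworth band-pass 0.5–64 Hz, polyphase
resampling to 100 Hz, least-squares EOG regression, and repair of residual
outliers (|x − median| > 4 IQR) by inverse-distance interpolation from
other channels averaged over ±40 ms. Intracranial: resample to 600 Hz,
0.5 Hz high-pass, local average reference against each channel's neighbor
set, and zero-phase order-500 FIR notches at 60 and 120 Hz (design edges at
±2 Hz so the line frequency sits in the full stop band rather than the
filter's transition region). BHA: 8 log-spaced Chebyshev type II band-passes
(order 4, 40 dB stop band) over 70–150 Hz, envelopes via the magnitude of
the FFT-constructed analytic signal, summed, resampled to 100 Hz, z-scored
per channel. All filtering is forward–backward; a band-limited test pulse
shifts by less than one sample.

## Statistics

* **Hierarchical bootstrap** of fold-level Δr: upper units (participants or
  trials) resampled with replacement, then lower units within each; p is
  the fraction of bootstrap means ≤ 0, floored at 1/N_boot (one-sided for
  the improvement hypothesis; two-sided for TRF peak values).
* **FDR** is Benjamini–Hochberg throughout.
* **Spatiotemporal cluster permutation**: one-sample t per channel × lag,
  cluster-forming threshold |t| > t-critical at two-sided α = 0.01,
  clusters connected through channel adjacency and lag contiguity with a
  common sign, cluster statistic = sum of t, null from sign-flipping whole
  viewings, p = (1 + #{null max ≥ observed})/(1 + N_perm).
* **Peaks**: magnitude is max |TRF|, latency its lag (earliest on ties),
  sign the TRF's sign there. A novelty modulation is *enhancement* when its
  sign at the novelty peak matches the baseline fixation TRF at that lag,
  *suppression* otherwise, and *indeterminate* when the baseline there is
  below 10% of its own peak.
* **Saccadic spike artifacts**: channels are clustered by average linkage
  on 1 − r of their saccade-locked TRFs (cut height 0.5); a cluster is
  flagged when its mean TRF peaks within ±20 ms of saccade onset *and*
  concentrates more than 60% of its energy within ±30 ms — a documented
  surrogate for the visual identification of stereotyped biphasic
  extraocular-muscle potentials.

## Validation experiments and their problem sizes

The acceptance layer (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) re-runs the full chain at these sizes, chosen as
the smallest scales at which the measured quantities are stable:

* **TRF recovery**: 600 s at 100 Hz, ~3 events/s, SNR 0.5, channels all
  carrying fixation and novelty bands; recovered kernels correlate ≥ 0.95
  with truth. This experiment generates exactly the two bands it measures.
  With four bands the saccade and fixation impulse trains are nearly
  collinear (a fixed 23–47 ms offset, quantized to 2–5 samples at 100 Hz),
  and the *split* between those two kernels — though not their sum, nor any
  feature kernel — is noise-limited at this SNR; the four-band condition is
  exercised by the Δr and demo experiments, which do not depend on that
  split.
* **Null calibration**: 240 s, 200 channels, novelty permuted with
  `make_null`, penalties from the sequential search, N_boot = 10³. The
  FDR-corrected significant fraction is ~0 (bound: 0.05 + 3 binomial SE)
  and Pr(p < 0.05) ≈ 0.05. Note that held-out Δr of a null band is slightly
  *negatively* biased — a band fitted to training noise can only lose
  out-of-sample accuracy — so the one-sided bootstrap p-values lean
  conservatively toward 1 rather than being exactly uniform. The package
  reports this as measured; the direction of the deviation protects, not
  inflates, the false-positive rate.
* **Cluster permutation**: 500 null stacks of 20 viewings × 16 channels ×
  81 lags with 10³ permutations give a family-wise false-positive rate
  ≈ 0.04 at α = 0.05.
* **Detection**: on a blink-free 60 s trace (blinks make gaze undefined and
  are the province of the exclusion rules, tested separately against a
  hand-enumerated fixture), sensitivity ≥ 0.99 with median onset error
  ≈ 3 ms.
* **Demo**: 300 s, 20 channels with novelty planted in 5, 12 trials,
  SNR 1; the pipeline flags a median of 5 true channels with 0 false
  positives over 10 seeds.

## Numerical choices and degenerate inputs

Event times are placed at the nearest sample with round-half-even. Lagged
designs are zero-padded at the boundaries, matching the generator's
convolution. The ridge solver removes the training-fold mean of the
response and centers/scales design columns by training statistics
(equivalent to an intercept; without the column centering, noiseless
recovery would be biased by the response mean). Zero-variance columns are
given unit scale; zero-variance responses make a fold's r undefined and the
fold is skipped with a warning. Constant patches return 0 skewness/kurtosis,
0 Michelson and orientation bias, GLCM contrast 0 / homogeneity 1 / ASM 1 /
correlation 0, and no blobs. Degenerate paired comparisons (zero-variance
nonzero difference) return a floored p-value.

## Known limitations

* The toy encoder captures low-frequency patch structure, not semantics; it
  validates the novelty *machinery*, and real analyses should inject a
  pretrained encoder.
* The saccade/fixation impulse-kernel split is weakly identified whenever
  saccade durations are nearly constant relative to the analysis rate; the
  package reports what the data support rather than hiding the degeneracy.
* Robust-PCA denoising, external saliency networks, and electrode
  localization are integration points (plain callables), not
  re-implementations.
* The per-fold Δr of truly null features is conservatively biased (see
  above); effect-size estimates for clearly significant features are
  unaffected.
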