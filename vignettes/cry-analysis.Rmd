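---
title: "Methods: acoustic signatures of infant cries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic signatures of infant cries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crysig)
```

## The scientific question

Human infant cries plausibly carry several kinds of information at once:
stable indexical cues (who is crying, how old they are, their sex) and
dynamic contextual cues (why they are crying). These hypotheses make
different acoustic predictions, and both are confounded in naturalistic
corpora by the nested structure of the data: cries come in sequences, nested
in recording sessions, nested in babies. A classifier that is allowed to see
cries from the same session in training and testing can "recognize" a baby
through the session's background noise or recorder gain rather than the
baby's voice. `crysig` packages the full analysis chain — segmentation,
descriptor extraction, leakage-safe classification experiments, drift
estimation, and a similarity map — together with a synthetic cohort
generator so each stage is testable against known ground truth.

## The synthetic cry and cohort model

### Source-filter synthesis

`synthesize_cry()` renders a cry from `cry_params()` controls that map
one-to-one onto the measured descriptors:

* a glottal pulse train follows a slow random f0 contour with the requested
  median and interquartile range (the contour is log-domain scaled, so the
  median is hit exactly and the IQR approximately);
* per-cycle period and amplitude noise inject jitter and shimmer. The
  injected Gaussian SD is pre-divided by E|e~i~ − e~i−1~| = 2/√π so that the
  *measured* local perturbation equals the requested percentage;
* pulses and an additive noise bed share an exponential spectral tilt
  e^−f/β^, with β solved numerically so the harmonic comb's
  magnitude-weighted centroid lands on the requested value; the noise level
  realizes the requested harmonics-to-noise ratio;
* sinusoidal amplitude modulation (default 70 Hz, inside the 30–150 Hz
  roughness band) supplies modulation-spectrum roughness;
* unvoiced gaps realize the requested voiced fraction. Gaps are kept under
  80 ms so the segmenter's 100 ms bridge keeps one cry in one piece, and the
  leading voiced run is at least 240 ms whenever the budget allows so that
  roughness (which needs a 200 ms voiced stretch) stays measurable.

The synthesizer is deliberately simple: no subharmonics, deterministic
chaos, formant tracking or perceptually realistic cry timbre. It exists so
that each descriptor has an independently controllable ground truth, and its
fidelity is asserted closed-loop in the test suite (monotone response of
each descriptor to its control; jitter recovered within ±0.5 points at 3%,
shimmer within ±1 point at 5%, median pitch within 5%).

### The latent cohort

`cohort_config()` defines a longitudinal design patterned on home-recording
cohorts: 24 babies by default, recorded at 0.5, 1.5, 2.5 and 3.5 months,
cries nested in crying sequences within sessions, with three cause labels
(hunger, discomfort, isolation) drawn at the sequence level with
probabilities matching the empirical shares of such corpora
(0.334/0.268/0.398). Per baby *b* and latent acoustic dimension *d*, a cry's
latent value is

u~bd~ + (slope~d~ + v~bd~)·age + cause~d~[c] + s~d~(session) + e,

with u~bd~ ~ N(0, `baby_signature_sd`) the individual signature, v~bd~ ~
N(0, `slope_sd`) between-baby drift variation, s~d~ ~ N(0,
`session_effect_sd`) a session-constant confound, and residual e. Defaults:
signatures at 1 SD (strong, recoverable individuality), population drift
encoding the tonality-up/roughness-down developmental pattern (entropy
−0.42 SD/month, voicing +0.24, HNR +0.17, pitch +0.11, centroid −0.19; the
perturbation/roughness dimensions, for which no published magnitude guided
us, are set to modest declines of 0.15–0.2 SD/month), zero cause effect
(the null that a cause classifier should confirm), and a 0.25 SD session
confound. Durations are log-normal with median 0.86 s, truncated to
[0.25, 12] s.

Latent SD-unit values reach physical units through fixed affine maps
(`latent_maps()`): pitch 450 ± 50 Hz per SD, centroid 1500 ± 300 Hz, HNR
12 ± 4 dB, and so on, clipped to plausible infant-cry ranges (the pitch
centre sits comfortably above the cry filter's 150 Hz floor). Values beyond
the map range are clipped rather than rejected; only non-finite or
physically impossible parameters error.

**Two tiers.** `simulate_cohort(audio = TRUE)` renders every cry to WAV and
the descriptors are then *measured* with `extract_features()` — the full
closed loop, used at small scale. `simulate_cohort(audio = FALSE)` (the
default) emits measured descriptors directly through the affine maps — the
fast path used for classifier-scale simulation studies (thousands of cries).
The latent model is identical in both tiers; the descriptor tier simply
bypasses the audio round trip, whose fidelity is certified separately. What
the descriptor tier does *not* emulate: pitch-tracking octave errors,
descriptor cross-talk (e.g. heavy jitter depressing measured HNR), or
missing descriptors on marginal cries. Conclusions from descriptor-tier
simulations are therefore about the statistical design, not about the
robustness of the measurement layer.

One seed stream per baby (counter-based) means enlarging a cohort never
reshuffles existing babies. Sex is assigned in a fixed 10:14 F:M proportion
and has no acoustic effect by default.

## The descriptors and their numerical choices

Frame analysis uses 40 ms Gaussian-windowed frames at a 10 ms hop, f0 search
range 150–1200 Hz, and a normalized-autocorrelation voicing threshold of
0.45 (all config-exposed). Specifics worth knowing:

* **Pitch.** The autocorrelation of a periodic frame peaks near-equally at
  T, 2T, 3T; the tracker takes the *shortest* lag whose peak is within 0.02
  of the maximum, then refines by parabolic interpolation. Per-cry pitch is
  the median (and IQR) over voiced frames — robust to residual tracking
  errors.
* **Wiener entropy** is spectral flatness (geometric/arithmetic mean of
  power), 0–1. Raw periodogram bins of white noise have flatness ≈ 0.56 from
  chi-square bin variability alone, so the per-frame spectrum is smoothed
  with a 9-bin running mean (~200 Hz at 44.1 kHz) before flatness; white
  noise then measures ≈ 0.8–0.9 and tones near 0. The exported
  `wiener_entropy()` applies no smoothing — it is the bare formula.
* **HNR** is 10·log₁₀(r/(1−r)) at the pitch lag, clipped to [−10, 40] dB;
  r ≥ 1 clips to 40 dB with a warning.
* **Jitter/shimmer** use the "local" period-to-period formula on glottal
  pulses tracked from the waveform (guided by the frame f0 contour, peaks
  parabolically interpolated, per-pulse amplitudes measured against a
  rolling-median baseline ~1.5 periods wide so AC-coupling offsets do not
  inflate relative amplitude variation). Tracking glitches (skipped or
  doubled pulses) appear as periods outside [0.55, 1.45]× the run median;
  runs are split at such points and the measures computed within clean
  stretches, weighted by length. Fewer than 3 consecutive periods yields a
  missing value.
* **Roughness** is the share of amplitude-envelope modulation power
  (envelope via rectification + 4th-order Butterworth low-pass at 400 Hz)
  in 30–150 Hz relative to 1–400 Hz, per voiced segment of ≥ 200 ms, median
  across segments. Whether "proportion of the modulation spectrum" means
  power or amplitude is a convention; this package uses power, and the
  denominator band 1–400 Hz, throughout.
* **Loudness is deliberately not a descriptor** (recording distance is not
  standardized in home corpora); all descriptors are invariant to overall
  amplitude scaling, which the tests assert.

Segmentation finds above-threshold runs of a 20 ms/10 ms RMS envelope
(3-point median smoothed; threshold 5% of the 95th-percentile envelope),
bridges gaps < 100 ms, drops runs < 50 ms, and then refines each boundary on
a 5 ms/1 ms envelope — without refinement the coarse windows smear a 30 ms
blip past the 50 ms floor. The four-condition cry filter applies its
inequalities exactly as printed (voicing ≥ 0.20 inclusive; pitch > 150 Hz,
duration > 0.250 s, entropy < 0.6 strict), and missing descriptors reject as
"unmeasurable" rather than pass silently.

## The classification experiments

All experiments share one engine, `run_experiment()`:

1. **Grouped split.** Whole sessions are assigned to train or test
   (test fraction 1/3); no session appears on both sides. Splits with every
   class on both sides are preferred; when class coverage makes that
   impossible (e.g. two sessions per baby within one age group), every class
   must at least appear in training. A class confined to fewer than two
   sessions errors by name. `group_key = NULL` gives the naive per-cry
   split — retained only to demonstrate leakage.
2. **Balance.** Each side is downsampled to its rarest class, so chance is
   exactly 1/K and macro = micro accuracy.
3. **Forest.** 500 trees, √p candidate features per split, no depth limit
   (`ranger`, single-threaded, seeded end-to-end including prediction
   tie-breaking, so experiments are bit-reproducible).
4. **Summary.** Median accuracy over repeated splits, empirical 2.5/97.5
   percentile coverage interval, odds ratio to chance, and impurity-based
   feature importance. An accuracy of exactly 1 maps to OR = ∞ and exactly
   0 to OR = 0 by convention.

`test_retest()` builds the age-transfer matrix (columns = training age,
rows = testing age) restricted to babies present at every age, sessions
disjoint even on the diagonal. `per_baby_cause_models()` trains cause
classifiers within one baby and tests on held-out sessions of the same baby
versus all other babies. `context_distances()` summarizes each baby per
cause by its mean *within-baby-normalized* descriptor vector and correlates
the per-cause baby-distance matrices (permutation p-values over babies);
within-baby normalization is essential here — under global normalization the
stable individual signature dominates every cause's matrix and correlates
them trivially, saying nothing about cause coding.

### Normalization scopes

`normalize_features()` z-scores within baby (for age and cause questions,
so signatures cannot masquerade as effects) or globally (for identity
questions, where the signature is the signal). The package follows this
pairing throughout.

### The drift estimator

`estimate_age_sex_effects()` deliberately replaces a multivariate Bayesian
mixed model with a transparent frequentist surrogate: per baby and feature,
an OLS slope of the feature against age, expressed in SD units per month by
dividing by the *residual* SD of that same fit. (Dividing by the baby's
total SD would fold the drift itself into the unit and attenuate every
slope toward zero — a ~25% bias at 0.4 SD/month over four ages.) Slopes are
aggregated by a precision-weighted mean; CIs come from a cluster bootstrap
over babies using a normal approximation with a t critical value on the
bootstrap SE, which holds nominal coverage with the ~10–24 clusters typical
of such cohorts where percentile intervals undercover. The sex contrast
(M − F) uses per-baby means under global normalization, same bootstrap. The
estimator is validated by parameter recovery: an injected −0.4 SD/month
slope is recovered without bias and its 95% CI covers the truth in ≥ 90% of
replicate cohorts (asserted in the test suite over 50 replicates of a
12-baby cohort — a size chosen for bootstrap validity, with run counts that
keep the default test run to a few minutes).

## Similarity and the acoustic map

`dtw_distance()` is classic dynamic time warping (diagonal/horizontal/
vertical steps, Euclidean local cost) over frame contours of pitch
(semitones, so distances are ratio-scaled), harmonicity (dB), entropy and
centroid (kHz), with total path cost divided by path length so longer cries
are not penalized. Unvoiced pitch gaps are imputed by last observation
carried forward (leading gaps by the first value) and features are z-scored
globally across the collection before comparison. The implementation is
native (Rcpp) and verified against exhaustive enumeration of all monotone
warping paths on short contours; backtracking prefers the diagonal, giving
the shortest path among cost ties. No warping window is imposed — cries are
short.

For the 2D map, the distance matrix is computed once and embedded with
non-metric MDS (`MASS::isoMDS` initialized from classical MDS), an
established algorithm that accepts precomputed distances and is
deterministic for a given matrix. `cluster_separation()` reports the mean
silhouette of any labelling on the distance matrix or the embedding; on the
default synthetic cohort, identity labels separate while cause labels do
not — the qualitative signature of a corpus with individual signatures and
no cause coding.

## Problem sizes and runtime choices

Audio synthesis plus full descriptor extraction costs ~0.2 s per cry, so
closed-loop audio checks run on tens of cries. Classifier-scale studies use
the descriptor tier: the null-calibration and signature-recovery experiments
in the tests use 12 babies × 2 sessions/age × 21 cries (~2000 cries) with
25–40 repeated splits; the drift studies use 6–12 babies with 6–25 splits
per cell or 50 replicate cohorts. These sizes are the package's defaults for
simulation studies; scaling any of them up only narrows the intervals.

## Known limitations

* The synthesizer's spectral model (exponential tilt, no formant structure)
  is enough to steer the centroid but not to imitate real cry timbre;
  transfer of numerical results to recorded corpora must go through the
  audio tier or real data.
* The descriptor tier has no measurement noise beyond the latent residual,
  so descriptor-tier accuracies are upper bounds relative to
  audio-extracted features at the same effect sizes.
* HNR saturates near 15–18 dB when jitter/shimmer are present (perturbation
  decorrelates the autocorrelation peak) — real phonation behaves the same
  way, but sweeps of the HNR control flatten at the top.
* The drift estimator assumes linear drift within the observed age range and
  ignores sequence-level dependence (sessions are the grouping unit; the
  stricter of the two).
* The session confound enters through the latent acoustic dimensions (an
  acoustically realized shift), not through an added noise bed in the audio;
  leakage via literal shared background noise is therefore emulated, not
  reproduced.
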