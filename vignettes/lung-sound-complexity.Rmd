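---
title: "Morphological complexity analysis of lung sounds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological complexity analysis of lung sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Chest auscultation picks up breath sounds whose character changes with
pulmonary disease: crackles (short explosive transients), wheezes
(sustained musical tones) and harsher, wider-band breath noise all
accompany obstructive and interstitial conditions. The temporal waveform
and the raw spectrum separate these classes poorly — breath sounds are
nonstationary and their spectra overlap — but the *morphology* of the
amplitude distribution and the *texture* of the signal do discriminate.

`lungmorph` implements an end-to-end pipeline on single-channel 8 kHz
PCM recordings:

1. **Enhancement.** First-order differencing removes slowly varying
   instrumental baseline; heart-sound (HS) interference is suppressed by
   empirical mode decomposition (EMD) and selective reconstruction.
2. **Respiratory-cycle segmentation.** Breathing-phase transition points
   are the minima of the smoothed Hilbert envelope; two consecutive
   phases form one cycle.
3. **Feature extraction**, per cycle: excess kurtosis `chi`, skewness
   `xi`, gliding-box lacunarity `zeta`, sample entropy `alpha`. The
   nested feature sets are set 1 = (chi, xi), set 2 = + zeta,
   set 3 = + alpha.
4. **Classification** with an extreme learning machine (ELM) or an
   RBF-kernel soft-margin SVM, evaluated by stratified 5-fold
   cross-validation reporting accuracy, sensitivity and specificity.

A seeded synthetic-recording generator with exact ground truth stands in
for clinical recordings, which cannot be redistributed.

## Enhancement

**First difference.** `first_difference()` maps the signal to
`y[n] - y[n-1]`. It removes DC and strongly attenuates drift; the output
is one sample shorter, and no stage downstream assumes equal length with
the raw input.

**EMD.** `emd_decompose()` performs standard sifting: cubic-spline
envelopes through the local maxima and minima, subtract the envelope
mean, repeat. We adopt the community defaults — Cauchy-type
normalized-SD stopping threshold 0.2, at most 10 sifting iterations per
IMF, at most 12 IMFs — and stop a sift early only when the IMF property
(extrema and zero-crossing counts within one of each other) also holds.
Spline envelopes mirror-extend two extrema beyond each edge, which
suppresses end swings without inventing data. The decomposition is
additive by construction, so reconstruction is exact to floating point.

**Heart-sound suppression.** S1/S2 heart sounds concentrate below about
150 Hz on the chest wall, while breath-sound energy extends well above.
`remove_heart_sound()` therefore attributes each IMF to the lung or
heart component by its spectral centroid, with a 150 Hz threshold
(config-exposed), and rebuilds the lung-sound estimate from the
high-centroid modes. The removed component is returned for inspection.
This centroid partition is this package's own rule: it is a transparent,
tunable criterion that behaves well on mixtures where heart and breath
energy are spectrally disjoint. Two caveats follow from EMD itself: mode
mixing can leave some burst energy in high-centroid IMFs when the HS
share is very large, and because EMD is nonlinear the operation is only
approximately idempotent — re-applying it can split off a further weak
low-frequency mode. Both effects are measured in the test suite.

The pipeline applies differencing first and HS suppression second; the
stages are composable in either order and can be disabled individually
for ablation.

## Cycle segmentation

The instantaneous amplitude is the magnitude of the analytic signal
(frequency-domain Hilbert transform). The raw envelope is smoothed by an
order-4 low-pass Butterworth at 5 Hz applied forward-backward. Zero
phase matters: transition points are derivative sign changes, and any
group delay would bias every boundary. A "Butterworth" filter is IIR by
construction; a linear-phase windowed-sinc FIR with the same cutoff is
provided as a config alternative (`kind = "fir_sinc"`) for users who
want strictly finite impulse response. Before filtering, the envelope is
odd-reflection padded by eight cutoff periods at each end; plain
forward-backward filtering implicitly assumes zeros beyond the edges and
would drag the smoothed envelope toward zero there, corrupting boundary
minima at the recording edges.

On sampled data the derivative is almost never exactly zero, so the
transition-point rule "derivative negative, zero, positive" is realized
as a sign change of the discrete first difference (non-positive followed
by positive), with ties over flat valleys broken toward the earliest
index. Three guards suppress spurious minima, all config-exposed:

* a **minimum phase duration** (0.3 s): candidate minima closer together
  are merged keeping the deeper one — no credible breathing phase is
  shorter;
* a **prominence floor** (10% of the envelope's 95th percentile):
  ripple notches that barely rise toward their neighbouring candidates
  are discarded. Prominence is measured toward neighbouring candidates
  only; the outward side of the first/last candidate is unbounded,
  since the envelope cannot be expected to rise beyond the recording
  edge;
* a **depth gate** (25th envelope quantile): a breathing-phase boundary
  sits near the envelope floor, so minima above the gate (for example
  gaps between crackle bursts mid-inspiration) are rejected.

Recording edges count as transition points when the envelope moves away
from the edge or the edge lies in the quiet sub-threshold range, so
recordings that begin and end at a phase boundary yield the full cycle
count. Whether a cycle starts with inspiration or expiration is not
detectable from the envelope alone; cycles are reported phase-agnostic,
which is consistent with the features, all of which are order
statistics of the cycle's samples.

## The morphological features

All moments use population (1/N) normalization, matching the
expectation-operator definitions; no small-sample bias correction is
applied.

* **Excess kurtosis** `chi = m4 / sigma^4 - 3` and **skewness**
  `xi = m3 / sigma^3` describe tailedness and asymmetry of the
  amplitude distribution. Crackle transients push `chi` up.
* **Lacunarity** `zeta(l) = M2 / M1^2` of the gliding-box masses: a box
  of `l` samples slides with stride 1; its mass is the sum of
  mass-transformed samples (default `abs`, since acoustic samples are
  signed and Jensen's inequality then guarantees `zeta >= 1`).
  Box lengths are not prescribed by the feature definition; the package
  sweeps the dyadic lengths `2, 4, ..., <= L/16` and summarizes by the
  geometric mean of `zeta(l)`, keeping the full profile available. The
  `L/16` cap keeps boxes well below the breathing-phase timescale, so
  the summary reflects texture *within* phases (crackle bursts,
  turbulent-flow roughness) rather than the inspiration/expiration
  geometry that both classes share.
* **Sample entropy** with the standard parameters m = 2 and
  r = 0.2 × SD of the cycle: the negative log conditional probability
  that templates matching at m points (Chebyshev distance, self-matches
  excluded) still match at m + 1. The SD-relative tolerance makes the
  index amplitude-invariant. Template counting is O(N²) and implemented
  in C++; the test suite pins it to an independent double-loop oracle at
  1e-12.

All four features (with SD-relative r) are invariant under amplitude
scaling, so microphone gain cannot leak into classification.

## Classifiers

Features are standardized to zero mean and unit variance, with the
scaler fitted on the training fold only — RBF distances are meaningless
across raw units.

**ELM.** A single hidden layer of 10 radial-basis nodes whose centers
and widths are drawn randomly and never tuned; only the output weights
are learned, as the minimum-norm least-squares solution via an SVD
pseudoinverse (singular values below 1e-10 of the largest truncated).
The sampling law is the package's choice: centers uniform over the
standardized training bounding box, widths uniform on (0, 1] scaled by
the inverse squared median inter-sample distance, which keeps
activations non-degenerate at any feature scale. The draw depends only
on the seed and order-invariant data summaries, so reordering the
training set does not change the model.

**SVM.** The usual soft-margin dual with Gaussian kernel, solved by
libsvm (through e1071) at a 1e-8 termination tolerance; support vectors,
dual coefficients and bias are extracted into a transparent model whose
prediction path is the explicit kernel expansion implemented here.
Defaults C = 1 and gamma = 1/d on standardized features. The dual
solution is cross-checked in the tests against an independent
interior-point QP solve, and the box/equality constraints are asserted
directly. Zero decision scores break toward the abnormal class for both
classifiers: in a screening context the costlier error is a missed
abnormality.

**Evaluation.** Stratified 5-fold cross-validation at the cycle level
mirrors the common protocol; per-fold percentages are averaged
arithmetically, and pooled-count metrics are reported alongside. Cycle
level splitting risks subject leakage when several cycles come from one
subject, so a `subject_grouped` mode that keeps all cycles of a subject
in one fold is provided and recommended whenever subject identity is
known. Metrics with zero denominators are reported as `NA`, never as 0.

## The synthetic generator

`gen_config()` / `generate_normal()` / `generate_abnormal()` emulate
the statistical structure the pipeline assumes, with exact ground
truth:

* **Normal class:** Gaussian noise band-passed to 150-900 Hz (vesicular
  breath band), amplitude-modulated by raised-cosine per-phase
  envelopes. Inspiration 1.2 s and expiration 1.8 s on average with
  0.1 s jitter; the expiration peak is drawn once per recording from
  U(0.3, 0.75) of the inspiration peak, emulating the wide
  inter-subject spread of expiratory loudness. A constant noise floor
  (5%) keeps the envelope realistic between breaths.
* **Abnormal class:** the same construction with four pathological
  departures, each config-exposed: (i) the carrier band extends to
  2200 Hz — the harsher, more bronchial spectrum of pathological breath
  sounds; (ii) the breath envelope is roughened by slow multiplicative
  noise (depth 0.5, ~40 ms correlation), emulating irregular turbulent
  flow — this timescale sits above the 5 Hz envelope smoother, so it
  cannot disturb segmentation, and below the phase timescale, where the
  lacunarity sweep looks; (iii) crackles: ~12 per cycle (Poisson),
  10 ms damped sinusoids at 600 Hz, 3.5× the local envelope,
  Poisson-placed within inspirations; (iv) wheezes: with probability
  0.7 per cycle, a ~400 Hz tone of 0.4 s at 0.6× the local envelope in
  the expiration. Event times are recorded. A single `severity` scalar
  scales crackle rate and wheeze amplitude so tests can sweep
  difficulty.
* **Heart sounds:** paired S1/S2 Hann-windowed bursts at 40/60 Hz,
  ~1 beat/s with 2% timing jitter; `mix_heart_sound()` scales the HS so
  the lung-sound component carries an exact target fraction of total
  energy (e.g. 20% LS + 80% HS).

With crackle rate 0, wheeze probability 0, zero irregularity and the
abnormal band equal to the normal band, `generate_abnormal()` is
bit-identical to `generate_normal()` under the same seed — the
departures are strictly additive to a shared construction.

**What the generator does not emulate** — and hence what green tests do
and do not show: real airway acoustics (transmission filtering through
lung tissue and chest wall), sensor coupling and ambient noise,
disease-specific crackle waveforms, squawks (covered only implicitly as
a crackle/wheeze combination), and genuine inter-subject correlation
structure. Passing the separation and classification benchmarks shows
the pipeline recovers the morphological structure the generator
plants — higher texture heterogeneity and irregularity in the abnormal
class — at realistic SNR; it does not certify clinical accuracy on
patient data, for which the subject-grouped protocol and a real
dataset are required.

## Numerical choices and degenerate inputs

* PCM scaling: divide by 32768 on read; multiply by 32768, round half
  away from zero and top-code 32768 to 32767 on write. Zero is lossless
  and a read-write round trip of any 16-bit file is bit-identical.
* FFT-based operations (analytic signal, spectra) zero-pad to the next
  2-3-5-smooth length; R's FFT degrades badly on lengths with large
  prime factors. The padded tail of the analytic signal is discarded.
* Zero-variance cycles cannot produce standardized moments or an
  SD-relative SampEn tolerance; they are skipped with a warning rather
  than failing a whole recording.
* SampEn with no template matches is an error reporting the counts, not
  a silent 0 or Inf; lacunarity of an all-zero-mass series is likewise
  an error.
* Ties: flat envelope valleys resolve to their earliest index; zero
  classifier scores resolve to the abnormal class.
* Classifier serialization uses decimal JSON (full precision); reload
  agrees with the original model to within a couple of ulps, and
  label predictions are identical.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their runs as follows
(package choices, balancing statistical resolution against a desk-scale
run): oracle equivalence on 100 random series of length ≤ 200; ELM
optimality on 50 random problems; SVM/QP agreement on 20-sample
problems; EMD reconstruction on 100 seeded signals; segmentation
recovery on 200 recordings (tests) and 60 (script); feature separation
on ≥ 100 cycles per class; and a 120-cycle benchmark — 15 normal and
15 abnormal recordings of 4 cycles each — for the 5-fold evaluation of
all three feature sets and both classifiers, mirroring a 120-cycle
clinical corpus in geometry. Benchmark accuracies are averaged over ten
repetitions of the 5-fold protocol with different fold seeds: a single
fold assignment on 120 cycles quantizes mean accuracy to 0.83% steps,
and repeated cross-validation is the standard way to average that
assignment noise out of set-to-set comparisons.

## Known limitations

* Cycle-level cross-validation on multi-cycle recordings is optimistic;
  use `split_mode = "subject_grouped"` for honest generalization
  estimates on real data.
* The centroid-threshold HS/LS partition is a transparent substitute
  for proprietary removal rules; with heavy HS dominance (80%+), some
  burst energy leaks into the retained modes.
* EMD has no convergence theory; the sifting caps bound its runtime but
  the decomposition is empirical, and mode mixing is possible.
* Full-cycle SampEn is O(N²): about 3 × 10^8 template pairs for a 3 s
  cycle at 8 kHz. The C++ kernel keeps this to roughly a second per
  cycle; decimating before SampEn would be faster but changes the
  feature's scale and is deliberately not done silently.
* Under the synthetic conditions `chi` and `zeta` are positively
  correlated — both respond to crackles and envelope roughness — so the
  incremental accuracy of set 2 over set 1 is modest (and for the SVM
  sometimes within fold noise); the sample-entropy increment of set 3
  is the large, consistent one.
* The claim that a higher-dimensional per-cycle representation (e.g.
  several windows per cycle) could further help is untested here; the
  three nested sets keep 2-4 dimensions per cycle.
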