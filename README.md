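# lungmorph

Discriminating normal from abnormal lungs using the morphological
complexity of auscultation sounds.

Chest recordings of breathing carry diagnostic structure that plain
spectra miss: crackles, wheezes and harsher bronchial noise change the
*shape* and *texture* of the signal. `lungmorph` implements a complete
pipeline for single-channel lung-sound recordings (16-bit PCM mono WAV,
8 kHz):

1. **Enhancement** — first-order differencing removes instrumental
   baseline; heart sounds are suppressed by empirical mode decomposition
   (EMD), keeping the intrinsic mode functions whose spectral centroid
   lies above 150 Hz.
2. **Respiratory-cycle segmentation** — breathing-phase transition
   points are the minima of the Hilbert envelope smoothed by a
   zero-phase 5 Hz Butterworth low-pass; two consecutive phases form one
   cycle.
3. **Per-cycle complexity features** — excess kurtosis
   χ = m₄/σ⁴ − 3, skewness ξ = m₃/σ³, gliding-box lacunarity
   ζ = M₂/M₁² (box-mass moment ratio, geometric mean over a dyadic box
   sweep), and sample entropy α = −ln(A/B) with m = 2, r = 0.2·SD
   (Chebyshev template matching, self-matches excluded). Feature sets
   are nested: set 1 = (χ, ξ), set 2 = (χ, ξ, ζ), set 3 = (χ, ξ, ζ, α).
4. **Classification** — an extreme learning machine (10 random RBF
   hidden nodes, output weights by Moore-Penrose pseudoinverse) or an
   RBF-kernel soft-margin SVM, evaluated by stratified 5-fold
   cross-validation reporting accuracy (CA), sensitivity (SEN, abnormal
   recall) and specificity (SPE, normal recall).

Because clinical auscultation corpora cannot be redistributed, the
package ships a seeded synthetic lung-sound generator with exact
ground-truth cycle boundaries, crackle/wheeze events and controllable
heart-sound mixtures; all benchmarks run against it. The methods
vignette (`vignettes/lung-sound-complexity.Rmd`) documents every model
choice, default and limitation.

The package is aimed at biomedical-signal-processing researchers and
engineers prototyping automated auscultation analysis; it is not a
clinical diagnostic tool.

## Worked example

Generate an abnormal recording, run the pipeline, and inspect the
per-cycle features:

```r
library(lungmorph)

rec <- generate_abnormal(gen_config(seed = 42))
rec$signal
#> <lung_sound> 98757 samples @ 8000 Hz (12.345 s), label: abnormal

enhanced <- enhance_signal(rec$signal)
cycles <- segment_cycles(enhanced)
cycles
#>   cycle_id start_sample end_sample transition_sample duration_s
#> 1        1            0      26413             10937   3.301625
#> 2        2        26413      48510             35536   2.762125
#> 3        3        48510      73932             59164   3.177750
#> 4        4        73932      98755             83163   3.102875

extract_features(enhanced, cycles, "set3")[, c("cycle_id", "chi", "xi", "zeta", "alpha")]
#>   cycle_id       chi           xi     zeta     alpha
#> 1        1 10.112469  0.036894658 1.921976 0.4653715
#> 2        2  9.119535 -0.034191802 1.817615 0.5074925
#> 3        3  4.773658  0.030406060 1.716430 0.4109029
#> 4        4  5.632916  0.003243978 1.751714 0.4738496
```

Four cycles are found, with boundaries within tens of milliseconds of
the generator's ground truth (`rec$true_boundaries`: 0, 10825, 25990,
35628, 49144, 59175, 74039, 83113, 98757). The abnormal cycles show
positive excess kurtosis inflated by crackles, near-zero skewness (the
amplitude distribution stays symmetric), lacunarity well above the
homogeneous-signal value 1, and the sample entropy of a wide-band
irregular signal — on matched normal recordings ζ and α are
systematically lower.

A full 120-cycle benchmark (15 normal + 15 abnormal recordings, 5-fold
cross-validation of every feature set and both classifiers):

```r
study <- run_study(seed = 1)
study$reports$elm.set3
#> <evaluation_report> elm / set3, 5 folds (cycle_stratified, seed 1)
#>  fold TP TN FP FN        CA       SEN SPE
#>     1  9 12  0  3  87.50000  75.00000 100
#>     2 11 12  0  1  95.83333  91.66667 100
#>     3 11 12  0  1  95.83333  91.66667 100
#>     4 12 12  0  0 100.00000 100.00000 100
#>     5 11 12  0  1  95.83333  91.66667 100
#> mean: CA 95.00%  SEN 90.00%  SPE 100.00%
```

Averaged over ten repetitions of the 5-fold protocol (what
`scripts/acceptance.R` reports at `--seed 1`), mean accuracy rises with
the nested sets for both classifiers — ELM 83.9% / 87.4% / 91.8% and
SVM 83.8% / 85.6% / 93.3% for sets 1/2/3: the texture (ζ) and
irregularity (α) indices carry most of the discriminative information.

## Command-line use

A thin CLI wraps the same functions:

```sh
lungmorph simulate --out data/ --n-normal 15 --n-abnormal 15 --seed 1
lungmorph extract --out features.csv data/*.wav
lungmorph evaluate --features features.csv --classifier elm --out report.json
lungmorph run-all --out results/ --seed 1
```

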