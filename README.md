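# eegscape

Within-subject decoding of perceived landscape category from multichannel
EEG. The package implements a complete, reproducible version of a
block-design perception study: subjects watch seven categories of
landscape video (forest, wetland, grassland, desert, water, farmland,
city; ~40-s blocks, two repeats each, randomized order), and the question
is whether the landscape category can be recovered from single 2-s epochs
of scalp EEG. Because the underlying human recordings are not publicly
deposited, the package ships a first-class synthetic-data generator that
reproduces the study design with a controllable class effect, so the whole
analysis is testable end to end.

## What it computes

For each 2-s epoch (29 channels × 500 samples at 250 Hz) and each
frequency band b ∈ {δ 1–4, θ 4–8, α 8–13, β 13–30, γ 30–70 Hz}, six
feature families:

* **MAS**: `log mean_{f ∈ b} |X(f)|` — log mean amplitude spectrum
  (Hann-tapered FFT);
* **PSD**: `log mean_{f ∈ b} S(f)` — log mean periodogram density;
* **DE**: `½ ln(2πe σ²_b)` — differential entropy of the band-filtered
  signal under the Gaussian closed form;
* **DASM / RASM**: `DE_left − DE_right` and `DE_left / DE_right` over 13
  mirror-symmetric electrode pairs;
* **DCAU**: `DE_frontal − DE_posterior` over 11 fronto-caudal pairs.

Per band this gives 29 / 29 / 29 / 13 / 13 / 11 dimensions, and the
"total" band (concatenation over the five bands) 145 / 145 / 145 / 65 /
65 / 55. Every (family × band) design is decoded per subject with four
classifiers — a back-propagation neural network, KNN (k = 5), a random
forest (500 trees) and a linear SVM — under stratified 10-fold
cross-validation with per-fold standardization, and aggregated across
subjects as mean ± SD accuracy.

Preprocessing: linked-mastoid re-referencing, linear detrending,
anti-aliased downsampling to 250 Hz, zero-phase 0.5–70 Hz band-pass,
ICA-based blink removal, 2-s epoching with 100 µV amplitude rejection.
A clean session yields 7 × 2 × 20 = 280 epochs per subject.

## Worked example

```r
library(eegscape)

montage <- default_montage()
schedule <- make_schedule(seed = 1)          # 14 blocks, 7 classes x 2
rec <- generate_subject(schedule,
                        class_signatures(montage),
                        noise_model(montage),
                        montage, seed = 1, subject_id = "S01")
rec
#> <eeg_recording> 32 ch x 1350.0 s @ 500 Hz, 14 annotations [S01]

epochs <- preprocess_recording(rec, montage, artifact_method = "ica")
epochs
#> <epoch_set> 280 epochs x 29 ch x 500 samples @ 250 Hz (0 rejected)

tensor <- extract_features(epochs, montage)
des <- make_design(tensor, "DE", "gamma")
cell <- evaluate_subject(des$X, des$y, classifier_spec("svm"), seed = 1)
round(cell$mean_accuracy, 3)
#> [1] 0.893
round(cell$sensitivity, 2)
#>    1    2    3    4    5    6    7
#> 0.82 0.70 0.85 0.90 0.98 1.00 1.00
```

The 280 epochs are the 20 contiguous 2-s windows of each of the 14 blocks;
`mean_accuracy` is the mean over the 10 cross-validation folds, and
`sensitivity` the per-class recall accumulated over held-out folds. With
the default class signatures (log-spaced gamma/beta power gains across
classes) gamma-band decoding is strong while delta-band decoding sits near
the 1/7 chance level — the band ordering the analysis is designed to
detect.

The numbered scripts under `analysis/` run the same pipeline as a
narrative workflow (simulate → extract → classify → report), writing EDF
recordings, feature tables, the grid of accuracies and a formatted
mean ± SD table under `results/`.

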