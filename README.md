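# dwtselect

Automatic selection of discrete wavelet transform (DWT) settings for EEG
seizure detection.

## The problem

Wavelet-based seizure detectors decompose an EEG segment with a multilevel
DWT, compute statistics of the coefficients in each frequency band, and feed
the resulting feature vector to a classifier. Their performance hinges on
four settings that are usually fixed by habit: the **mother wavelet**, the
**decomposition level**, the **frequency bands** kept, and the **coefficient
features** extracted. `dwtselect` searches these settings systematically,
scoring every candidate by cross-validated classification accuracy and
preferring low-dimensional feature vectors, so a detector can be tuned to a
recording setup instead of inherited from one.

The package is aimed at biomedical-signal researchers who have labeled
seizure / non-seizure EEG segments (or want to simulate them) and need a
reproducible way to choose DWT settings.

## The method

An EEG segment `s` of `N` samples is decomposed with the Mallat pyramid
algorithm: at each level the signal is split by a conjugate pair of filters
into a detail band `d_j` and an approximation `a_j`, and the approximation is
split again. A level-`j` decomposition yields `j + 1` bands. For a signal
occupying `(a, b)` Hz, detail band `n` occupies
`(a + (b-a)/2^n, a + (b-a)/2^(n-1))` and the final approximation
`(a, a + (b-a)/2^j)`, so bands map onto the conventional EEG rhythms
(δ, θ, α, β, γ). The deepest useful level for a wavelet with filter length
`F` is `L = floor(log2(N / (F - 1)))`.

Each band contributes up to nine statistics — Max, Min, Mean, STD, skewness,
kurtosis, Energy (Σc²), nSTD (STD/(Max−Min)) and nEnergy (Energy/n) — and the
selected (band × feature) values form the segment's feature vector, which an
RBF-kernel SVM classifies as seizure or non-seizure.

Two exhaustive search blocks find the settings:

1. **Wavelet-Level Selection** — for each of 54 catalog wavelets (15 bior,
   5 coif, 10 db, 15 rbio, 7 sym, dmey, haar) and every level `1..L`, build
   feature vectors from *all* bands and *all* nine features, run
   cross-validation (leave-one-subject-out, or stratified k-fold when
   subjects are not annotated), and keep the best (wavelet, level) per
   family.
2. **Band-Feature Selection** — for a chosen wavelet/level, score every
   non-empty pair of band and feature subsets:
   `(2^(j+1) − 1) · (2^m − 1)` combinations (130,305 for `j = 7`, `m = 9`).
   The winner maximizes accuracy, with ties broken toward the smaller
   dimension. The reported *dimensionality reduction*,
   `100 · (1 − n_bands·n_features / ((j+1)·9))` %, measures how much of the
   full representation the winner discards.

Both searches reuse fixed cross-validation folds so every setting is scored
on identical splits, and the DWT is computed once per segment and sliced by
the subset enumeration.

## Worked example

Simulate a small multi-subject study (pink-noise background, a gain-3 power
elevation in 2–5 Hz during seizures), then run both selection blocks:

```r
library(dwtselect)

cfg  <- synthetic_config(n_subjects = 4, segments_per_class = 10, seed = 42)
segs <- generate_dataset(cfg)           # 80 labeled 20 s segments at 256 Hz

wl <- wavelet_level_search(segs, wavelets = c("haar", "db4", "sym5"),
                           scheme = cv_scheme("loso"), max_level = 4)
wl
#> <wavelet_level_result> 12 (wavelet, level) settings on 80 segments (loso CV)
#> Best per family:
#>  family wavelet level accuracy
#>      db     db4     1   0.9375
#>    haar    haar     4   0.9750
#>     sym    sym5     3   0.8750

bf <- band_feature_search(segs, "sym5", 3,
                          candidate_features = c("STD", "Energy", "kurtosis"))
bf
#> <band_feature_result> sym5 level 3: 105 combinations scored
#>   best: bands {2,4} x features {STD} (dimension 2)
#>   accuracy 0.9625, dimensionality reduction 94.44%
```

Every (wavelet, level) pair separates the classes well above chance; the
subset search then compresses the representation from 36 values
(4 bands × 9 features) to 2 while *raising* the pooled leave-one-subject-out
accuracy — band 4 is the approximation band holding the planted 2–5 Hz
rhythm:

```r
band_table(decompose(segs[[1]], "sym5", 3))
#>   band_index          kind freq_lo  freq_hi n_coefficients            rhythms
#> 1          1        detail 64.2500 128.0000           2564              gamma
#> 2          2        detail 32.3750  64.2500           1286              gamma
#> 3          3        detail 16.4375  32.3750            647         beta,gamma
#> 4          4 approximation  0.5000  16.4375            647 delta,theta,alpha,beta
```

Real data enter through `read_edf_record()` + `segment_record()` +
`balance_classes()` (EDF recordings with seizure-interval annotations) or
`read_ubonn_segment()` (single-column text segments). A command-line
front-end with `simulate` / `select` / `report` subcommands is installed as
`exec/dwtselect`.

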