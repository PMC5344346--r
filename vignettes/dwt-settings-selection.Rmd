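---
title: "Selecting DWT settings for seizure detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting DWT settings for seizure detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwtselect)
```

## The model

`dwtselect` treats seizure detection as binary classification of fixed-length
single-channel EEG windows. Each window is decomposed with a multilevel
discrete wavelet transform; per-band coefficient statistics form the feature
vector; an RBF-kernel support vector machine separates seizure from
non-seizure. The package's contribution is not the classifier but the
*search over the transform's settings*: mother wavelet, decomposition level,
band subset and feature subset are all scored by pooled cross-validated
accuracy, on identical folds, and the lowest-dimensional of equally accurate
settings wins.

The method's central assumptions are that (i) ictal activity manifests as a
change in the distribution of wavelet coefficients in *some* frequency
bands, (ii) the informative bands and statistics differ between recording
setups, which is why they must be searched rather than fixed, and (iii)
accuracy estimated by subject-aware cross-validation is a fair ranking
criterion for settings.

## The wavelet machinery

**Catalog.** 54 mother wavelets: bior1.1–bior6.8 (15), coif1–5, db1–10,
rbio1.1–rbio6.8 (15), sym2–8, dmey and haar. Filter coefficients ship with
the package as a plain-text table; reconstruction filters are derived from
the quadrature-mirror relations `rec_lo[n] = (-1)^(n+1) dec_hi[n]`,
`rec_hi[n] = (-1)^n dec_lo[n]`.

**The discrete Meyer filter.** `dmey` is a 102-tap FIR approximation of the
Meyer conjugate mirror filter, built for this package by frequency-sampling
the Meyer low-pass response and then refining all taps so the double-shift
orthonormality conditions hold to machine precision (a Gauss–Newton solve of
the 51 orthogonality equations in 102 unknowns, started from the
linear-phase frequency-sampled filter; see `data-raw/make_filters.py`). A
popular shorter 62-tap variant was rejected because its taps are materially
non-orthonormal (‖h‖² ≈ 1.0045), which caps multilevel reconstruction
accuracy at the percent level; the filter used here reconstructs to ~1e-13
relative error at five levels, and its length F = 102 gives the expected
maximum level of 5 on a 5120-sample segment.

**Decomposition.** The Mallat pyramid with *symmetric half-point* boundary
extension (each end mirrored including the edge sample, repeating the
reflection when the pad exceeds the remaining signal). One analysis step
keeps ⌊(N+F−1)/2⌋ coefficients per branch; synthesis trims F−2 leading
samples and cuts to the recorded input length of that level, which inverts
the analysis exactly for every catalog wavelet. These conventions match the
common pyramid-algorithm implementations, so coefficients are directly
comparable across tools; the test suite pins a set of single-step
coefficients against an independently computed reference.

**Maximum level.** `max_decomposition_level(n, f) = floor(log2(n / (f−1)))`.
A frequently printed variant adds 1 to this bound, but that convention
leaves fewer coefficients than filter taps in the deepest band; the floor
rule is the one under which the deepest band remains meaningful, and it
reproduces the expected levels for all catalog wavelets at both standard
segment lengths used in the tests (5120 and 4097 samples).

**Band bookkeeping.** Band index = detail level, so band 1 is the
*highest*-frequency band and band j+1 the approximation. The source range
defaults to (0.5 Hz, Nyquist): 0.5 Hz because the standard preprocessing
high-passes there. Rhythm overlap uses the conventional open ranges δ(0–4),
θ(4–7), α(8–15), β(16–31), γ(>31 Hz); as printed these leave 7–8 Hz and
15–16 Hz unassigned, and the package reports overlaps literally rather than
inventing a smoothing.

## Features

Nine statistics per band, in fixed order: Max, Min, Mean, STD, skewness,
kurtosis, Energy, nSTD, nEnergy. Conventions the definitions leave open were
fixed to mirror the defaults of the numerical environment this style of
analysis is usually run in, and are part of the package contract:

* STD is the sample standard deviation (n−1 denominator);
* skewness and kurtosis are standardized central moments with the
  population (n) denominator, kurtosis *not* excess-corrected (a normal
  sample gives ≈ 3);
* Energy is Σc²; nSTD is STD/(Max−Min); nEnergy is Energy/n, reading the
  "size of the band" as its coefficient count — the quantity actually
  available per band — rather than its bandwidth in Hz;
* features are computed on raw coefficients, not absolute values (under
  absolute values Max/Min would be largely redundant with Energy);
* degenerate bands (constant, or a single coefficient) yield 0 for the
  moment and ratio features instead of NaN, so an exhaustive search never
  aborts on a pathological subset.

Feature vectors are laid out bands-major (`b2_Min, b2_STD, …, b3_Min, …`),
and every position is named, so subset slicing is auditable.

## Classification and cross-validation

The SVM hyperparameters are deliberately plain and exposed in
`classifier_config()`: cost 1.0, kernel width γ = 1/dimension unless set,
features standardized to zero mean / unit variance with statistics learned
on the training fold only. Reported accuracies depend on these choices,
which is exactly why they are explicit configuration rather than buried
defaults.

Two schemes are provided. *Leave-one-subject-out* holds out all segments of
one subject per fold — no subject appears on both sides of a fold, so the
estimate reflects generalization to new individuals. *Stratified k-fold*
(default k = 10) is for corpora without subject annotations; folds preserve
the class ratio to within one segment, degrading to a plain shuffle with a
warning when a class has fewer than k members. Folds are built once per
search and reused across all settings so that ranking differences are not
fold noise. Predictions are pooled over folds into a single confusion matrix
(micro-averaging), from which accuracy, sensitivity, specificity, PPV and
NPV follow; a rate with a zero denominator is NA rather than an invented 0
or 1. Seizure is the positive class throughout.

Tie-breaking is deterministic everywhere: among equally accurate settings
the search prefers lower level, then shorter filter, then name
(Wavelet-Level stage), and smaller dimension, then lexicographic subsets
(Band-Feature stage) — always toward the computationally cheaper choice.
When the threshold-based family rule (`pick_family_best_threshold`, default
0.95 accuracy, then lowest level, then fewest vanishing moments) finds no
qualifying entry, it falls back to the maximal-accuracy rule and says so;
the discrete Meyer wavelet, whose underlying wavelet has no finite
vanishing-moment count, sorts last in that preference.

## Preprocessing choices

The high-pass preprocessing is a linear-phase FIR design (Hamming window) of
order 48 with a 0.5 Hz cutoff, applied single-pass and causally (zero
initial conditions), so results are reproducible sample for sample; the
start-up transient is `order` samples and the group delay `order/2` samples.
One property of this design is worth stating plainly: at 256 Hz a 49-tap
filter's transition band is far wider than 0.5 Hz, so the response at 0 Hz
is ≈ 0.92 — the filter *tilts* the lowest frequencies rather than removing
DC outright. The test suite asserts the implemented filter matches its own
designed frequency response (and that a much longer filter at the same
cutoff does drive DC toward zero), rather than pretending the short design
has a stopband it cannot have. Users who need stronger drift removal should
raise `order`.

Windowing labels a segment *seizure* only when it lies entirely inside an
annotated interval and *non-seizure* only when it overlaps no interval;
windows straddling a boundary are discarded. Annotated intervals are
half-open `[start, end)` seconds, merged when overlapping. Per-subject class
balancing subsamples the majority class uniformly with an explicit seed.
Multi-channel records are windowed per channel, each channel window becoming
an independent labeled segment.

## The synthetic generator

`generate_dataset()` emulates a multi-subject labeled corpus: non-seizure
segments are 1/f^β Gaussian noise (β = 1 by default — the canonical
broadband slope of resting EEG); seizure segments add, per configured effect
band, a random-phase band-limited component whose RMS is `gain` times the
background RMS inside that band. A per-subject log-normal gain
(`subject_gain_sd = 0.3`) makes effect strength vary across subjects, so
leave-one-subject-out is genuinely harder than pooled k-fold — the same
reason subject-aware validation matters on real data. Defaults (6 subjects,
20 segments per class each, 20 s windows at 256 Hz, one gain-3 effect in
2–5 Hz) describe a small but realistic planted-effect study: a gain of 3
multiplies in-band power by 10, comparable to the rhythmic power elevation
of an unmistakable ictal discharge.

Two deliberate design points. First, synthesized segments are scaled by the
*theoretical* RMS of their spectral envelope, not the realized sample SD —
normalizing each segment empirically would make background amplitude an
artificial constant and hand any classifier a spurious cue. Second, seizure
morphology is modeled purely as band-limited power elevation: there are no
spike-wave complexes, no evolving frequency, no artifacts (eye blink, EMG),
no channel correlation. Passing tests on this generator therefore shows the
*pipeline machinery* recovers planted spectral structure and stays at chance
under a null; it does not certify accuracy on clinical EEG, where
morphology, artifacts and non-stationarity matter.

The generator is a pure function of its config (including the seed) and
restores the caller's RNG state.

## Problem sizes in the shipped tests

The test suite runs the full machinery at sizes chosen to exercise every
code path while staying desk-scale: the planted-band recovery study uses the
generator defaults (6 subjects × 40 segments of 5120 samples) over 20 seeds
with a restricted candidate grid (four bands × two features), the
level-discrimination study uses 5 subjects × 20 segments of 1024 samples
over 10 seeds, and the exhaustive-search tests enumerate up to
`count_combinations(2, 9)` subsets on 36-segment corpora. Reconstruction,
tiling, feature-law and confusion-identity properties run over the complete
54-wavelet catalog and hundreds of random configurations.

## Known limitations

* The exhaustive Band-Feature stage is exponential by design
  (`(2^(j+1)−1)(2^m−1)` cross-validation runs); at `j = 7, m = 9` that is
  130,305 CV runs, feasible but slow in plain R. Restricting candidates —
  e.g. to bands covering the rhythms a pathology implicates — is the
  intended speed lever; no greedy shortcut is offered because approximating
  the search would change what the result *means*.
* The EDF reader supports the standard continuous 16-bit layout with one
  sampling rate across signals; EDF+ annotations and discontinuous records
  are out of scope (annotations are supplied as a CSV).
* Only the nine catalog statistics are implemented — no entropy,
  line-length or Hjorth features — and no continuous wavelet transform or
  wavelet-packet decomposition.
* Accuracy estimates from small synthetic corpora carry binomial noise of
  several percentage points; the tests therefore assert bands and paired
  comparisons, not point values.
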