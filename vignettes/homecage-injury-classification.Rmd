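---
title: "Classifying brain-injury state from home-cage behaviour: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying brain-injury state from home-cage behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcaclassify)
```

## The problem

Home-cage automated (HCA) monitoring records the behaviour of group-housed
mice continuously and non-invasively through an RFID baseplate under the
cage. In a controlled cortical impact (CCI) model of traumatic brain injury,
the interesting question is whether the injury state of an animal — naive,
brain-injured (TBI), or sham (craniotomy-only control) — can be read off
these behavioural traces alone. `hcaclassify` implements that classification
pipeline end to end: four behavioural channels sampled every 15 minutes over
72-hour weekly sessions are cut into bins, featurised two ways (per-bin
channel means for shallow classifiers; full within-bin sequences plus their
wavelet scaleograms for a dual-branch deep network), and evaluated with
leakage-safe leave-one-out cross-validation (LOOCV).

The four channels, in the package's fixed order, are distance travelled
(mm), body temperature (°C), separation from cage-mates (mm) and grid
transitions (a count over the 12 RFID grid sections). The class map is fixed
throughout: naive → 0, injured → 1, sham → 2.

## The synthetic cohort generator

The real recordings are not redistributable with the package, so every
stage is exercised against a seeded synthetic cohort whose statistical
structure mirrors a typical CCI monitoring design: 4 naive animals recorded for one
baseline week, 6 injured and 6 sham animals recorded for 5 post-intervention
weeks, 290 samples per animal-week on a 15-minute grid.

Each channel is a single-harmonic cosinor
$$x(t) = M + A\cos\!\big(2\pi (t - \phi)/\tau\big) + \varepsilon,$$
with mesor $M$, amplitude $A$, acrophase $\phi$, period $\tau = 1440$ min
and Gaussian noise $\varepsilon$. A one-cosinor model is the simplest
generator that reproduces the day/night structure of real traces; the
transition channel is drawn as a Poisson count with circadian-modulated
rate, because it is a count. Distance and separation are clipped at zero
after noise; temperature is left unclipped and stays within a physiological
band by parameter choice.

Injury enters as multiplicative factors on amplitude and mesor per group,
week and channel. The defaults encode a severe week-1 deficit with monotone
recovery: injured amplitude factors (0.30, 0.45, 0.60, 0.75, 0.90) across
weeks 1–5 and activity-channel mesor factors (0.50, 0.65, 0.80, 0.90,
0.95); sham animals show a milder, faster-recovering deficit (amplitude
0.70 → 1, mesor 0.90 → 1). Body temperature keeps its physiological mesor
(a ~0.4 °C week-1 dip only): a multiplicative 0.5 on a 36.5 °C mesor would
be biologically meaningless. Noise defaults are roughly 10% of each
activity channel's mesor (distance 200 mm, separation 15 mm) and 0.25 °C
for temperature.

What the generator deliberately does *not* emulate: ultradian rhythms and
bout structure within the circadian envelope, inter-animal interaction
dynamics beyond a separation channel, inter-individual variability in
baseline parameters, missing intervals, and analgesia effects. Passing
tests on this cohort therefore demonstrate that the pipeline's mechanics
(featurisation, leakage control, training, scoring) are correct and that
the models can exploit a planted circadian deficit; they say nothing about
accuracy on real recordings, whose class structure is far less separable.

Generation order is fixed and all randomness flows through one seed, so
equal configurations produce bitwise-identical cohorts.

## Binning and featurisation

Each animal-week record is split into `n_bins` (default 6; any value
between 1 and 20 is supported for bin-count sweeps) contiguous,
non-overlapping segments covering all samples in order. When the length is
not divisible by `n_bins` the remainder goes one sample each to the
earliest bins, so 290 points yield segment lengths (49, 49, 48, 48, 48,
48). The bin is the classification unit and inherits its animal's class.

* Record features: the arithmetic mean of each channel over the bin — a
  4-vector per observation, consumed by the SVM, random forest and FFNN.
* Sequence features: the full within-bin time course, zero-padded at the
  tail to `target_len` = 48; segments longer than 48 are truncated at the
  tail (the minimal reading of padding-to-48 given that 290/6 ≈ 48.3). A
  mask records real versus padded positions.

Standardisation is always fitted on training data only. For sequences the
per-channel moments are pooled over *unpadded* positions only, and padded
positions are re-zeroed after scaling, so padding never contaminates the
statistics and stays exactly zero.

Class imbalance is handled two complementary ways: balanced class
weights $w_c = N/(K\,n_c)$ used as loss multipliers (so
$\sum_c n_c w_c = N$), and SMOTE oversampling for the record-style datasets
only — each synthetic point is $x_i + u\,(x_j - x_i)$ with $u \sim U(0,1)$
and $x_j$ one of the $k = 5$ nearest same-class neighbours. SMOTE is never
applied to sequence data and never inside the headline LOOCV comparison;
when enabled for a shallow model it runs strictly inside each training
fold.

## Scaleograms

The deep model's second branch views each standardised sequence as an
image: the continuous wavelet transform magnitude across scales and time,
channel-stacked into one multi-channel image. The mother wavelet is the
analytic Morlet with centre frequency 6 (a Ricker wavelet is available);
the transform is computed exactly as a dense kernel-matrix product, so it
is deterministic, linear, zero-preserving and absolutely homogeneous —
properties the tests assert directly against a time-domain oracle.

The default scale grid is 1–8 in unit steps. At sequence length 48 a
Morlet at scale $a$ has effective support of about $6a$ samples, so scales
above $\sim L/6 = 8$ produce coefficients dominated by the window
boundaries rather than signal structure; capping the grid there also keeps
the image branch compact. The grid is configurable, and predictions on the
synthetic cohort were verified to be unchanged under the wider 1–16 grid.
Scaleograms are recomputed per LOOCV fold, after per-fold standardisation,
so the image branch cannot leak held-out information.

## The classifiers

**Dual-branch deep network.** The raw-sequence branch applies two 1-D
convolutional blocks — convolution ('same' padding, stride 1), batch
normalisation, ReLU, max-pooling with pool size 2, in that order — and
feeds the resulting 12-step, 64-channel sequence into an LSTM whose final
hidden state summarises the bin. The scaleogram branch applies two
analogous 2-D convolutional blocks and flattens. The branch outputs are
concatenated, passed through a dense layer, dropout, and a 3-way softmax.
L2 weight decay is attached to the convolutional, LSTM and dense kernels.
Training minimises class-weighted sparse categorical crossentropy with
Adam.

The network is implemented in the package itself as batched matrix algebra
(im2col convolutions over BLAS, BPTT through the LSTM) with compiled inner
kernels for the memory-bound elementwise steps. Two small architectural
conventions are worth noting: convolutions that feed a batch-norm layer are
built without bias (BN's centring makes a conv bias an exact no-op), and
max-pool ties break toward the earlier time step or cell, making forward
passes fully deterministic.

Defaults (all configurable; filter counts and widths of this kind are
conventionally tuned heuristically, and these are simply the package's
documented choices): conv-1D filters
(32, 64) with kernel 3; LSTM width 64; conv-2D filters (16, 32) with 3×3
kernels; dense width 64; dropout 0.3; L2 1e-3; Adam learning rate 1e-3;
batch size 64 (chosen for single-CPU throughput of the BLAS-backed loop);
100 epochs by default, with evaluation harnesses free to train shorter.
Batch-norm uses $\epsilon$ = 1e-3 and running-statistic momentum 0.9 — the
faster momentum keeps inference statistics usable after short trainings.
Weights are Glorot-uniform initialised; the LSTM forget-gate bias starts
at 1. Identical spec seeds give identical initial weights and, in this
single-threaded implementation, identical training trajectories.

**Feed-forward network.** Dense(32) → BN → ReLU → Dense(32) → BN → ReLU →
Dense(3, softmax) on the 4 standardised per-bin means, trained with the
same loss.

**Shallow baselines.** The SVM is libsvm's C-classification (via e1071):
one-vs-one multi-class scheme — 3 pairwise classifiers for 3 classes — with
the default cost C = 1 and the library-default RBF kernel, class weights
supported. The random forest is a ranger probability forest with maximum
tree depth 4 and 100 trees; class weights enter as case weights.

## Evaluation

LOOCV retrains the model once per observation. Everything that could leak
is redone inside each fold: standardiser fitted on the N−1 training rows,
class weights recomputed from the training labels, scaleograms rebuilt from
the per-fold standardised sequences. A fold whose training set loses a
class entirely is reported invalid rather than silently skipped. For
expensive models a label-stratified, seeded `max_folds` subsample can be
evaluated instead of all N — each selected fold still trains on all N−1
remaining observations.

Metrics: per-class precision TP/(TP+FP), recall TP/(TP+FN), F1 =
2PR/(P+R), with 0/0 defined as 0 (the natural value for a never-predicted
class). Macro values are unweighted means over classes — macro-F1 is the
mean of per-class F1 scores, *not* the harmonic mean of macro precision and
recall; support-weighted variants are reported alongside. Softmax argmax
ties break toward the lowest class index. The two-component PCA view of the
record features is mean-centred, unscaled, with each component's sign fixed
so its largest-magnitude loading is positive.

## Problem sizes used by the test suite and acceptance script

The packaged checks run at desk scale, as a deliberate package choice: the
default synthetic cohort (64 animal-weeks → 384 binned observations), 90
stratified LOOCV folds, and 15 training epochs for the neural models.
Under these conditions the deep network reaches roughly 0.8 LOOCV accuracy
and every model clears 0.4 against a majority-class rate of about 0.47;
naive observations are the hardest class — they are systematically absorbed
into sham, exactly the confusion pattern expected when recovered sham
animals are statistically indistinguishable from uninjured ones.

## Known limitations

* The cosinor cohort is intentionally idealised; accuracies on it are not
  comparable to accuracies on real HCA exports.
* The SVM branch emits hard labels only (no probability calibration).
* NN training determinism is guaranteed for a fixed BLAS in single-threaded
  execution; across different BLAS builds results reproduce statistically
  rather than bitwise.
* No hyperparameter search is provided; defaults are documented choices.
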