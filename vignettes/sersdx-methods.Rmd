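---
title: "Spectral diagnostics of serum exosomes with sersdx: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral diagnostics of serum exosomes with sersdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersdx)
```

## The problem

Label-free surface-enhanced Raman spectroscopy (SERS) of serum exosomes
produces, for every serum sample, a bundle of spectra (hundreds per
sample), each an intensity vector on a shared Raman-shift axis in
cm^-1^. Because any single spectrum probes a random subset of captured
exosomes, diagnosis is a two-level problem: classify individual spectra,
then aggregate spectrum-level class probabilities into one per-sample
call. `sersdx` implements that pipeline end to end -- simulation,
preprocessing, a hybrid CNN + stacked-MLP classifier under grouped
cross-validation, sample-level evaluation, and an interpretability layer
built around three anchor bands: 1080 cm^-1^ (attributed in the liquid-biopsy
literature to deoxyadenosine triphosphate, elevated in cancer),
1380 cm^-1^ (phosphatidylserine, reduced in cancer), and the stable
643 cm^-1^ band used as an internal reference.

## The synthetic cohort generator

No public spectra archive accompanies the serum-exosome studies this
package is designed around, so the generator is a first-class module: it
defines the study conditions under which every downstream stage is
tested. A cohort plan fixes class signatures, samples per class, spectra
per sample, the wavenumber grid, a noise model and one master seed.

**Spectral model.** Each class is a sum of Gaussian bands (Lorentzian
optional). All classes share ten serum-like base bands -- including
phenylalanine ring breathing near 1004 cm^-1^, CH~2~ deformation near
1450 cm^-1^ and amide I near 1655 cm^-1^ (the strongest band, amplitude
1 a.u.) -- with the 643 cm^-1^ reference band planted at an identical
amplitude in every class, which the plan constructor enforces. Every
cancer class carries the pan-cancer effect direction: the 1080 cm^-1^
amplitude offset is positive and the 1380 cm^-1^ offset negative; the
constructors refuse signatures that violate this. Default effect sizes
are +0.15 and -0.10 a.u. (15% and 10% of the strongest band). These are
synthetic calibrations, not estimates of any real effect: they are
chosen so that a desk-scale cohort is separable but not trivially so
(additive noise SD 0.03 gives single-channel signal-to-noise of ~5, but
baseline drift and amplitude jitter make single-channel rules
unreliable, so the classifier must integrate over the axis).

**Axis.** 400-1800 cm^-1^ at 1 cm^-1^ (1401 channels) by default --
instrument ranges for the relevant spectrometers are rarely printed, so
this is an explicit stand-in covering all discussed bands; any uniform
axis covering the three anchors is accepted.

**Artifacts.** Four stochastic layers emulate what the preprocessing
chain is meant to remove:

* a random quadratic baseline `c0 + c1 t + c2 t^2` (t in [0,1]) with
  coefficient ranges chosen to keep the baseline nonnegative across the
  axis (c0 in [0.1, 0.4], c1 and c2 in [-0.05, 0.3]); a baseline that
  dips below zero would interact with the final clip-at-zero and create
  exactly flat runs no real fluorescence background produces;
* additive Gaussian noise (SD 0.03 a.u.);
* cosmic-ray spikes: a Poisson count per spectrum (default rate 0.1),
  one channel wide, uniform over interior channels, amplitude uniform in
  [2, 5] a.u. -- the model requires the minimum spike height to exceed
  10x the additive noise SD so that ground truth is unambiguous at test
  time;
* a lognormal per-spectrum global amplitude jitter (CV 10%, mean 1)
  modelling exosome-sampling heterogeneity -- the reason per-sample
  bundles of many spectra are collected, and the reason min-max
  normalization is consequential.

Ground truth (spike channels, jitter, planted deltas) is recorded per
spectrum, so despiking can be scored as a detector and interpretability
outputs can be compared against what was planted.

**What the generator does not emulate.** Real SERS spectra have
correlated (pink-ish) noise, substrate-to-substrate enhancement
variation, wavenumber calibration drift, band-shape changes with
chemical environment, and biological heterogeneity far richer than a
global amplitude jitter plus fixed band offsets. Passing tests on this
generator therefore demonstrate that the pipeline's machinery is correct
and well calibrated -- not that any particular accuracy would transfer
to patient serum.

## Preprocessing

The chain is despike -> baseline -> smooth -> min-max, each step
individually callable. The order is configurable; despiking is run first
by default so spikes cannot distort the baseline fit.

**Cosmic-ray removal.** A channel is flagged when the modified z-score
of the spectrum's second difference exceeds 8. The score is centred on a
rolling median (window 21 channels) and scaled by the larger of the
rolling MAD and the spectrum-wide MAD of the second differences. Both
terms matter: the global term stabilizes the scale where a small-window
MAD would have heavy tails in noise (pure rolling scaling produced
false-positive rates of roughly one channel per two spectra at these
noise levels), while the local term keeps genuinely sharp bands -- which
have locally high curvature -- from being flagged in near-noiseless
spectra. Window 21 also matters for recall: with an 11-channel window,
two spikes three channels apart put six contaminated values into one
window, exceeding the MAD's 50% breakdown point so that both spikes hide
each other. Channels are repaired one at a time, worst first, by linear
interpolation between the nearest clean neighbours, and the curvature is
re-examined after each repair; this one-at-a-time scheme is why spike
shoulders are not flagged. The edge channels have no curvature estimate
and are never flagged. A spectrum whose channels would all be flagged is
a declared error.

**Baseline.** Asymmetric least squares (second-difference penalty
lambda = 1e5, asymmetry p = 0.01, 10 reweighting iterations), the
de-facto Raman default: points above the running estimate get weight p,
points below 1 - p, so the estimate hugs the band-free floor. The normal
equations form a pentadiagonal SPD system solved by banded Cholesky in
O(channels) per iteration. Negative residuals are retained -- clipping
would bias downstream ratio features. The fitted baseline is exposed for
inspection on single spectra.

**Smoothing.** Discrete Gaussian convolution, sigma = 2 channels, kernel
truncated at 4 sigma and renormalized to unit sum, reflect boundary
handling (edge element included). Sigma 2 preserves ~10 cm^-1^ FWHM
bands on the default axis.

**Normalization.** Per-spectrum min-max to [0, 1] -- per spectrum, not
per cohort, because spectra are normalized individually for the
classifier and because the per-spectrum amplitude jitter is exactly what
this step is meant to absorb. A constant spectrum maps to zeros with a
warning. For peak-ratio analyses the normalization step should be
omitted (`steps = c("despike", "baseline", "smooth")`): a ratio of two
channels of one spectrum is already scale-free, and min-max would
distort it.

## The classifier

**Spectrum-level CNN.** One 1D convolution (64 filters, kernel 3,
stride 1, valid padding) -> leaky ReLU -> dropout (rate 0.25) ->
max-pooling (size 2, stride 2) -> flatten -> one dense leaky-ReLU layer
-> softmax (slope 0.01; see below for why the slope is not zero). On the
default 1401-channel axis the shapes are 1399 x 64 after convolution,
699 x 64 after pooling, 44736 after flatten (`build_cnn()` prints the
exact report for any input length). The convolution/pooling geometry,
the 50-epoch / batch-64 schedule and the plateau patience of 5 are the
reference architecture; where the architecture is not pinned down the
package makes its own choices: the dense bottleneck is 16 units wide by
default -- against a 44736-dimensional flatten, the bottleneck width
sets much of the computational cost of training, and at the shipped
problem sizes the cross-validated tasks converge identically at widths
16, 24 and 32, so the narrowest of those keeps a full grouped five-fold
run on a plain single-CPU machine in the minutes range (configurable
when richer contrasts demand more capacity);
dropout 0.25; Adam (lr 3e-4) with cross-entropy -- against the
44736-dimensional flatten, a 1e-3 rate interacting with aggressive
pre-pool dropout intermittently drives training into the
uniform-prediction attractor (all-dead ReLUs) within the first epoch,
while 3e-4 trains stably across folds and seeds; reduce-on-plateau
halves the rate after 5 epochs without validation-loss improvement
(1e-5 absolute tolerance); gradients are clipped to global norm 1 --
with a nonnegative 44736-dimensional flatten, first-epoch Adam steps are
sign-aligned across huge fan-ins and can swing logits hard enough to
park training in the uniform-prediction basin, which clipping prevents. Optional inverse-frequency class weights
handle imbalanced cohorts; they are off by default because the synthetic
presets are balanced.

The trainer is written in RcppArmadillo (single precision; the dense
stack on BLAS GEMM, the convolution front end as fused kernels).
Convolution biases are initialized at a small positive value (0.05):
preprocessed spectra are nonnegative, so a zero-bias He initialization
starts roughly half the ReLU units dead and occasionally lets training
fall into an all-dead uniform-prediction attractor; the offset is the
standard mitigation. All
randomness -- initialization, batch shuffling, dropout -- derives from
one integer seed through counter-based generators, so a fit is
bit-reproducible on one machine.

**Grouped cross-validation.** Folds are assigned to samples, never to
spectra: all spectra of a serum sample stay in one fold, because
spectrum-level splitting would leak sample identity and inflate
accuracy. Assignment is stratified by class (round-robin after a seeded
shuffle, so per-fold class counts are within one sample of the target),
and `cross_validate()` verifies the empty train/validation sample
intersection in every fold.

**Stacked refiner.** The CNN's class probabilities are refined by an MLP
(n_classes -> 64 -> 64 -> n_classes, ReLU hidden, softmax output). How
such a refiner can be trained without leaking is a real design question:
a refiner trained on probabilities a CNN produced for its own training
spectra would learn from overconfident inputs. The package implements
stacked generalization: only out-of-fold CNN probabilities are
admissible as refiner training data (enforced -- unmarked inputs raise
an "in-fold leakage" error). One refiner is trained on the pooled
out-of-fold probabilities of all folds; training per-fold refiners on
the other folds' probabilities was tried and rejected, because each
fold's CNN has idiosyncratic calibration, and a refiner fitted to other
CNNs' outputs systematically mis-maps the one it is applied to. The
refiner has its own schedule (300 epochs at lr 1e-3, a 20% held-out
slice of its training rows, and best-validation-loss weight restore):
its inputs are tiny probability vectors so convergence costs seconds,
and the early stop keeps it calibrated -- a refiner driven to
cross-entropy saturation would replace soft sample-level averaging with
a hard majority vote and lose graded evidence on borderline samples.

**Sample-level diagnosis.** The diagnostic vector of a sample is the
unweighted arithmetic mean of its spectra's refined probabilities. The
call is the argmax with a deterministic lowest-index tie-break; for the
binary tasks a configurable threshold (default 0.5) on the mean
cancer probability is used instead -- no decision threshold is ever
stated for the reference workflow, so 0.5 is the neutral choice.

**Evaluation.** Integer confusion matrix, accuracy, one-vs-rest
sensitivity and specificity per class, and ROC by threshold sweep over
the sample-level mean probabilities with trapezoidal AUC; multiclass AUC
is macro-averaged over one-vs-rest curves (per-class curves are shown in
the field without a stated averaging convention; macro is the neutral
default for balanced synthetic cohorts).

## Interpretability

**Feature importance.** "Weight-based" importance is not an algorithm
until one makes it one. The default method is input-gradient saliency:
the mean absolute gradient of the winning logit with respect to the
input, averaged over a representative spectra set, projected to channels
and normalized to percent. It is model-faithful and
architecture-agnostic. The literal first-layer alternative
(`method = "weights"`) propagates squared dense-layer weights back
through the pooling map onto convolution positions and combines them
with squared kernel weights per input channel. Both profiles sum to
100%; band scores sum channel percents in a +/-10 cm^-1^ window around a
named center (band-level percentages are conventionally reported without
a window definition; +/-10 cm^-1^ matches the generator's band widths).
The printed real-data contributions of the 1080 and 1380 cm^-1^ bands
are model- and data-specific and are not reproduction targets here; what
is tested instead is planted-feature recovery: when only those two bands
differ between classes, they should rank first and second among
non-overlapping 21-channel bands in nearly every seeded training run.

**Differential spectra.** Channelwise mean class spectrum minus the mean
non-cancer spectrum, after preprocessing; exactly antisymmetric under
group swap, zero for identical groups, and carrying the planted signs
(positive at 1080, negative at 1380 cm^-1^) for every synthetic cancer
class at default effect sizes.

**Peak ratios.** Per-spectrum intensity at the channel nearest
1080 (or 1380) cm^-1^ divided by the channel nearest 643 cm^-1^,
computed on preprocessed but un-normalized intensities, compared between
groups with a Welch (unequal-variance) two-sample t-test -- the plain
"t-test" is underspecified, and Welch is the safer default under
per-group variance differences. Spectra with nonpositive reference
intensity are excluded with a message; if 5% or more are nonpositive the
reference band is declared absent and the test errors. Stars follow the
p < 0.05 / 0.01 / 0.001 / 0.0001 convention.

## Numerical and engineering choices

* Tie-breaks: argmax calls take the lowest class index; the pooling
  comparison prefers the even position on exact ties.
* The ALS solver works in double precision; network training in single
  precision (the heavy linear algebra), with the learning-rate schedule
  tracked in double so reported rates are exact.
* Degenerate inputs are defined, not accidental: constant spectra
  normalize to zeros with a warning; an all-flagged spectrum, a
  single-class training split, a class with fewer samples than folds,
  and an absent reference band are errors with explicit messages.
* Reproducibility: every public operation is deterministic given its
  seed; `run_experiment()` writes a manifest (seed, configuration hash,
  package version) and its `metrics.json` is byte-identical across
  reruns of the same configuration on one machine.

## Problem sizes

The shipped experiment presets are desk-scale by design: the binary
presence task uses 2 classes x 40 samples x 50 spectra and the 11-class
typing task 11 x 15 x 30, both under five-fold grouped cross-validation
-- large enough that grouped evaluation is meaningful (16 and 33
held-out samples per fold) and small enough that a complete run fits in
minutes on one CPU. Real cohorts (hundreds of samples, >= 200 spectra
each) are handled by the same code paths; only wall-clock time scales.

## Known limitations

* The generator's independence assumptions (iid noise, per-spectrum
  baselines) are optimistic; see the generator section for what passing
  tests do and do not show.
* The refiner can only help when the CNN's errors carry structure in
  probability space; on cohorts the CNN already classifies perfectly it
  is a no-op by construction, and the package only guarantees it does
  not hurt (paired, same folds and seed).
* Saliency is a local explanation; strongly correlated bands can share
  or swap attribution. The weight-projection method ignores data
  entirely and is included as the literal reading of weight-based
  importance, not as the recommended default.
* Only pool size 2 / stride 2 and convolution stride 1 are implemented
  -- the reference geometry; other values error rather than silently
  diverge from it.

## A worked example

```{r example, eval = FALSE}
plan <- binary_cohort_plan(samples_per_class = 12, spectra_per_sample = 20,
                           seed = 21)
cohort <- simulate_cohort(plan)
pp <- preprocess_pipeline(cohort)
cv <- cross_validate(pp, model_config(2, seed = 21), k = 5)
diagnoses <- aggregate_samples(cv, threshold = 0.5)
evaluate_diagnoses(diagnoses)

imp <- feature_importance(cv$models$cnn[[1]], pp$intensities,
                          grid = cohort$grid)
band_importance(imp)                       # percent at 1080 / 1380 cm^-1

raw <- preprocess_pipeline(cohort, steps = c("despike", "baseline",
                                             "smooth"))
peak_ratio_test(raw, 1080, 643)            # Welch t-test vs non_cancer
```
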