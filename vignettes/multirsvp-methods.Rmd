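---
title: "Multi-stream RSVP target detection: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stream RSVP target detection: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multirsvp)
```

## The problem

In a rapid serial visual presentation (RSVP) target-detection experiment,
images flash at a fixed location at several per second while EEG is
recorded. A rare target image elicits a P300 — a positive event-related
deflection peaking roughly 300–500 ms after onset, maximal over
centro-parietal electrodes — and a classifier turns each 1000 ms
stimulus-locked epoch into a scalar *interest score*. Single-trial P300
detection is noisy; presenting each image several times would allow
multi-trial averaging but would slow the stream down.

The multi-stream (dual/triple) RSVP paradigm solves this by showing two or
three copies of the same image sequence simultaneously at different screen
positions, each copy delayed by a fixed interval (750 ms between streams at
4 Hz, i.e. three frames). The observer watches the base (left) stream; on
spotting a target they shift their gaze to the next stream, view the same
target again when it reappears there, and then return. Each attended target
thus yields two or three P300s whose interest scores can be *fused*
(averaged per image), improving detection without slowing the stream.

This package implements the full chain — scheduling, a deterministic gaze
model, a synthetic EEG generator, preprocessing, two single-trial
classifiers (HDCA and SWLDA), score fusion with cross-validated ROC/AUC
evaluation, and the analytic target-miss model — so that every stage is
testable end-to-end without access to recorded EEG.

## Stimulus schedules and the gaze model

`generate_schedule()` builds a blocked base sequence (default 10 blocks of
200 images, 20 targets per block, 4 Hz) and replays it on the delayed
streams. Two structural constraints matter:

* **Delays are whole frames.** Stream delays must be integer multiples of
  the frame period; the defaults are 0 / 750 / 1500 ms = 0 / 3 / 6 frames.
* **Targets are separated.** Consecutive targets in the base sequence are
  at least `min_target_gap_frames` apart (default 6 for dual, 9 for
  triple). The gap is chosen to exceed the gaze-travel span so that the
  images skipped during an excursion are always nontargets.

Target placement is sampled uniformly among gap-feasible placements block
by block, conditioned on the previous block's last target, via the
bijection between gap-constrained subsets and unconstrained subsets of a
shortened index range. Plain rejection sampling is impractical here: at the
default density (20 targets in 200 frames, gap 9) the acceptance
probability of an unconstrained draw is vanishingly small, while the
bijection is exact and O(targets) per block.

`derive_gaze()` makes the attention protocol explicit. Attention starts on
the left stream. When an attended target appears at frame `t`, the
observer follows it: frames `t+1 … t+3` on the right stream (seeing the
target again at `t+3`), frames `t+4 … t+6` on the bottom stream for triple
schedules, then `refixation_frames` frames in transit attending nothing,
resuming on the left stream afterwards. A base image is *missed* when none
of its presentations falls on the stream the observer is attending.

With delay span `D` frames and refixation `r`, an isolated attended target
causes exactly `D + r` missed images: 5–6 for dual and 8–9 for triple
geometry with `r` = 2–3. We default `refixation_frames` to 2. This is the
one place where the protocol admits a genuine choice — the refixation time
is not measurable from the schedule itself — and `r = 2` is the value at
which the default gap constraints (6 and 9 frames) *strictly* guarantee
that no target is ever missed: with `r = 3` a follow-up target at exactly
the minimum gap would land on the last transit frame. The parameter is
exposed, and both values reproduce the documented 5–6 / 8–9 skip counts.

When excursions occur close together, a skipped image can still be caught
later: its delayed-stream presentation may fall inside a subsequent
excursion's attended window. `derive_gaze()` applies the definition ("no
presentation attended"), so such rescues are counted correctly rather than
assumed away.

## The synthetic EEG generator

`simulate_recording()` generates, per channel,

* background noise: a stationary AR(1) process with marginal SD
  `noise_sd_uV` (default 10 µV). The AR coefficient (default 0.95) is
  defined per sample *at the 2400 Hz acquisition reference rate* and
  adapted as `0.95^(2400/fs)` when simulating at another rate, so the
  autocorrelation time (≈ 8 ms) is a property of the simulated brain, not
  of the sampling grid;
* mains interference: a 50 Hz sinusoid (default 2 µV) so the acquisition
  notch stage has something to remove;
* evoked activity: for every target presentation that is attended under
  the gaze trace, a Gaussian-envelope bump (FWHM 200 ms) is added,
  projected on a fixed centro-parietal topography maximal at Pz.

The repetition structure carries the paradigm's key physiology: the default
template uses peak latency / amplitude of 300 ms / 6 µV for the first
viewing, 300 ms / 5.5 µV for the second and 400 ms / 4 µV for the third —
the third P300 is smaller and later because the observer anticipates the
reappearance. All of this is configurable through `erp_template()`.

Two conventions deserve a note:

* **Amplitude is the peak-channel amplitude.** The stored topography is a
  unit-Euclidean-norm shape vector; `amplitude_uV` is the deflection at
  the maximal channel (Pz), which is how ERP amplitudes are read off
  electrode traces. Spreading 6 µV across the vector norm instead would
  produce a ≈ 3.8 µV Pz P300 — visibly inconsistent with a "6 µV P300" —
  and an effectively unlearnable signal at the default noise level (even a
  matched filter given the true template stays below 0.88 AUC).
* **Unattended presentations add nothing.** A target the gaze model marks
  as missed contributes no evoked component on that stream; this is the
  premise that makes the miss-probability model meaningful.

What the generator does *not* emulate: ocular and muscle artifacts,
channel-to-channel noise correlation, 1/f spectral shape beyond AR(1),
latency jitter within a repetition, and amplitude habituation over the
session. Passing tests on this generator therefore demonstrate the
*pipeline's* correctness and the paradigm's statistical structure, not
performance on real recordings.

## Preprocessing

`preprocess()` chains the standard steps in a fixed order: band-pass
0.5–60 Hz, downsample to 600 Hz, extract 1000 ms post-stimulus epochs, and
baseline-correct. Numerical choices:

* the band-pass is a cascade of 4th-order Butterworth high- and low-pass
  sections, each applied forward–backward (zero phase). A single 8-pole
  band-pass polynomial with a 0.5 Hz edge at 2400 Hz is numerically
  unstable in transfer-function form — its output diverges on recordings
  longer than a few seconds — while the split sections are well
  conditioned;
* downsampling removes the per-channel mean, low-passes at 80% of the new
  Nyquist frequency (6th-order zero-phase Butterworth), restores the mean
  and keeps every n-th sample, so constants survive exactly;
* the baseline window defaults to the 200 ms immediately preceding onset,
  taken from the continuous recording; `"whole_epoch"` is available as an
  alternative since the original acquisition choice is not documented;
* epochs are *not* rejected for overlap. At 4 Hz with 1000 ms epochs,
  consecutive epochs share 75% of their samples by design; the same signal
  appears in several epochs and nontarget epochs adjacent to a target
  contain parts of its P300. This contamination is a property of the
  paradigm, and it induces correlation between the per-stream scores of
  the same image even where their sample windows are disjoint.

## HDCA

`hdca()` implements the two-layer hierarchical discriminant:

1. the 1000 ms epoch is cut into `K` windows of `T` = 25 ms (`N = T·fs`
   samples; at 600 Hz, `K` = 40 and `N` = 15). For window `k`, a spatial
   filter `w_k` maximises the Fisher criterion between target and
   nontarget per-window channel means, giving a window score
   `y_k = (1/N) Σ_n Σ_i w_ki · x_i[(k−1)N + n]`;
2. a logistic regression learns temporal weights `v_k`, and the interest
   score is `y_IS = Σ_k v_k y_k`.

Implementation choices, all on the estimation side:

* the pooled within-class covariance is shrunk toward a scaled identity
  with the Ledoit–Wolf analytic shrinkage intensity. With 16 channels and
  windows of 15 averaged samples the raw covariance can be
  ill-conditioned; shrinkage keeps the filters stable without a tuning
  parameter;
* window scores are z-scored with training-set statistics before the
  logistic layer, whose ridge penalty is a fixed 0.01 on the standardised
  scale (intercept unpenalised); the fit is deterministic
  (Newton/IRLS, no stochastic solver);
* spatial filters are oriented so targets score higher in every window;
* epoch lengths that do not divide into whole windows lose the final
  partial window with a warning.

## SWLDA

`build_feature_vectors()` reduces each channel to 60 points by
non-overlapping block means (a naive subsampling alternative is provided)
and concatenates channels: with the default 14-channel subset this yields
the canonical 840-point feature vector. The recording montage has 16
channels while the discriminant uses 14; which two are excluded is not
documented anywhere we can check, so the default drops the frontal-polar
pair Fp1/Fp2 — the channels most affected by ocular artifacts, and the
least informative for a centro-parietal component — and the subset is an
explicit argument.

`swlda()` regresses the 0/1 labels on the features by least squares with
forward entry (most significant candidate enters while `p < p_enter`,
default 0.10) followed after each entry by backward removal (any retained
feature with `p > p_remove`, default 0.15, leaves), until stable or
`max_features` (default 60) is reached. These control values follow the
long-standing P300-speller convention. Entry p-values use the partial-F
statistic computed by residualising candidates against the current model
(Frisch–Waugh), which makes each forward sweep a single matrix product;
ties break to the lowest feature index so fits are bit-for-bit
reproducible. The test suite pins the selection path to an independent,
naive `lm()`-refit oracle.

## Fusion and evaluation

`fuse_scores()` averages the interest scores of the same image over the
streams on which it was scored; an image missing from a stream (possible
under relaxed gap constraints) simply averages over the streams present.
`kfold_cv()` performs stratified 10-fold cross-validation *grouped by
image*: all stream presentations of an image share a fold, so the
held-out fold never leaks other-stream epochs of its images into training.
One classifier is fitted per fold on all training epochs, and the held-out
scores are fused at each level (left; left+right; left+right+bottom),
giving matched single/dual/triple AUCs. AUC is the Mann–Whitney rank
statistic with midranks, which equals the trapezoidal area under the
threshold-swept curve; a brute-force pairwise oracle pins it in tests.

`paired_wilcoxon()` provides the exact two-sided signed-rank test used for
paradigm comparisons. The exact null distribution is computed by integer
convolution over (doubled) midranks, which — unlike the standard
`wilcox.test()` — remains exact in the presence of tied absolute
differences; with eight all-positive differences the two-sided p-value is
exactly 2/2⁸ = 0.0078125.

Hard decisions, where needed, use a threshold halfway between the class
medians of the training scores (`midpoint_threshold()`); all headline
evaluation is threshold-free AUC.

### What fusion can and cannot gain here

With equal-strength repetitions every extra stream adds evidence and the
single < dual < triple ordering is essentially deterministic at the
default problem size (2000 images). With the default *attenuated, delayed*
third repetition, the triple-vs-dual increment collapses to approximately
zero in expectation while dual-vs-single stays clearly positive — the
diminishing-returns pattern that motivates stopping at three streams. Two
structural effects cap the gain: the per-stream scores of one image are
positively correlated (shared raw samples between overlapping epochs, and
shared proximity to contaminating neighbour targets), and the pooled
classifier is tuned to the dominant 300 ms latency rather than the third
repetition's 400 ms. The acceptance suite tests the ordering with uniform
repetitions and the increment collapse with the attenuated default.

## The target-miss model

While the gaze travels, `N` base images pass unattended; if each image is
a target independently with probability `p`, the probability that an
excursion misses at least one target is `P_miss = 1 − (1 − p)^N`
(`miss_probability()`). `simulate_miss_rate()` checks this by direct
Monte-Carlo, and `miss_curve()` tabulates it over a probability grid for
the dual/triple/quadruple geometries (`N` = 6, 9, 12 by default) — the
curve that makes explicit why the paradigm suits rare targets only.

`schedule_miss_rate()` runs the *actual* schedule and gaze model instead.
Under the default gap constraint it returns exactly 0 (the constraint is
designed so skipped images are nontargets). With the constraint relaxed
the empirical rate sits well *below* the analytic curve at the nominal
window (≈ 0.31 versus 0.41 at `p` = 0.1, dual): chained excursions rescue
tail-window images whose delayed copies fall into a later excursion's
attended window, and the fixed per-block target count adds negative
dependence. The analytic model is an idealised upper bound, and the test
suite validates the simulated dynamics against an independently coded
excursion simulation rather than against the bound.

## Problem sizes and reproducibility

Every stochastic element takes an explicit seed (schedules, recordings,
fold assignment, Monte-Carlo), and `run_pipeline()` reproduces all numeric
outputs bit-for-bit from a JSON-serialisable config. The test suite runs
the statistical checks at deliberately chosen sizes: the fusion-direction
check uses 20 simulated sessions of the full 2000-image triple paradigm at
600 Hz (the acquisition-rate path 2400 → 600 Hz is exercised separately on
shorter recordings); parameter recovery uses 20 sessions of 200 images at
5 µV noise; the null-calibration check uses 300 images with a
zero-amplitude template. The miss-model grid uses 10⁶ Monte-Carlo trials
per cell.

## Known limitations

* The synthetic generator's simplifications (above) mean synthetic AUC
  levels should not be read as predictions for real subjects; only
  structural and directional conclusions transfer.
* The gaze model is deterministic; attention lapses, blinks and variable
  refixation times are out of scope.
* The EDF writer/reader covers plain 16-bit EDF with one uniform sampling
  rate — sufficient for the package's loop and simple external files, not
  a general EDF+ implementation.
* `hdca()` extends beyond the canonical 600 Hz / 1000 ms / 25 ms geometry
  (any rate where the window holds a whole number of samples); behaviour
  away from the canonical geometry is our extension, tested for shape
  correctness only.
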