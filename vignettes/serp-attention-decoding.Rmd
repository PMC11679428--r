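---
title: "Decoding selective tactile attention from somatosensory ERPs"
author: "serpbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding selective tactile attention from somatosensory ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpbci)
```

## The decoding problem

An electrotactile brain-computer interface delivers brief electrical pulses
to two sites on the right forearm — dorsal (D) and volar (V) — while the
user covertly attends one of them (counting the pulses felt there). Both
sites are stimulated equally often, so the only information about the
user's intent is carried by the *somatosensory event-related potential*
(sERP): the stimulus-locked cortical response recorded over the
sensorimotor cortex. Early, *exogenous* deflections (N20, P50, N70) are
driven by the afferent volley itself and are insensitive to attention;
later, *endogenous* components (P100, N140, P300) are enhanced when the
stimulated site is the attended one. A classifier that can tell "attended
D" from "attended V" waveform patterns turns this modulation into a binary
command channel.

The package implements the complete analysis as a pipeline of small,
testable stages:

1. **Protocol** — 6 blocks of 5 sub-blocks, 60 pulses each (1800 per
   session, 900 per site), pseudorandomized with 25–35 pulses per site per
   sub-block and no more than 3 consecutive pulses at one site; the
   attended site alternates between blocks
   (`protocol_spec()`, `generate_protocol()`).
2. **Recording** — six channels (C3, Cz, C4, CP3, P3 over sensorimotor
   cortex, Fp1 for ocular artifacts) at 1200 Hz
   (`synthesize_recording()` for synthetic data, `read_recording()` for
   the delimited interchange format).
3. **Preprocessing** — zero-phase second-order Butterworth band-pass
   (0.1–25 Hz EEG, 1–10 Hz Fp1), 650 ms epochs (100 ms baseline + 550 ms
   poststimulus), baseline correction of the poststimulus interval,
   rejection at 50 µV (EEG) / 80 µV (Fp1), extraction of the 50–550 ms
   trial window (600 samples) without Fp1 (`preprocess_recording()`).
4. **Features** — trials averaged in chronological groups of
   `navg` (2–10) per cluster (attended × stimulated site), decimated by 8
   to 75 samples per channel, channels concatenated (375 values), and the
   D-stimulation and V-stimulation averages joined into one 750-sample
   vector labelled only by the attended site (`build_features()`).
5. **Selection and classification** — wrapper-based sequential forward
   selection (cap 40) scored by 5-fold inner cross-validation, followed by
   a grid search over each classifier family, all nested inside a 5-fold
   outer cross-validation (`nested_evaluate()`).
6. **Reporting** — accuracy tables, selected-feature maps, paired
   significance across `navg`, and the information-transfer-rate (ITR)
   trade-off (`accuracy_table()`, `feature_maps()`, `compare_navg()`,
   `compute_itr()`).

## The synthetic-data generator

Real sERP recordings of this protocol are not publicly deposited, so the
package ships a generator that produces recordings with the statistical
structure the analysis assumes. It is first-class, tested code — every
downstream stage is exercised end-to-end against it.

The sERP template is a superposition of Gaussian-windowed deflections, one
per classical component, with defaults

| component | latency (ms) | width (ms, SD) | amplitude (µV) | attention gain |
|---|---|---|---|---|
| N20  | 20  | 5  | −2 | 1 (exogenous) |
| P50  | 50  | 8  | +3 | 1 (exogenous) |
| N70  | 70  | 10 | −3 | 1 (exogenous) |
| P100 | 100 | 18 | +4 | 1.5 |
| N140 | 140 | 22 | −6 | 1.5 |
| P300 | 300 | 60 | +8 | 1.5 |

The attention gain multiplies endogenous components when the stimulated
site is the attended one; channel weights concentrate both response and
effect on the contralateral/central electrodes (C3, CP3, Cz), consistent
with the topography of forearm somatosensory responses. These are
generator defaults — the real study reports no effect sizes in µV, so
parameter-recovery tests are judged against generator truth, not against
the study's subject tables.

Noise is `1/f` (exponent 1 by default) plus a white floor, scaled to a
12 µV SD — a realistic raw-EEG amplitude that keeps the single-trial
attention effect (≤ 4 µV at the best channel) below the noise floor, so
averaging is genuinely necessary. Eye blinks (150 µV Hann bumps at Fp1,
propagated at small fractions to the scalp channels) and gross movement
bursts (120 µV half-sines on all EEG channels) occur at Poisson times;
the default rates (1.2 and 0.3 per minute) were chosen so that roughly 2%
of epochs fail the rejection thresholds, matching the rejection statistics
the protocol design anticipates (a few tens of the 1800 epochs). The
generator is deterministic given its seed, and the `truth` field retains
every generating specification.

What the generator does *not* emulate: volume-conducted spatial
correlation of the background EEG (channels get independent noise),
line-frequency interference (the acquisition chain is assumed notched),
latency jitter and habituation of the components, and inter-subject
topography differences. Passing recovery tests on synthetic data therefore
demonstrates that the pipeline's machinery is correct and leak-free — not
that the real-data accuracies of any particular cohort are reproduced.

```{r example, eval = FALSE}
rec <- simulate_subject(seed = 1)
trials <- preprocess_recording(rec)
features <- build_features(trials, navg = 10)
fit <- nested_evaluate(features$x, features$y, "svm",
                       sfs_config(max_features = 10), seed = 1)
summary(fit)
```

## Feature selection and the nested design

Selection is a greedy wrapper: starting from the empty set (incumbent
accuracy 0), every remaining candidate is scored by the mean inner-CV
accuracy of the classifier trained on the current set plus that candidate,
using the classifier's fixed SFS-time parameters (LR: L2, strength 0.1;
KNN: K = 10; SVM: linear, C = 1; RF: 30 trees, depth 5, Gini; MLP:
batch 8, rate 1e-3). The argmax candidate — ties to the lowest feature
index, so reruns are order-independent — is added only if it *strictly*
improves the incumbent, otherwise selection stops; the cap is 40 features.
The same inner splits are reused for every candidate, every iteration, and
the subsequent hyperparameter grid search, and they are built once per
outer fold from the outer-training rows only. Scale-sensitive classifiers
(KNN, SVM, MLP) see features standardized with statistics computed on the
inner-training rows of each fold — never on validation or outer-test rows.

Design choices worth knowing (each was genuinely open):

* "Improves performance" is read as *strictly greater*, so selection can
  stop well before the cap; the empty set's baseline is 0, so the first
  feature is always accepted.
* The LR "regularization strength" values are the penalty weight λ on the
  mean-log-loss scale (larger = stronger shrinkage), not its inverse; the
  constant `lr_strength_is_lambda` isolates the reading.
* The RBF SVM's γ applies to the RBF kernel only; the linear-kernel grid
  rows carry no γ.
* The RF tree-count grid runs 20–40 in steps of 5 by default
  (`classifier_spec("rf", rf_trees_step = 1)` enumerates all 21 values).
* The MLP architecture is one hidden layer of 32 rectified-linear units,
  cross-entropy loss, Adam, a 200-epoch budget and patience-20 early
  stopping on a held-out 15% slice of its training rows; nothing deeper is
  warranted by a few hundred exemplars of 750 correlated amplitudes.
* Trials are averaged in consecutive non-overlapping chronological groups
  and leftover trials are discarded; pairing for vector assembly is by
  chronological rank within cluster. Overlapping or recycled groupings
  would couple exemplars across cross-validation folds.

The classifier kernels themselves (penalized logistic regression, hinge
SVM by dual coordinate descent, KNN, random forest, MLP) are implemented
in compiled code inside the package: the wrapper loop evaluates on the
order of 2×10^5 fits per (subject, classifier, navg) cell, and the
implementations guarantee bit-reproducibility (cyclic coordinate descent,
seeded bootstrap and initialization, lowest-index tie-breaking) that is
not part of the contract of the usual fitting packages. The test suite
cross-checks each kernel against an independent implementation: glmnet
(coefficients to 1e-4), e1071 (SVM predictions), class::knn (exact
predictions away from its internal distance-tie tolerance) and
randomForest (accuracy parity).

## Numerical and statistical conventions

* **Sampling conventions.** Event onset maps to sample
  `round(onset × rate)`; the epoch is the half-open window
  `[onset − 120, onset + 660)` samples, the trial `[onset + 60, onset + 660)`
  — 600 samples, decimated at offsets 1, 9, … to 75. Downsampled sample
  `j` (1-based) sits at `50 + (j − 1)·1000/150` ms.
* **Filtering** is applied to the continuous recording before epoching, so
  epochs carry no per-segment edge transients; the forward–backward pass
  squares the magnitude response and zeroes the phase. The band-pass at
  0.1–25 Hz leaves a 50 Hz probe below 6% of its amplitude.
* **Rejection** applies to the full 650 ms baseline-corrected epoch
  (thresholding before baseline correction would let slow drifts through
  on one side and double-reject on the other; the processing order is
  filter → epoch → baseline → reject → extract and is enforced by an
  integration test).
* **Protocol balance.** Per-sub-block D counts are drawn uniformly in
  [25, 35] but in complementary pairs, so each session delivers exactly
  900 pulses per site, as the protocol prescribes.
* **Significance across navg** (the interval maps): two-sided paired
  Wilcoxon signed-rank across subjects at α = 0.05, uncorrected — raw
  p-values are retained in the result so any correction can be applied
  downstream. The test refuses fewer than 6 subjects. With tied
  difference magnitudes R's exact small-sample p-value is unavailable and
  the normal approximation is used; the `p` matrix records what was
  computed.
* **Accuracy summaries** use the sample (n−1) standard deviation.
* **ITR** defaults to the selection-rate convention
  (`log2(N) × 60 / (2·navg·0.75)` bpm), which is what the headline 20 →
  4 bpm trade-off numbers express; the Wolpaw accuracy-adjusted form is
  available via `convention = "accuracy_adjusted"` and the two only agree
  at perfect accuracy. Both are exposed because published ITR figures for
  this paradigm follow the accuracy-independent convention while citing
  the Wolpaw formula; the discrepancy is surfaced, not resolved.
* **Optimal navg** scans downward from the largest setting and reports the
  first whose accuracy differs significantly from navg = 10 — the fastest
  setting reachable before an established accuracy drop — with its
  selection-rate ITR; with no significant pair it returns the smallest
  navg, flagged.

## Problem sizes used by the shipped checks

The test suite and the acceptance script size their simulations to what
the properties need, not more: protocol properties run on 400 reduced
protocols plus a couple of dozen full ones; convergence of event-locked
averaging is checked at 10/100/400 trials; the selection engine is proved
equivalent to a literal greedy transcription on 25 instances of up to 20
features and 120 rows; and the end-to-end recovery study uses 3 full
synthetic subjects (1800 stimuli each) with the LR and SVM classifiers,
navg ∈ {2, 10} and a selection cap of 10. At those sizes the recovery
study establishes the qualitative findings that matter — accuracy rising
with navg, chance-level decoding when the attention gain is 1, and
selected features concentrating at endogenous latencies on C3/CP3/Cz —
while any single-cell accuracy remains a stochastic quantity with a few
points of seed-to-seed spread.

## Known limitations

* The generator's independence assumptions (white-in-space noise, fixed
  component latencies) make the synthetic task somewhat easier at matched
  SNR than real recordings; absolute synthetic accuracies should not be
  read as predictions for any real cohort.
* Full-cap (40-feature) selection with the RF or MLP classifier is
  computationally heavy in the wrapper loop (those fits cannot be swept in
  compiled batch); the fast kernels (LR, SVM, KNN) are the practical
  choice for 750-feature runs.
* Ocular artifacts are rejected, not corrected; ICA/regression correction
  and re-referencing are out of scope.
* The delimited-text recording format is the supported interchange; EDF
  and other binary acquisition formats are not read or written.
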