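---
title: "Frame-level detection of positional nystagmus: methods and design"
author: "nystagmusdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-level detection of positional nystagmus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Benign paroxysmal positional vertigo (BPPV) produces brief attacks of
vertigo accompanied by nystagmus — involuntary rhythmic eye movement —
when the head is moved into a provoking position, classically during a
Dix-Hallpike test (a 45° head turn followed by a rapid recline to supine).
A wearable recorder capturing horizontal and vertical electrooculography
(EOG) at ~41.67 Hz together with a 3-axis accelerometer at ~20 Hz makes it
possible to look for these events over days of ordinary life. The
detection problem is extreme: attacks are seconds long, predominantly
vertical and oscillatory, occur only after a supine manoeuvre, and occupy
on the order of 0.03% of the recorded samples.

This package implements a complete frame-level detection pipeline for
such recordings, and a simulator that generates labelled recordings with
the same statistical structure, so that every stage is trainable and
testable without clinical data.

## The pipeline

1. **Preprocessing** (`highpassFilter()`, `alignAccelerometer()`). EOG
   baseline drift is removed with a second-order Butterworth high-pass at
   0.25 Hz. Filtering is causal (forward-only) with zero initial state, as
   a streaming device would apply it; the startup transient of a few
   seconds is accepted, and a zero-phase two-pass option exists for
   offline use. The accelerometer is *not* filtered; it is linearly
   interpolated onto the EOG sample grid (clamped beyond its last sample)
   so the five channels can be stacked.

2. **Framing** (`velocity()`, `makeFrames()`). A 400-sample window
   (9.6 s at 41.67 Hz) slides with 75% overlap (hop 100). Per frame, the
   two EOG rows are first-differenced to velocity (a leading zero
   preserves length) and the three accelerometer rows enter raw; each of
   the five rows is normalised to a unit L2 vector. The window of 400
   samples fixes the EOG rate at 41.67 Hz rather than the nominal 42 Hz:
   400 samples must span 9.6 s, and 400/9.6 = 41.67. Two label views are
   kept: *training* labels take the modal sample label of the window so
   only unambiguous examples train the networks, while *testing* labels
   are positive if any covered sample is nystagmus, so no event escapes
   evaluation. Velocity is applied to the EOG rows only — it is the
   eye-movement velocity that is informative, and the accelerometer
   carries orientation, which differencing would destroy.

3. **Balancing** (`smoteBalance()`). Classes (0 = none, 1 = nystagmus,
   2 = supine without nystagmus) are equalised by SMOTE on the flattened
   2000-dimensional frame vectors: synthetic minority examples are uniform
   interpolants between a class member and one of its k = 5 same-class
   Euclidean nearest neighbours. k = 5 and the Euclidean metric are the
   canonical choices of the original technique. Synthetic rows are not
   re-normalised: interpolants of unit rows are near-unit already and
   renormalising would depart from the cited method. Balancing is applied
   once per training fold, never to test data.

4. **Networks** (`networkConfig()`, `buildNetwork()`, `trainNetwork()`).
   The classifier is a small convolutional network over the 5×400 plane.
   Because the published description does not fix the exact layer
   dimensions, the package defines an explicit reference architecture:
   three blocks of (16, 3×7), (32, 3×7) and (64, 1×5) filters, each with
   ReLU and 1×2 max-pooling along time, then a dense layer of 64, dropout
   0.5, and a 3-way softmax; a two-block "reduced" variant serves small
   training budgets. A 1-D baseline treats the five rows as separate input
   channels with time-only kernels. Training is Adam on categorical
   cross-entropy, learning rate 0.001, batch size 20, 30 epochs, no
   validation split or early stopping. All initialisation, shuffling and
   dropout derive from one integer seed, so training is exactly
   reproducible. The convolution and pooling forward/backward kernels are
   compiled code in the package (no external deep-learning framework is
   used); gradients are finite-difference checked in the test suite.

5. **Ensemble and post-processing** (`trainEnsemble()`,
   `predictEnsemble()`, `majorityVote()`, `remapClass2()`,
   `sieveFilter()`). Five networks differing only in seed vote per frame;
   the plurality class wins. An odd member count precludes binary ties,
   but three-class pluralities can still tie (e.g. 2-2-1); such ties
   resolve to class 0, the conservative clinical default (configurable).
   Class 2 exists only to teach the networks what supine non-nystagmus
   looks like and is folded into class 0 after fusion (a pre-vote remap is
   available). The binary track is then sieve-filtered: positive runs
   shorter than `openLen` are removed, then internal negative gaps shorter
   than `closeLen` are filled. The published account gives no lengths;
   the defaults are 2 and 2 frames (each new frame adds 2.4 s of signal),
   consistent with the reported removal of a lone positive frame. Opening
   precedes closing, following the order in which the operations are
   described.

6. **Evaluation** (`confusionCounts()`, `frameMetrics()`,
   `aggregateF1()`, `runCrossfold()`). Scoring is frame-level:
   sensitivity = 100·tp/(tp+fn), specificity = 100·tn/(tn+fp),
   F1 = 2tp/(2tp+fp+fn). A fold with no positive truth frames reports
   F1 = 1.00 if it also produced no false positives and 0.00 otherwise —
   the generalisation of the published convention for the positive-free
   fold; sensitivity with an empty positive set reports as 100%. The
   cross-fold harness trains on all-but-one file and tests the held-out
   file, sieving each test file's track independently and summing counts
   within a fold; the aggregate is the mean per-fold F1 with standard
   error sd/√n (the published account does not define its standard error;
   this is the conventional choice). Counts before sieving are also kept,
   since the published tables do not state at which stage single-network
   sensitivities were measured.

## The simulator

`simulateRecording()` generates labelled recordings with the structure the
pipeline must exploit:

* **EOG** = low-frequency drift (a low-pass-filtered random walk, rescaled
  to `drift_scale`; its power lies well below the 0.25 Hz cut-off) +
  white noise + Poisson step-like saccades (conjugate, random direction,
  2–8× noise) + nystagmus bursts: raised-cosine-enveloped sinusoids at
  2–5 Hz, vertical amplitude `vertical_dominance` (default 2.5) times the
  horizontal, amplitude `nystagmus_amp` (default 4) times the noise
  standard deviation. A sawtooth "jerk" waveform is available but off by
  default: the modelled target is the oscillatory appearance of positional
  nystagmus, not jerk morphology.
* **Accelerometer** = a unit-gravity orientation trace: upright, with a
  smooth 2 s spherical rotation into a supine 45°-yawed pose before every
  event and back after it (Dix-Hallpike kinematics reduced to fixed
  constants: 2 s rotation, 1 s latency to burst onset, 2 s supine tail),
  plus Gaussian noise of `accel_noise_g`. The noise-free trace has norm
  exactly 1 g at every sample.
* **Labels**: 1 during bursts, 2 during supine holds without nystagmus,
  0 elsewhere. Negative supine events (manoeuvre without attack) provide
  class-2 confounds for the accelerometer; oscillatory *upright*
  eye-movement episodes (walking-induced vestibulo-ocular oscillation or
  visual tracking — matching the bursts in band, amplitude and vertical
  dominance) provide class-0 confounds for the EOG. The latter component
  is what makes single-modality detection genuinely hard, mirroring the
  clinical observation that eye movement alone cannot identify positional
  nystagmus: only its coincidence with supine posture can.

Default conditions target the clinical regime: a single 3–30 s episode in
a 12 h recording, i.e. an expected nystagmus share of ≈0.04% of samples —
the order of the ≈0.03% clinical figure. Durations and event counts are
per-recording parameters, not tuned quantities.

What the simulator does **not** model: blink artefacts, torsional eye
movement (invisible to 2-channel EOG), saccadic main-sequence kinematics,
electrode pop or dropout, and realistic Dix-Hallpike kinematics. Passing
tests on simulated data therefore demonstrate that the pipeline's
machinery is correct and that it can learn the supine-gated oscillation
structure; they do not establish clinical performance.

## The validation regime and problem sizes

End-to-end validation uses `easyRegimeConfig()`: three 720 s recordings,
each with four 18–25 s bursts at amplitude 8× noise and vertical dominance
3, two negative supine events and seven upright oscillatory confusers,
evaluated leave-one-out with the reduced architecture, 5 epochs and a
five-member ensemble. Two sizing choices deserve explanation:

* *Episode length.* Under the any-overlap test-labelling rule, an episode
  of d samples intersects ≈(d+399)/100 test-positive frames but contains
  only ≈(d−200)/100+1 majority-labelled (trainable) ones. For 10 s
  episodes that ratio caps attainable sensitivity near 40% no matter how
  good the classifier — the same geometry that holds clinical frame-level
  sensitivity at 52% for seconds-long attacks. Validation episodes of
  18–25 s (about twice the window, still within the clinical 3–30 s
  range) make high frame-level F1 attainable while preserving the
  boundary-frame effect.
* *Confound mix.* Upright oscillatory episodes outnumber negative supine
  manoeuvres (7 vs 2 per file), reflecting that in daily-life recordings
  motion-locked eye oscillation is ubiquitous while deliberate provocation
  manoeuvres are rare. This asymmetry is what reproduces the published
  qualitative ordering — combined features > accelerometer only > EOG
  only — in simulation.

The three-file, five-epoch, reduced-architecture budget keeps a complete
three-arm experiment within minutes on one CPU while leaving the ordering
and the >0.8 ensemble F1 stable across simulation seeds.

## Numerical choices and degenerate inputs

* Modal-label ties in training frames (e.g. a 200/200 split) resolve to
  the larger label value, preferring the informative class; rare and
  covered by a test.
* All-zero feature rows (a constant EOG segment has zero velocity) are
  left as zero vectors rather than dividing 0/0.
* Trailing samples that do not fill a window are discarded.
* NaN or non-finite samples are rejected at read time; the recording
  format stores 17 significant digits so write-read is the identity.
* Argmax ties in prediction break toward the lower class index.
* SMOTE with a class of one member errors; an absent class is skipped;
  k is truncated (with a warning) when a class is smaller than k+1.
* Recordings shorter than one window, kernels larger than their input
  extent, and even ensemble sizes are rejected with explicit errors.
* Member seeds default to `baseSeed + 0:(n-1)`; per-fold seeds are
  derived offsets so folds are independent but reproducible.

## Known limitations

* The reference network architecture is an explicit substitution for an
  under-specified original; absolute performance numbers are therefore
  not comparable layer-for-layer, only the surrounding protocol is.
* Frame-level scoring undercounts clinically: a detected event whose
  boundary frames are missed still counts several false negatives.
  Event-level scoring is deliberately out of scope.
* The SMOTE neighbour search is exact (O(n²) distances), adequate for
  fold-sized frame sets, not for corpus-scale balancing.
* Training is single-threaded, deterministic CPU code sized for frames of
  a few thousand, not a GPU replacement for multi-hour training runs.
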