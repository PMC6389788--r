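---
title: "Neural keyword spotting from ECoG high-gamma features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural keyword spotting from ECoG high-gamma features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A speech brain-computer interface needs a "wake word": a detector that
watches a continuous neural recording and fires, with low latency and few
false alarms, when the user produces one specific utterance. `neurokws`
implements a two-stage detector for electrocorticographic (ECoG)
recordings of overt speech:

1. **Neural voice-activity detection (VAD).** A spatiotemporal template of
   the average speech-evoked high-gamma response is cross-correlated
   against the streaming feature array; causal peak-picking on the squared,
   smoothed correlation marks utterance times.
2. **Keyword discrimination.** At each detected utterance, a linear
   max-margin classifier decides keyword vs non-keyword speech from
   PCA-reduced template-correlation features.

The task is block-randomized production of 12 consonant-vowel (CV)
syllables spanning three articulatory axes: place of articulation
(bilabial /b,p/, alveolar /d,t/, velar /g,k/), consonant voicing, and
vowel height (/a/ vs /i/). One session (the "reading" task) trains every
artifact; a separate session (the "repetition" task) tests them with no
recalibration except feature normalization, which is per-task by design.

## Signal model and features

High-gamma (70--110 Hz) band power tracks local population firing and
modulates at the time scale of articulator movements. Features are
extracted causally:

- 128 ms hamming-tapered FFT window sliding in 16 ms hops (62.5 frames/s);
  a frame's timestamp is the time of the **last** sample in its window, so
  a feature value never depends on future samples.
- Log power per bin is z-scored per channel per frequency against the
  *pooled baseline*: all frames whose window lies in the second before a
  stimulus onset, pooled over trials of the task.
- Bins with center frequency in [70, 110] Hz are averaged and the band
  feature re-z-scored per channel against the same baseline frames.

Causality is therefore relative to the task-level normalization
constants: the pooled baseline is computed in one offline pass per task
(as in the reference methodology), and the streaming transform is
strictly causal given those constants.

Channels are common-average re-referenced over the non-excluded set
(exclusion happens *before* the average) and downselected to the speech
regions of interest, ventral sensorimotor cortex (vSMC) and superior
temporal gyrus (STG).

Microphone voice onsets are detected from 250--450 Hz band power
(rectangular analysis window: energy arriving at the causal window edge
must register immediately), smoothed 50 ms, thresholded at 5 baseline
SDs, with a backtrack along the contiguous super-threshold run and a
half-hop midpoint correction so the estimate is unbiased to within
+/- 8 ms. Trials with no crossing keep a missing onset -- microphone
failures are data, not errors.

## Templates and matched filtering

Response epochs are 63 frames (about 1 s) centered on each trial's voice
onset. From these:

- the **response template** is the grand mean over all trials;
- one **discrimination template** per contrast (12 syllables, 3 places,
  2 voicing classes, 2 vowel heights -- 19 in all) is the condition mean
  minus the response template, temporally smoothed (hamming, 0.1 s,
  zero-phase: templates are offline objects) and then significance-masked:
  elements whose condition-mean z against baseline falls below 3.0 are set
  exactly to zero (one-sided, following the source convention);
- the **VAD template** is the response template restricted to vSMC
  channels; STG auditory channels are excluded because they also respond
  to *perceived* speech.

Filtering is causal: the window at frame *t* spans frames *t-62 .. t*.
The correlation is a **masked-template cosine similarity**,

$$ r(t) = \frac{\sum_{\mathrm{mask}} T \cdot X_t}{\lVert T \rVert_{\mathrm{mask}} \, \lVert X_t \rVert_{\mathrm{full}}} , $$

with neither side re-centered. This is a deliberate design decision at a
point the source methodology leaves open ("correlation" is not further
specified). A Pearson correlation computed *over the unmasked entries*
fails structurally here: the significance mask selects exactly the
active regions, so re-centering over the mask support subtracts the
template's own signal -- a one-lobe window then anti-correlates on a
two-lobe template's absent lobe, and during development this inverted the
voicing axis (place templates preferred the wrong voicing class). With
template entries already being deviations from the response and the
stream already z-scored, zero is meaningful on both sides; normalizing by
the full-window energy keeps $|r| \le 1$ and amplitude-invariant.

Discrimination outputs are causally smoothed (hamming, 0.25 s); the VAD
output is the squared correlation causally smoothed (hamming, 1.0 s).
Kernel lengths are `floor(duration * 62.5 + 0.5)` frames: 6, 16 and 63.

**Event-time conventions.** Three frame offsets map filter outputs back
to event times, all carried as attributes on the output object:

- `center_offset` (31): window center of the correlation window;
- `y_event_offset` (39): adds the 0.25 s smoother's ~8-frame group delay --
  the frame where an event's template outputs actually peak. Training
  alignment, ROC scoring and detection-time classification all read
  features at this offset; reading at the bare window center samples the
  rising edge of the smoothed response at about two-thirds amplitude.
- `vad_event_offset` (62): adds the 1.0 s smoother's 31-frame delay, so a
  VAD peak at frame *t* reports an event ~1 s earlier -- which is also the
  detector's end-to-end latency.

## Detection

The smoothed VAD series is standardized against its pooled-baseline
frames with robust statistics (median, IQR/1.349). A plain SD is the
wrong scale estimator here: a baseline frame's *trailing 1 s window* can
brush the previous trial's response tail, and how often that happens
depends on the session's realized intertrial intervals -- two otherwise
identical sessions showed baseline SDs differing by 1.5x, which wrecked
cross-session transfer of the operating threshold. Robust scale
estimates agreed to ~10%.

Peak-picking follows the derivative rule: after the standardized series
crosses the threshold upward, the first sign change of the first
difference marks a detection; the detector re-arms once the series falls
back below threshold (the re-arm rule is a recorded choice; the source
does not describe one). The reported event time is then refined to the
argmax of the *unsmoothed* squared correlation within the trailing
smoother window -- strictly past data, so still causal -- because peak
localization on a 1 s-smoothed series carries +/- 2 frames of jitter that
the raw correlation peak does not.

The operating threshold sweeps 0--20 SD in 0.25 steps; matching detections
to true onsets uses +/- 100 ms with injective greedy matching (extra
detections near an already-matched onset are false positives). The
equal-error-rate (EER) threshold minimizes |miss rate - false positives
per utterance|, ties broken toward the higher threshold.

## Discrimination

A PCA is fit over *all* frames of the training task's 19 template-output
series; the minimal number of components reaching 90% cumulative
variance is retained, and transformed series are standardized by the
training-set SD of each component.

Training pairs are assigned within stimulus blocks: every keyword trial
against every non-keyword trial of the same block, plus one
silent-period competitor (1.0 s before the keyword trial's stimulus
onset) per keyword trial -- with 5 keyword trials in a 60-trial block
this is 5 x 55 + 5 pairs per block. Each competitor carries a +/- 6-frame
(+/- 100 ms) context.

The classifier is trained online with the passive-aggressive PA-I rule,
which realizes the cited max-margin discriminative approach concretely
(the source gives no loss constants): for each pair, the competitor is
the most keyword-like frame in its context under the current boundary,
and

$$ w \leftarrow w + \tau\,(x^+ - x^-), \qquad
   \tau = \min\!\big(C,\ \ell / \lVert x^+ - x^- \rVert^2\big), \qquad
   \ell = \max(0,\, 1 - w \cdot x^+ + w \cdot x^-), $$

with C = 1, at most 10 epochs over a seed-fixed shuffled order, early
stop at zero epoch loss. The trained weight vector is rescaled by the
training-frame score SD so decision scores sit on a unit baseline scale;
without this, the fixed threshold sweep [-10, 10] can fail to contain a
model's operating point. Each keyword's decision threshold is chosen at
the equal error rate on the training task.

## Evaluation

- **ROC mode**: classifier scores at the microphone-derived onsets of the
  test task; AUC is the Mann-Whitney pair statistic (ties count 1/2),
  exact regardless of sweep resolution.
- **Permutation null**: training labels are permuted *within blocks*
  (preserving block balance), the classifier retrained (templates and PCA
  stay frozen), and the test AUC recorded; the 95th percentile of the
  null is the significance cutoff. Note a subtlety of this null at small
  trial counts: the permuted classifier *anti-learns* the true keyword
  (true-keyword trials sit among its competitors), so individual null
  means sit slightly below 0.5, and with 5--10 "keyword" draws from 12
  classes the null is wide (95th percentiles near 0.95 are normal).
- **Simulated keyword spotting**: the causal peak-picker runs at the
  trained VAD threshold; each detection's feature vector is classified by
  every keyword model; a keyword trial counts as detected if a
  keyword-classified detection falls within +/- 100 ms of its onset, and
  every other keyword-classified detection is a false keyword detection,
  normalized per utterance. A leakage guard refuses to evaluate a model
  on its own training session.

## The synthetic world

`generate_session()` emulates what the pipeline assumes about real
sessions; its defaults are the stated world and are not tuned per run:

- **Task structure**: blocks of 60 trials, 5 per syllable, randomized
  within block; 1 s stimulus; 2--3 s intertrial interval; voice onset
  0.8 s (SD 0.1) after stimulus onset.
- **Background**: per-channel pink (1/f) noise plus a shared common-mode
  component at half amplitude, so common-average referencing is exercised
  nontrivially.
- **Responses**: band-limited (70--110 Hz) noise bursts under a hamming
  envelope (0.3--0.5 s per channel), centered near the true voice onset
  with a fixed per-channel latency offset (+/- 50 ms).
- **Selectivity map** (fixed per simulated *subject* via `profile_seed`,
  so a train/test pair shares physiology while trial order, noise and
  burst waveforms differ): vSMC holds 2 non-selective channels that
  respond identically to every utterance -- what the VAD template relies
  on -- and 9 place-selective channels (3 per place; full amplitude for
  the preferred place, 0.15 otherwise). Voicing is encoded **purely as
  timing** on alternating place channels: on unvoiced trials their bursts
  lead the acoustic onset by `voicing_shift` (articulatory pressure
  buildup before the plosive release). STG holds /a/- and /i/-preferring
  channels (amplitude contrast 1 vs 0.35) plus non-selective auditory
  channels. "Other"-ROI channels are pure noise and exercise
  downselection. The heterogeneous map (timing-coding channels mixed with
  timing-stable ones) mirrors the single-trial electrode phenomenology
  the method was designed around; an all-channels-timed map also biases
  VAD detection times by half the voicing shift per class.
- **`voicing_shift` = 0.2 s**: the discriminative trainer deliberately
  maximizes competitor scores over a +/- 100 ms context, so any timing
  code at or below 100 ms lies inside the classifier's designed
  shift-invariance and cannot work as a keyword cue. 0.2 s is outside
  that window and physiologically ordinary for pre-plosive activity.
- **`burst_snr` = 5**: the target peak high-gamma feature z of a
  full-scale burst. The generator calibrates the burst amplitude
  numerically against a pink-noise reference using the exact feature
  definition (per-bin log-power z, band average, re-z), solving for the
  amplitude whose predicted peak z equals the target.
- **Microphone**: near-silent noise floor plus a 250--450 Hz burst
  starting at the true voice onset with a 10 ms attack (real voicing
  onsets rise fast; a slow symmetric envelope would make +/- 16 ms onset
  recovery impossible for *any* detector).

What a green test does **not** establish: the generator has no
inter-ictal artifacts, no electrode drift or impedance changes, no
coarticulation or utterance-length variability, no perceived-speech
activation of STG (so the motivation for excluding STG from the VAD
template is honored but not stress-tested), and its noise is Gaussian.
Passing recovery criteria on this world demonstrates the pipeline's
correctness and calibration, not clinical performance.

## Numerical choices and degenerate inputs

- Smoothing kernels are unit-sum hamming FIRs; causal smoothers
  renormalize their partial kernel over the first frames instead of
  emitting NAs.
- Zero-variance windows or all-masked templates give correlation 0;
  frames before the first full window give 0.
- A PCA over constant outputs, an empty baseline, a channel with zero
  baseline SD, an empty VAD curve, and dimension mismatches are errors
  with the offending item named.
- Pair updates with identical keyword and competitor vectors and positive
  loss are skipped with a warning (zero denominator).
- All public times are in seconds; frame indexing is 1-based in R code
  while offsets (31/39/62) are counts, so conventions survive the
  language boundary.
- Detection-count monotonicity in the threshold holds in the operating
  regime (thresholds above the baseline noise floor); below it the
  fall-below-threshold re-arm rule merges excursions, which is a property
  of the specified algorithm.

## Known limitations

- The detector assumes isolated utterances surrounded by silence;
  keywords embedded mid-vocalization would need a different peak-picking
  rule.
- The permutation null retrains only the classifier, not templates or
  PCA -- the tractable reading of "scrambling labels while training
  keyword detectors"; a full-pipeline null would be wider still.
- Session containers are plain-text directories rather than a binary
  scientific container; adequate at desk scale, not for hour-scale
  clinical recordings.
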