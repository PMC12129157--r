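---
title: "Methods: acoustic screening for cognitive decline with vocog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic screening for cognitive decline with vocog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Language and speech production degrade early in most dementias: articulation
slows, pauses lengthen and multiply, and prosodic variation flattens. vocog
implements a purely acoustic screening pipeline for cognitive decline (CD)
from roughly one-minute conversational speech samples. No transcription or
linguistic analysis is involved: the signal chain goes from a waveform to a
single probability that the speaker is cognitively declined.

Ground truth for training is the Mini-Mental State Examination (MMSE,
0–30): a score of 23 or lower defines the CD class (label 1), 24 or higher
the cognitively normal (CN) class (label 0). This cutoff targets
moderate-and-worse impairment; it is not sensitive to MCI-level decline,
and the package deliberately offers no alternative cutoffs
(`label_from_mmse` is the single labeling rule, and stored label columns in
manifests are only cross-checked against it).

## Signal chain

1. **Standardization** (`read_wav`, `standardize`, `rms_normalize`,
   `denoise`). All audio is converted to 16-bit, 16 kHz mono. Stereo is
   mixed by channel averaging. Resampling is polyphase
   (`signal::resample`), with the rational rate conversion fixed by the
   two sample rates, so outputs are reproducible across runs. RMS
   normalization to a target level (default −20 dBFS, configurable —
   the level itself is a package choice, made configurable because no
   single standard exists) removes recording-volume differences before
   feature extraction. An optional spectral-gating denoiser (noise profile
   from the lowest-energy 10% of 32 ms frames; bins under profile ×
   gate-factor attenuated by `strength`) is off by default: the pipeline
   assumes reasonably quiet, single-speaker recordings, and speaker
   separation is the caller's responsibility.

2. **Windowing** (`make_segments`). Feature extraction runs on 5-second
   windows with a 1-second overlap, i.e. starts every 4 s while a full
   window fits. A 60-s clip yields 14 windows; trailing audio shorter than
   5 s is discarded (padding is opt-in via `pad = TRUE` for short clips).

3. **Per-window features** (1028 values, laid out
   `[embedding 768 | voiced_prob 100 | f0 100 | mfcc 60]`):
   * *Embedding (768)*: a pluggable per-window speech representation. The
     default `encoder_mock` mean-pools the gain-normalized log-mel
     spectrogram over time and projects it to 768 dimensions through a
     fixed, seeded random matrix. It exists so the pipeline is fully
     testable offline and deterministic; it is not a learned
     representation, and swapping in a pre-trained self-supervised speech
     encoder (mean-pooled final hidden layer) changes values only, never
     shapes or formats.
   * *Voicing probability (100)* and *F0 (100)*: a YIN-style estimator on
     64 ms frames with a 50 ms hop — the hop is chosen so a 5-s window
     yields exactly 100 frames, the simplest geometry that produces the
     required dimensionality. The cumulative-mean-normalized difference
     function is minimized over lags corresponding to 60–400 Hz (adult
     conversational range); the pitch lag is the first local minimum below
     0.15 (falling back to the global minimum) with parabolic refinement.
     Voicing probability is 1 − CMND at the chosen lag, hard-zeroed for
     near-silent frames; frames with probability < 0.5 report F0 = 0,
     keeping the track numeric everywhere. Low voicing probabilities are
     exactly the silent-interval signal that marks pausing.
   * *MFCC aggregate (60)*: 20 MFCCs per 25 ms frame (10 ms hop, 40 mel
     filters, orthonormal DCT-II), aggregated per window as
     per-coefficient maximum, mean, and mean first-order delta, in that
     order. The delta reduction to a mean mirrors the mean entry; it is
     one of several defensible reductions and is isolated in
     `extract_mfcc_agg` if a different one is wanted.

4. **Classifier** (`vocog_fit`). Each window's 1028-vector passes through
   a fully connected stack (1128 then 768 units, ReLU) applied identically
   at every time step; the transformed sequence feeds a two-layer
   bidirectional LSTM with 512 hidden units per direction; the final
   forward and backward hidden states are concatenated (1024 values) and
   classified through 1024- and 512-unit ReLU layers ending in one sigmoid
   unit. The default architecture has 15,145,225 parameters (pinned by a
   test against closed-form arithmetic). A probability ≥ 0.5 is called CD;
   the tie goes to CD by definition of the rule.

The network, backpropagation-through-time and the Adam optimizer are
implemented in base R on BLAS-backed matrix operations, with one small
compiled kernel for the in-place Adam update. Gradients are verified
against central finite differences in the test suite, including
variable-length (masked) batches.

## Training procedure and its defaults

Training minimizes binary cross-entropy with Adam (learning rate 1e-4),
batch size 8, at most 50 epochs, and a stratified 20% validation split.
The parameters with the lowest validation loss are kept; training stops
early when validation loss has not improved by at least `min_delta`
(1e-4) for `patience` (10) epochs. These are conventional defaults, all
exposed in `train_config`, as are dropout-free, unweighted-loss choices —
the package takes the simplest configuration that trains reliably at this
scale.

Two numerical choices matter in practice and are package decisions:

* **Feature standardization.** Columns are z-scored with training-set
  statistics stored in the fit and re-applied at prediction time. Raw
  feature scales span four orders of magnitude (low-order MFCCs versus
  embedding coordinates); no first-order method trains sensibly without
  this.
* **Reproducibility.** All randomness (initialization, split, batch
  order, synthesis) is derived from integer seeds via a local-RNG helper
  that never touches the caller's RNG state. Identical seeds give
  identical fits on one machine; across BLAS builds, floating-point
  reassociation can perturb long training trajectories, which is why
  acceptance-style checks assert performance bands rather than exact
  weights.

## The synthetic corpus: what it does and does not show

No public audio exists for this task, so the package ships a
source-filter speech simulator (`synth_utterance`, `synth_corpus`):
voiced runs of harmonic syllables (per-syllable F0 ~ Normal(`f0_mean`,
`f0_sd`), fixed vowel-like formant envelope, raised-cosine amplitude
contour, mild amplitude jitter) alternate with silent pauses steered to a
target silent fraction. Default phenotypes:

| parameter | CN | CD | direction rationale |
|---|---|---|---|
| syllable rate (per voiced s) | 4.0 | 2.5 | slower articulation |
| pause ratio | 0.20 | 0.45 | longer, more frequent pauses |
| mean pause (s) | 0.4 | 1.2 | inter-sentence pausing |
| F0 mean (Hz) | 180 | 180 | (held equal deliberately) |
| F0 SD (Hz) | 30 | 10 | flattened prosody |

The directions follow the clinical phenomenology; the magnitudes are
package choices fixed once, aimed at a contrast that is learnable from
the traditional features but not trivially separable by a single value.
Synthetic MMSE scores (CD: uniform 10–23; CN: 24–30) are metadata glue so
the labeling path is exercised; no claim is made that the acoustics
encode a particular score.

Passing end-to-end tests on this corpus demonstrates that the plumbing,
features, optimizer, and evaluation behave correctly and that the
classifier can recover a known prosodic contrast from raw audio. It does
**not** demonstrate clinical validity: real conversational speech has
lexical content, speaker identity, channel effects, and far subtler
class differences than the simulator's.

## Evaluation layer

`evaluate_screening` computes confusion counts and
accuracy/sensitivity/specificity at the ≥ 0.5 rule; single-class inputs
return `NA` for undefined proportions with an explicit flag rather than a
silent 0. `roc_auc` computes AUC by pairwise concordance (ties counted
half, evaluated exactly via midranks) — the distribution-free estimator —
and keeps the trapezoidal area under the swept ROC as a cross-check; the
two agree exactly in the absence of ties, and concordance is also checked
against an exhaustive O(n²) pair count and an independent ROC
implementation in the tests.

`screening_test_fixture` packages a published 20-subject discrimination test
(diagnosis, MMSE, label, model probability per subject). Evaluating it at
threshold 0.5 reproduces that test's reported metrics exactly: accuracy
0.950, sensitivity 0.875, specificity 1.000, and AUC 0.990 (95 of 96
CD–CN pairs concordant). The CD rows' mean MMSE is 18.4 at one decimal.
The fixture's CN-group mean MMSE (26.75) rounds to 26.7, one tenth below
the 26.8 printed alongside the original table; the package reproduces
only the CD-group summary for this reason.

## The permutation null

The end-to-end check pairs the real run with a permutation control:
training on randomly shuffled labels should leave held-out AUC near 0.5.
One design subtlety: with shuffled labels, validation loss never improves,
so best-epoch selection would return an essentially untrained network —
whose nearly-constant outputs still rank inputs along their dominant
acoustic axis, pushing AUC to an arbitrary extreme. A meaningful null
requires actually fitting the shuffled labels, so the control run selects
by training loss (`validation_split = 0`) over the full epoch budget. This
is the standard construction of a permutation reference distribution:
destroy the label–feature link, train identically otherwise.

## Problem sizes and degenerate inputs

The shipped end-to-end configuration uses 40 + 40 training and 10 + 10
held-out 60-second clips — comfortably reproducible on a single CPU while
leaving the classification problem non-trivial. Degenerate inputs are
rejected loudly: empty clips, windows of the wrong length, single-class
training sets, out-of-range MMSE scores, manifests with duplicate
subjects or labels inconsistent with MMSE, and infeasible phenotype
parameter combinations all raise errors naming the offending rows or
values.

## Known limitations

* The mock encoder is a fixed random projection: adequate for pipeline
  validation, useless as a learned representation; the adapter for a real
  pre-trained speech model ships as an interface stub only (no weights).
* Single-speaker audio is assumed; diarization is out of scope.
* The MMSE ≤ 23 rule cannot see MCI-level decline, and MMSE regression is
  out of scope.
* WAV is the only supported container; real-time capture is out of scope.
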