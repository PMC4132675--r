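---
title: "Decoding incidentally learnt tone clouds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding incidentally learnt tone clouds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmvpa)
```

# The experimental paradigm

`tcmvpa` simulates and analyses a class of incidental auditory-learning
experiments built on *tone clouds*: noise-like stimuli made of brief pure
tones ("pips") placed randomly on a fixed time-frequency grid. A 1.5 s
stimulus is three contiguous 0.5 s segments and comes in three flavours:

* **RTC** (repeated tone cloud) — one freshly drawn segment repeated three
  times; a within-trial repetition is present.
* **NTC** (non-repeated tone cloud) — three independent segments; no
  repetition.
* **RefTC** (reference repeated tone cloud) — like an RTC, but the *same*
  exemplar recurs across trials. Listeners are never told this; repeated
  exposure alone produces incidental learning of the three RefTC exemplars,
  measurable behaviourally (repetition-detection d′ rises above the RTC
  level) and neurally (the exemplar identity becomes decodable from
  region-of-interest fMRI activity patterns).

The package provides every stage as a tested, reusable component: stimulus
synthesis, trial-sequence design with a simulated observer, synthetic ROI
fMRI data, trial-wise GLM estimation, multivoxel decoding with searchlight
feature selection, and group-level inference.

# Stimulus model

The time-frequency plane from 100 Hz to 10 kHz is tiled by contiguous
frequency channels of half an octave (two channels per octave; the last
channel is truncated at 10 kHz, giving 14 channels) and 50 ms time windows
(10 per segment). Each grid cell receives exactly one 50 ms pip whose onset
is uniform within the window and whose frequency is log-uniform within the
channel. Equal pip counts per channel and window match the long-term
spectrum and temporal envelope of all clouds on average; only the detailed
arrangement differs between exemplars.

Numerical choices the grid description leaves open:

* *Frequency law.* "Random frequency within the cell" is implemented
  log-uniformly, consistent with the octave-based channel construction.
* *Window overrun.* Pip duration equals the window length, so a pip with a
  random onset necessarily overruns its window; strict containment is
  impossible. Pips keep their full 50 ms but are truncated at the *segment*
  boundary, which keeps repeated segments sample-identical when tiled —
  the defining property of RTC and RefTC waveforms.
* *Ramps and level.* Each pip carries a 5 ms raised-cosine onset/offset
  ramp (click suppression); all pips have equal amplitude and the final
  waveform is RMS-normalised (default 0.1). Sample rate defaults to
  44.1 kHz.

`write_stimulus()` renders WAV plus a JSON sidecar holding the spec and the
full pip tables, from which a stimulus can be reconstructed exactly.

# Task design and the simulated observer

Training blocks hold 20 trials each of one RefTC exemplar, RTC and NTC,
ordered so that two RefTC trials are never adjacent. Rather than rejection
sampling (a uniform shuffle of 20-in-60 satisfies the constraint with
probability ≈ 6×10⁻⁵, so rejection is impractical), the non-RefTC trials
are shuffled and the RefTC trials inserted into 20 of the 41 distinct gaps,
which samples uniformly from the valid arrangements. The test session mixes
20 trials of each of the three trained exemplars with 60 RTC and 120 NTC
trials in fully random order. Trials are spaced at 4.5 s (1.5 s stimulus +
3 s inter-stimulus interval), unjittered.

The simulated observer is deliberately minimal: repeated stimuli draw "yes"
at a base rate (default 0.6), NTC trials at a false-alarm rate (0.25), and
every prior exposure to a given RefTC exemplar adds a learning increment
(0.02) to that exemplar's yes-probability, capped at 1; lapses flip the
response with probability 0.02. These values were fixed once so that a
simulated test session yields a RefTC−RTC d′ difference of roughly 0.5,
large enough that a 7-subject paired one-tailed t-test detects it with
power above 0.8. The observer makes no claim to psychophysical realism
(no memory decay, no criterion shifts, no reaction times); it exists to
exercise the d′ and group-statistics machinery end to end.

d′ is z(H) − z(FA) with extreme rates corrected by the 1/(2N) rule
(log-linear correction available). Each RefTC exemplar's hit rate is
compared against the session-wide NTC false-alarm rate.

# Synthetic fMRI model

ROI masks are single 6-connected blobs grown from a random seed voxel;
`roi_voxel_target()` converts reference region volumes (mm³,
hemispheres summed) into voxel counts at 1.5 mm isotropic (the in-plane
resolution of the acquisition; slice thickness is taken as the same).

Exemplar-specific signal lives on *informative voxels*: all mask voxels
within `cluster_radius` (default 2) of `n_clusters` (default 3) random
cluster centres. Within clusters each of the three exemplars receives
independent standard-normal deviations scaled by `amplitude`; outside them
the three patterns are identical. Clustering matters: it gives the
radius-3 searchlight spatial structure to find, which scattered informative
voxels would not.

Trial betas are `baseline + pattern(label) + N(0, noise_sd)`. RefTC trials
reuse their exemplar's fixed pattern; RTC and NTC trials get trial-unique
fresh draws on the informative voxels, mirroring stimuli generated anew
each trial — this is what makes the pseudo-class control sit at chance.
The effective SNR is `amplitude / noise_sd`.

The time-series route instead emits BOLD at TR = 4.2 s: per voxel, the sum
over trials of the trial's amplitude times an HRF-convolved 1.5 s boxcar,
plus iid Gaussian noise (optional AR(1)). Noise is white by default; with
4.5 s between trials and a 32 s kernel, neighbouring trial regressors
overlap substantially, so GLM-estimated betas carry inflated noise relative
to the direct route — matched-SNR comparisons should scale the scanner
noise by the design's variance-inflation factor (see
`test-synthetic-fmri.R` for the construction).

# Trial-wise GLM

The canonical HRF is the standard double-gamma difference: a gamma density
peaking at ~5 s minus one sixth of a gamma density peaking at ~15 s,
sampled on [0, 32] s and peak-normalised. Each trial is one regressor: its
1.5 s listening event convolved with the kernel at a 0.1 s microtime grid
(avoiding aliasing of the short event at the 4.2 s TR), then sampled at
scan times. All trial regressors enter a single model together with an
intercept and optional confounds, and ordinary least squares per voxel
yields the trials × voxels beta matrix. No high-pass filter or prewhitening
is applied — appropriate for the simulator's iid noise, and both are
deliberately out of the model rather than hidden defaults.

# Decoding pipeline

Decoding which RefTC exemplar was heard is a three-class problem on the 60
RefTC trials (20 per exemplar), cross-validated with stratified 10 folds
(2 trials per class per fold). Within each fold, strictly on the training
portion:

1. **Standardisation.** Each voxel is z-scored with training-fold mean and
   SD; the same transform is applied to the held-out trials.
2. **Searchlight feature selection.** Every mask voxel centres a sphere of
   radius 3 (voxel-index units), clipped to the ROI, so spheres shrink near
   borders. Each candidate sphere is scored by the inner 5-fold
   cross-validated accuracy of the very classifier used downstream
   (the score the selection rule needs but that a verbal description of
   "greatest decoding information" does not pin down). The best-scoring
   sphere's voxel set is selected; ties go to the lowest centre index. A
   union-of-top-k mode exists (`n_best`) but the single best sphere is the
   default.
3. **ECOC linear SVM.** One soft-margin linear SVM (C = 1, fixed — no
   hyperparameter search) per column of a one-vs-rest code matrix.
   Held-out trials are decoded by minimum Hamming distance between the
   predicted sign vector and the class codewords; ties break by the larger
   summed signed margin, then the lower class index. For a one-vs-rest
   code this decoding provably coincides with the arg-max rule whenever
   margins are distinct.

Accuracy is pooled over all folds (each trial tested exactly once); chance
is 1/3.

The SVM dual is solved by sequential minimal optimisation with
maximal-violating-pair working-set selection, implemented in compiled code
together with the neighbourhood scorer — one cross-validation run scores
thousands of sphere × inner-fold × binary-problem fits, which is the hot
loop of the whole package. The solver is validated against LIBSVM (via
e1071) and against direct primal minimisation in the test suite. Searchlight
scoring uses a looser duality tolerance and an iteration cap
(`score_tol`, `score_max_iter`); selection is ordinal, so ranking spheres
does not require tightly converged duals, and the final per-fold models use
the tight settings.

## Controls

* **Label shuffle**: the full pipeline is re-run with per-trial permuted
  labels. Expected accuracy is chance. A subtlety worth knowing: because
  RefTC trials of the same exemplar share a true pattern, permuting labels
  induces a small *negative* dependence between training and held-out
  labels within each pattern cluster (hypergeometric sampling without
  replacement), so the shuffle null tends to sit a few tenths of a
  percentage point *below* 33% rather than exactly at it.
* **Pseudo-class split**: the 60 RTC trials are split randomly into three
  classes of 20 and decoded. RTC patterns are trial-unique, so no stable
  representation exists and the expectation is exactly chance.

## Leakage guarantees

Feature selection and SVM training see only training-fold trials. The test
suite verifies this directly by corrupting held-out folds and asserting
that the selected voxel sets are unchanged under a replayed RNG stream.

# Group-level inference

Per-subject accuracies are tested against chance with one-tailed one-sample
t-tests (directional hypotheses), regions are compared with a one-way
within-subject ANOVA (F = MS_region / MS_region×subject, df =
(r−1, (r−1)(n−1)); no sphericity correction, matching the uncorrected df
convention, with the Greenhouse–Geisser epsilon attached for reference),
followed by two-tailed paired t-tests. Hemispheres are collapsed by
per-subject averaging only after paired tests find no left/right difference
in any ROI at α = 0.05; otherwise the collapse is withheld and the
asymmetric ROIs flagged. α = 0.05 throughout, uncorrected across the six
ROIs — a deliberate replication of the analysis convention, noted here
because six uncorrected tests inflate family-wise error.

Zero-variance inputs (all accuracies identical) raise an error rather than
returning t = 0: a t statistic with zero denominator is undefined, and
silently returning a value would mask degenerate simulations. The one
exception is the hemisphere check on exactly identical hemispheres, which
reports t = 0 and proceeds with the collapse.

# Problem sizes and reproducibility

All randomness flows through R's RNG; every generator is deterministic
given `set.seed()`. Simulated ROI sizes in the examples, tests and the
acceptance script are desk-scaled (40–160 voxels) rather than the
anatomical 500–4300 voxels implied by the printed region volumes: the
informative-cluster geometry, searchlight selection and all statistical
properties are unchanged by ROI size, while nested scoring cost grows
linearly with it. `roi_voxel_target()` provides the full-size counts for
users who want anatomically sized simulations.

What passing tests on synthetic data do and do not show: the generator
emulates stable exemplar-specific patterns, trial-unique controls,
configurable SNR and (optionally) HRF-mediated temporal structure, but not
physiological noise spectra, motion, spatial autocorrelation of real BOLD,
inter-subject variability in informative-voxel location, or any real
auditory encoding. Green tests certify the pipeline's statistical
machinery — calibration at chance, power at stated SNR, leakage-freedom,
correct bookkeeping — not claims about real brains.

# Known limitations

* The observer model is a plumbing stand-in, not a psychophysical model.
* The SMO solver handles the small dense problems this design produces
  (tens to a few hundred trials); it is not a general-purpose SVM.
* Whole-brain searchlight mapping, nonlinear kernels and spatial smoothing
  are out of scope.
* With 2 test trials per class per fold, single-subject accuracy is
  quantised in steps of 1/60; group statistics absorb this.
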