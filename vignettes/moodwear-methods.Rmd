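---
title: "Methods: from raw wrist-wearable physiology to mood-episode classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw wrist-wearable physiology to mood-episode classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Research-grade wrist wearables (Empatica-E4-style devices) stream several
physiological channels at heterogeneous rates: triaxial acceleration
(ACC, 32 Hz, in g), electrodermal activity (EDA, 4 Hz, in µS), skin
temperature (TEMP, 4 Hz, in °C), blood volume pulse (BVP, 64 Hz, arbitrary
units) and a derived heart rate (HR, 1 Hz, bpm), plus an interbeat-interval
(IBI) event list. In naturalistic psychiatric recordings these signals are
noisy — poor skin contact, device removal, motion — and the clinical
questions are supervised: can the *severity* of a mood episode (acute /
response / remission, within one patient) and the *polarity* of illness
(seven diagnosis/state classes across patients) be read from the raw
channels? `moodwear` implements the full chain: archive I/O, rules-based
quality control, time alignment, windowing, balanced partitioning, a
bidirectional LSTM classifier, permutation feature importance with Kendall W
rank agreement across tasks, and mutual-information association between
channels and the items of the YMRS and HDRS psychometric scales. Because no
patient data ship with the package, a first-class synthetic generator
reproduces the session format, the class-conditional signal structure, and
plantable artifacts violating each quality-control rule.

## Quality control

Five rules mark seconds as invalid. Rules 1–4 act on native-rate samples of
a governing channel: EDA outside [0.05, 60] µS (floor/ceiling artifacts);
EDA slope outside ±10 µS/s (forward difference scaled by the sampling rate,
first sample defined 0); TEMP outside [30, 40] °C (sensor off the wrist);
HR outside [25, 250] bpm. Rule 5 flags every otherwise-valid second within
5 s of a second caught by rules 1–4 (transition effects). Decisions the
rule table leaves open, fixed here:

* **Evaluation order.** Rules run on native-rate samples first, then project
  to one-second units (any violating sample invalidates its second). The
  alternative — averaging to 1 Hz before filtering — would dilute the 4 Hz
  slope rule; both orders are possible via the exported primitives, the
  native-rate order is the default pipeline.
* **Global invalidity.** A flagged second is removed from *all seven*
  channels, because the classifier consumes complete multichannel vectors
  and imputation is deliberately out of scope.
* **Inclusive endpoints.** A sample exactly at a range limit is valid.
* **Slope estimator.** Forward difference; a central difference differs only
  at artifact edges, which rule 5 pads over anyway.

## Alignment, windowing, partitions

All channels are reduced to per-second means (time unit µ = 1 s; HR passes
through) and joined on the absolute seconds common to all channels — so a
channel that starts late (the generator can delay HR by 10 s, a real device
behavior) shifts the whole grid. Windows of w consecutive *contiguous* valid
seconds are cut without overlap; windows never straddle a validity gap, and
trailing remainders are dropped, so 3600 contiguous seconds at w = 32 yield
exactly 112 segments. Powers of two from 1 s to 2048 s are accepted for w;
32 s is the default operating point, and `sweep_window()` reproduces the
tuning procedure that motivates it. Non-overlapping windows were chosen
because overlap would leak near-duplicate segments across partitions.

Per class, 20 segments are held out as the test set (never touched during
training), and the remainder is split 80/20 into train and validation at
segment level, pooled across the sessions of a task rather than per session
(the split's granularity is not dictated by the procedure; pooling is the
simpler choice and is configurable through the partition functions). Train
*and* validation are balanced by down-sampling to the smallest class —
validation balance keeps early stopping on a balanced criterion. Min–max
normalization parameters come from the train partition only; validation and
test values may fall outside [0, 1] and are not clipped; a train-constant
channel maps to 0 everywhere. A separate *generalization* set takes whole
held-out subjects (zero subject overlap), normalized with the training
parameters — the two evaluation surfaces (within-session test,
across-subject generalization) answer different questions and the package
keeps them distinct.

## The classifier

A shallow bidirectional LSTM: one recurrent layer of 128 hidden units per
direction with tanh cell activation, the two final hidden states
concatenated and fed to a dense softmax layer. Training minimizes
cross-entropy with Adam (learning rate 0.001, batch size 32) for at most
120 epochs, with inverted dropout (default rate 0.2) on the concatenated
recurrent output and early stopping. The recurrent cell, backpropagation
through time and Adam are implemented directly on base R matrix algebra;
the gradients are verified against finite differences in the test suite.
Choices the training recipe leaves open:

* **Early stopping** monitors validation loss with patience 10 and restores
  the best-validation weights; 120 epochs is a cap, not a target.
* **Dropout rate** defaults to 0.2 and sits on the recurrent output.
* **Input layout** is w time steps × 7 features, the natural layout for a
  recurrent net.
* **Hyperparameter search**: `random_search()` provides a seeded random
  search over learning rate, dropout and hidden units; defaults stay pinned
  to the values above.
* **Initialization**: Glorot-uniform weights, forget-gate bias 1; all
  randomness (initialization, batch order, dropout masks) flows from one
  integer seed, so a fixed seed reproduces the entire history bit for bit.

Evaluation reports accuracy (the primary metric on perfectly balanced
sets), precision/recall/F1 in micro and macro averages (which coincide with
accuracy on balanced sets — the suite asserts the identity to machine
precision), the confusion matrix, and one-vs-rest AUROC per class (each
class in turn positive, the rest pooled negative; computed via pROC).

## Interpretability

**Permutation importance.** For one channel at a time, its values are
scrambled across test segments and the drop in accuracy relative to the
intact baseline is recorded (positive = the channel matters). Whole
segments of the channel are shuffled between segments by default,
preserving within-segment temporal structure — the perturbation unit equals
the unit the model consumes; per-timestep scrambling is available as an
option. Ten repeats are averaged (mean ± SD). Because motor activity is one
sensor read as three axes, the table reports the three ACC axes both
individually and as one jointly scrambled group. Agreement of channel
rankings across tasks uses the Kendall coefficient of concordance with tie
correction, W = 12S / (m²(n³−n) − mT); the suite cross-checks it against
the Friedman statistic in base R (χ² = m(n−1)W).

**Channel–item mutual information.** Each segment inherits the YMRS/HDRS
item scores of its source session; each channel is summarized per segment
by its mean on the aligned, unnormalized scale (SD is available — the
summary is configurable, and the segment was chosen as the observation unit
because it is the same object the classifier consumes). The summary is
discretized into 8 equal-frequency bins (robust to skew; configurable), the
item score keeps its native integer levels, and the plug-in MI (nats) is
computed from the joint frequency table. Each item's row is then scaled by
its maximum across channels, so every nonzero row peaks at exactly 1.0 —
this operational, per-item-max normalization is the default; the symmetric
variant MI/√(H(x)H(y)) sits behind a flag. A constant item yields a zero
row with a warning rather than an error, since remission-capped items are
legitimately constant in some pools.

## The synthetic generator

Each channel is white Gaussian noise around a slowly varying baseline — a
mean-reverting (Ornstein–Uhlenbeck) walk with ~30 s correlation time,
reflected inside the physiologically valid range — plus a class-conditional
mean shift and variance factor. Mean reversion matters: a pure random walk
would give every session a persistent level fingerprint, which a classifier
tested on held-out segments *from the same sessions* would read as a class
label even with zero class separation; with the OU baseline, the
no-separation cohort sits at the chance floor, as the acceptance suite
verifies. One separation knob δ scales all class shifts (and, symmetrically,
the variance factors), so δ = 0 makes classes identically distributed by
construction. Severity shifts order T0 > T1 > T2 on ACC, EDA and HR with
TEMP depressed in acute states; BVP carries no class information — so the
importance analysis has a known negative control. Sessions of 1600–3600 s
and δ = 4 are the suite's standard "separable cohort" conditions; they were
fixed with the generator, and the problem sizes keep a full severity run
under a minute on one CPU.

Subject random effects (small per-channel offsets) make subjects
heterogeneous; the `confound = "subject"` variant permutes the
class-to-shift mapping per subject, so a model can be internally accurate
yet generalize at chance — the qualitative gap between within-subject test
accuracy and across-subject generalization that motivates keeping the two
surfaces separate. Psychometric items are drawn from label-conditioned
targets under the real instrument maxima (acute mania reaches YMRS totals
near 24; remission keeps both totals ≤ 7), giving the MI analysis a
recoverable ground truth. ACC is quantized to 1/64 g integer counts, the
on-device convention the I/O layer converts on read.

What the generator does **not** emulate: realistic pulse waveforms,
circadian structure, sleep architecture, medication effects, or
autocorrelated symptom dynamics. Passing tests therefore demonstrate that
the pipeline recovers structure *of the planted kind* — mean/variance class
signal, rule-violating artifacts, label-linked item scores — not that real
recordings carry such structure.

## Numerical and degenerate-input choices

* Archive samples are written with 6 significant digits (beyond device
  resolution); header lines (start time, rate) keep full precision so
  absolute-second alignment survives a round trip.
* An empty unit in downsampling is dropped; a window longer than every
  contiguous run yields zero segments with a warning, not an error.
* A class with fewer than 21 segments fails partitioning loudly, naming the
  class.
* Softmax is computed with max subtraction; probabilities are floored at
  1e-12 inside the loss.
* `derive_seed()` fans one global seed out to fixed per-stage seeds so any
  stage can be re-run in isolation and still match the full pipeline run.

## Worked example

```{r, eval = FALSE}
library(moodwear)

co <- generate_cohort(cohort_config("severity", subjects = 1,
                                    session_length = 1600, delta = 4,
                                    seed = 1, generalization_subjects = 1))
res <- run_severity_task(co, seed = 1)
print(res)

te <- with(res, list(x = dataset$segments[dataset$partition == "test", , ],
                     y = dataset$labels[dataset$partition == "test"]))
imp <- permutation_importance(res$model, te$x, te$y, seed = 1)
plot(imp)

nmi <- nmi_table(co, "intra", w = 32)
plot(nmi)
```

## Known limitations

* The BiLSTM trains on a single CPU core; the intended problem sizes are
  research cohorts of hours-long sessions, not streaming deployments.
* The MI estimator is the plug-in estimator on binned summaries; it is
  biased upward at small segment counts, which is why association tables
  should be read against the permutation null (the suite calibrates this).
* The severity task trains one model per subject by design; nothing is
  shared across subjects, so cross-subject transfer is exactly what the
  generalization surface measures, not what the model optimizes.
* IBI data are parsed and carried through I/O but never modeled, and no
  heart-rate-variability features are derived.
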