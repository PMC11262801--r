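---
title: "Methods: posture windows, self-supervised pre-training and screen statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture windows, self-supervised pre-training and screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(larvaction)
```

# The problem

Large behavioural screens film dozens of *Drosophila* larvae from above and
keep only tracking output: a timestamped midline (spine) per animal, and
sometimes a contour. The behavioural readout used to compare genetic lines
is discrete — at every timestep each larva is tagged with one of a small
dictionary of archetypal actions (crawl, bend, back, hunch, roll, stop,
plus a catch-all *small action* class for weak versions of any of them).
Hand-built classifiers with fixed kinematic features cannot be retrained
when the action dictionary, the tracker, or the genetic background changes,
so this package takes the representation-learning route: learn a continuous
latent representation of short posture sequences without any annotation,
then train a small classification head on top of it from whatever labelled
data exists.

# Posture windows

The classifier sees a 2-s window of postures around each timestep, nothing
else. A raw window is interpolated to `L = 20` uniform time samples, and
each midline is resampled to `S = 5` points uniform in arc length. Both
values are configurable (`windowing_config()`); they are the smallest
values that still resolve one peristaltic cycle (about 1 Hz at typical
10 Hz tracking) and the lowest bend mode, and keeping the window small
keeps every model in the package cheap to train.

Normalization removes the similarity transform: the window centroid moves
to the origin, coordinates are divided by the mean body length over the
window, and the window is rotated so the head-to-tail axis of the first
time sample lies along +x. What remains is dimensionless posture *change*:
within-window drift (crawling direction), length dynamics (peristalsis,
hunches), transverse bending — which is what distinguishes actions.
Normalization is applied per window rather than per track, so the features
are insensitive to slow drift in tracker calibration; the cost is that
absolute speed information is discarded, which is deliberate: the same
action performed by a slow line should look like the same action.

Choices worth knowing about:

* **Boundary padding.** Every timestep receives a window; beyond the track
  ends the first/last frame is replicated. Disable with
  `pad_boundaries = FALSE`.
* **Tracking gaps.** Timestamps are authoritative and never assumed
  equispaced. Windows are interpolated linearly in time, but a
  between-frame gap longer than half the window length invalidates the
  window; the timestep is reported untagged rather than guessed.
* **Resampling order.** Each frame is resampled to `S` arc-length-uniform
  points first, then interpolated in time. The two operations commute to
  first order and this order costs O(T) spine resamplings per track
  instead of O(windows × L).
* **Head/tail orientation.** Tracks are assumed head-first; there is no
  automatic head detection. This is a documented limitation — data whose
  tracker flips head and tail will confuse crawl and back.

# The autoencoder

The encoder is a dense feed-forward network (hidden widths 128-96-64-32,
tanh, then a linear map to a `D = 16` dimensional latent code Z); the
decoder mirrors it and expands Z to the *extended* sequence: one window
length of past postures, the window itself, and one window length of
future postures (`context_windows = 1`). Training minimizes mean squared
error over the whole extended sequence, equally weighted. Having to
predict the past and future forces Z to encode the dynamics of the
behaviour, not just the current shape, and needs no labels — so the
encoder can be pre-trained on arbitrarily large unlabelled repositories.

Numerical choices: Xavier-uniform initialization (also the baseline arm of
the transfer experiment), Adam (default learning rate 1e-3, batch 64), a
10% validation split with best-weights restoration and optional early
stopping, and seeded, single-threaded training throughout, so a given
`train_config()` reproduces its run bit for bit. The latent dimension 16
and the 4-layer depth were chosen as the smallest configuration whose
pre-trained latents reliably beat a fresh Xavier-initialised encoder in
the small-sample transfer setting; with a much smaller latent space the
reconstruction objective starts discarding action-discriminative detail,
and with a shallower encoder a randomly initialised network is already so
easy to train on this package's simulated data that pre-training has
nothing left to add.

# The tagger

A small head (one tanh layer of 32 units, then softmax) maps Z to class
probabilities. Training uses weighted cross-entropy with inverse-frequency
class weights (screens are dominated by crawling; without weighting rare
actions like hunch would be ignored). Unless `freeze_encoder = TRUE` the
encoder is fine-tuned jointly at a reduced learning rate
(`encoder_lr_scale = 0.1`): the usual transfer-learning regime in which
the pre-trained representation is adapted gently while the head trains at
full rate. Full-rate fine-tuning would let even a random encoder re-learn
everything from the labelled set when that set is large — which defeats
the point of pre-training and empirically erases the small-sample benefit.

Prediction is per window, mapped back to the window's centre timestep; no
temporal smoothing is applied to the label sequence (a smoothing hook
exists but defaults to off, because any smoothing rule is a modelling
decision the user should make explicitly). Ties resolve to the first class
in dictionary order. The *small action* class is a class like any other:
there are no priority rules between actions. Timesteps whose window was
invalidated by preprocessing stay untagged.

# The simulator

`simulate_track()` and `simulate_assay()` generate dorsal-view midline
kinematics with per-timestep ground-truth labels. The simulator is a
kinematic cartoon, not a biomechanical model; its only job is to give the
learning and statistics modules distinguishable, labelled classes with
controllable difficulty:

* **crawl** — travelling longitudinal compression wave (default 1.2 Hz,
  relative amplitude 0.15, half a wavelength per body) with net head-first
  displacement (0.15 body lengths per cycle);
* **back** — the same wave reversed, with slower tail-first displacement;
* **bend** — the anterior 40% of the body swings about a pivot with a
  1.2 rad amplitude;
* **hunch** — a rapid uniform contraction (30% of body length, complete in
  0.2 s), held briefly, released, and repeated after a rest. The
  retraction speed exceeds the crawl wave speed *by construction*, and
  both scale with the phenotype speed multiplier, so the contrast survives
  a globally slowed line — the reason duration-invariant features matter
  in the first place. A hunch is modelled as a transient event because a
  permanently contracted, motionless larva would be indistinguishable
  from a stopped one at the posture level;
* **roll** — alternating-sign midline curvature with lateral drift of the
  whole body. Dorsal-view rolling has no faithful 2-D midline signature,
  so this is the weakest, most stylized class by design;
* **stop** — a frozen posture; its only motion is tracking noise.

Per-larva phenotype variation (`sample_action_params()`) draws a
log-normal speed multiplier (σ = 0.25) and ±20% jitter on the main rates
and amplitudes, emulating between-line variability. Gaussian coordinate
noise (default sd 0.05 mm on a 4 mm body, about 1% of body length —
typical midline-fit jitter at screen resolutions) is added last.
`simulate_assay()` mirrors the stimulus protocol: every larva follows a
pre-stimulus action mixture, switches exactly at stimulus onset to actions
drawn from the post-stimulus mixture (segment durations 1.2–3 s, so the
1-s analysis window after onset reflects the post mixture), and the
metadata records onset and duration (defaults 45 s and 38 s).

What the simulator does **not** emulate: contours, collisions and track
merging, head/tail detection errors, tracker-specific artefacts,
behavioural sequences with realistic transition statistics, or any real
line's kinematic parameters. Tests passing on simulated data therefore
demonstrate that the machinery is correct and that the learning pipeline
behaves as designed — not that a given real screen would reach the same
accuracy.

# Screen statistics

The evaluation module reproduces the screen comparison procedure:
stimulus-aligned action-probability time series
(`probability_timeseries()`), then for a chosen analysis window (typically
the 1 s right after onset) a per-line, per-action comparison against a
control line. Counting is at the larva level: a larva performs an action
in the window if any of its timesteps there carries the label; `n` counts
larvae with at least one tagged timestep in the window. Each comparison is
a Pearson chi-squared test on the 2×2 table (no Yates correction by
default; switchable), Bonferroni-corrected. The correction count `m`
defaults to the number of tests actually performed; the original screen's
inventory (m = 471) is reproduced by setting it explicitly. The
significance level defaults to α = 0.05, which the procedure's source
never states — both this and larva-level counting are interpretations, and
frame-level counting is available as an alternative reading. Outcomes are
three-level (positive, negative, none), and `agreement()` summarizes
concordance between two taggers' outcome maps, separating effects lost,
effects gained and opposite calls. Degenerate zero-margin tables return
chi² = 0, p = 1; lines with no tagged larva in the window are flagged
untestable rather than tested.

# Problem sizes

The package's own test and evaluation runs use: pools of 600 windows per
class (six classes) with phenotype variation; pre-training on 1800
windows for 200 epochs with a 200-window held-out reconstruction set;
six-class taggers trained on 500 windows per class and evaluated on 100
per class; transfer experiments at 10 and 200 windows per class with five
seeds per arm; null and alternative screen simulations with 60 larvae per
line (200 and 40 replicates respectively). These sizes were chosen so that
every property of interest is measurable with comfortable margins while a
complete run stays cheap on a single CPU.

# Known limitations

* Rotation alignment uses the first time sample only; a window whose
  first sample is strongly bent is aligned by its chord, which adds
  orientation variance for bend-heavy windows.
* The latent space is trained per package defaults on simulated data;
  real deployments should pre-train on their own unlabelled repositories.
* `roll` is intrinsically ambiguous in 2-D midline terms and is expected
  to be the weakest class.
* No head/tail disambiguation, no contour features, no predefined
  kinematic features.
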