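---
title: "Position-aware indoor activity recognition: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-aware indoor activity recognition: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Compound indoor activities — eating, desk work, cooking, doing laundry —
are built from the same low-level motions (walk to a spot, sit or stand,
put the phone down). Inertial sensors alone therefore confuse them:
eating and desk work are both "walk, sit, stationary". What separates
them is *where* they happen. `lmiar` implements a recognizer that fuses
two feature streams extracted from a single smartphone:

* a **location branch (LFN)**: the 3-axis geomagnetic field and ambient
  light carry a room-specific fingerprint (steel and wiring distort the
  Earth's field differently in each room; illumination differs too). Each
  1024-sample window of the four channels is laid out as a 32x32x4 image
  and classified by a convolutional network with ResNet18 topology whose
  classification layer is replaced by a 128-d feature head and a 6-room
  softmax head;
* a **motion branch (MFN)**: each of the six IMU axes (Ax, Ay, Az, Gx,
  Gy, Gz) of the same window is split into 16 tokens of 64 samples and
  passed through a transformer encoder (6 layers, 8 heads by default); a
  final fully connected layer maps the 16x64 encoder output to a 128-d
  feature per axis.

Axis features are concatenated per sensor (`Za`, `Zg`, 384-d each) and
fused with the location feature `Zl` (128-d) by **low-rank multimodal
fusion (LMF)**: conceptually `Zm = W (Za (x) Zg (x) Zl) + b` for a
trilinear weight tensor `W`, computed without materializing the tensor by
writing `W` as a sum of `r = 4` rank-one factors:

```
Zm = b + sum_{i=1..r} (wa_i Za') * (wg_i Zg') * (wl_i Zl')
```

with `*` the elementwise product and `'` a trailing-1 augmentation that
keeps unimodal and bimodal terms alive in the product. `full_tensor_oracle()`
materializes `W` and the outer-product tensor explicitly on small
instances; the equality `lmf_fuse == full_tensor_oracle` is the central
correctness property and is asserted over a hundred random configurations
in the test suite. The fused 512-d feature feeds a one-layer softmax
classifier over the six activities.

Training is two-stage: the LFN is pretrained as a room classifier
(Adam, cross-entropy, batch 32, learning rate 0.01 in the full-size
recipe), then its classification layer is dropped, the remaining weights
are frozen, and the motion branch, fusion factors and activity head are
trained on activity labels. Freezing is structural here: the frozen LFN
is excluded from the optimizer and no gradient path reaches it, and a
checksum test asserts its weights are bit-identical before and after
stage 2. Three variants support the ablation harness: `LM-IAR` (full),
`LM-IAR-nl` (LFN without the light channel, 3-plane images) and `M-IAR`
(no location branch; two-modality LMF).

## The neural-network engine

No deep-learning framework is used: the package carries its own compact
engine — dense, 2-D convolution (im2col), batch/layer normalization,
multi-head attention, the LMF layer, softmax cross-entropy, and Adam —
with hand-derived backward passes. Every layer's gradient is validated
against central finite differences in the test suite, and the
transformer forward pass is additionally checked against a hand-rolled
attention oracle written in plain matrix algebra. Evaluation is
deterministic: given fixed seeds, training histories and evaluation
reports reproduce bit-for-bit on the same machine.

Two engine-level choices matter scientifically:

* **Normalization-free option for the LFN.** The room signature lives in
  the *absolute* level of the image planes. With batches of 32, a
  batch-normalized network can learn to read levels *relative to its
  batchmates*, which transfers poorly to single-sample inference (we
  measured large train/eval disagreement). `lfn_config(norm = "none")`
  replaces batch norm with identity (plus a damped residual-branch init
  and centered inputs), making training and inference the same function;
  the scaled-down experiments use it. The full-size default keeps batch
  norm, as in the canonical ResNet18, together with a "precise BN"
  recalibration pass that recomputes the running statistics under the
  final weights.
* **Damped position encodings.** Encoder tokens are raw sensor samples in
  `[0,1]` — there is no learned input embedding — so the sinusoidal
  position table is scaled by 0.1; at full amplitude it dominates the
  signal. Position encoding can be disabled entirely
  (`positional_encoding = "none"`), in which case the encoder is exactly
  permutation-equivariant over tokens (a property test asserts this).

## Preprocessing

Per session: the first and last 3 s are trimmed (start/stop handling
interference); each channel is filtered by the weighted recursive
average `A_k = (1-alpha) A_{k-1} + alpha D_k` with `alpha = 2/(N+1)`,
`N = 5` by default (the filter state starts at the first sample, so a
constant signal is a fixed point); channels are min-max normalized to
`[0,1]`; and 1024-sample windows are cut with a 200-sample stride.

Two normalization scopes exist. The default is **per session**: the
min/max are taken over the whole recording, which preserves the contrast
between vigorous phases (walking) and quiet ones (phone on the table) —
per-window scaling would blow stationary noise up to full scale and
erase exactly the amplitude structure the motion branch needs.
`normalize_scope = "segment"` is available for comparison.

Location images are scaled differently. `form_location_image()` with no
bounds follows a per-window min-max (its documented degenerate contract:
a constant channel maps to an all-zero plane). The pipeline, however,
passes **fixed instrument-range bounds** (±80 µT per magnetometer axis;
0–600 lx, log-scaled, for light): a per-window min-max cancels constant
offsets exactly, and the room fingerprint *is* such an offset — under
per-window scaling, moving all rooms' fields apart would change the
images not at all. Illuminance is log-scaled (`log1p`) before scaling
because indoor light spans decades between day and night and a linear
map crushes all night-time contrast into a few gray levels.

## The synthetic apartment

The simulator generates labeled sessions with the statistical structure
the recognizer assumes, so the whole pipeline is testable without any
private recordings. It is a statistical emulation, not a physical one.

* **Geomagnetics.** Each of six disjoint rooms has an affine field:
  a base vector plus a smooth linear spatial gradient (~1 µT/m) plus
  Gaussian noise (sd 0.5 µT). Base vectors are a shared Earth-field
  component (norm ~48 µT) plus per-room deviations scaled by a single
  `separation` knob; deviations are spread in the coordinates a phone
  with uncontrolled heading can actually resolve — the vertical
  component `Bz` and the horizontal magnitude `|Bxy|` — because a
  heading rotation mixes `Bx`/`By` arbitrarily but preserves those two.
  Base magnitudes stay inside a plausible 20–70 µT indoor band (the
  constructor enforces it).
* **Light.** Per room, a daylight and a night level (e.g. living room
  420 lx day / 60 lx night; bedrooms a few lux at night), drawn per
  session with a 50/50 day/night mix; sensor noise scales with the
  current level (5% + 2 lx).
* **Motion.** Each activity has a phase script (walk, sit-down or
  lie-down transition, stand-with-task, stationary-on-table, or a
  breathing-coupled lie-still phase for sleeping) with duration ranges;
  the last phase stretches to fill the session. Walking contributes a
  ~2 Hz gait oscillation plus sway; transitions contribute half-sine
  pulses in accelerometer and gyroscope; gravity (9.81 m/s², rotated
  with the phone) is included since phones report raw accelerometer.
  Three simulated subjects carry fixed amplitude and gait-timing
  multipliers.
* **Orientation.** The default `handheld` model reflects how people
  actually hold phones: heading uniform over [0, 2pi) and *drifting with
  the walking direction* (a walker faces where they walk), tilt a ~5°
  jitter around screen-up. `random` (uniform over all 3-D rotations) and
  `fixed` exist for the orientation-robustness comparisons, and a
  per-phase re-draw models the hold-then-put-down transition. Under any
  model, `||B||` at a fixed position is rotation-invariant, which the
  tests assert.
* **Trajectories.** An Ornstein-Uhlenbeck-style velocity random walk
  confined to the room rectangle, speed-capped at 1.5 m/s, frozen during
  stationary phases.

Two built-in scenarios install the ambiguities the ablation needs:
`motion-confusable` gives eating and desk work *identical* motion
scripts in different rooms (separable only through location), and
`light-only` makes the living and dining rooms magnetically identical so
that separating the activities in them requires the light channel.

What the simulator does **not** model: real indoor magnetic anomalies
(nonlinear near appliances), body-shadowing of the light sensor,
sensor biases and temperature drift, magnetometer hard/soft-iron
calibration error, and realistic human variability beyond two scalar
multipliers per subject. Passing the synthetic experiments therefore
shows the pipeline learns the *kind* of structure the method posits —
not that it reaches any particular accuracy on real recordings.

## Scaled-down study sizes

The package's defaults state the full-size architecture (ResNet18
widths, 6-layer/8-head encoder, 128/384/512-d features, 300 training
epochs). The experiments run by the test suite and the acceptance script
use scaled-down sizes chosen as deliberate study conditions for a
single-CPU reproduction:

* room-classification study: 16 walking-survey sessions per room of
  26–34 s, LFN widths (12, 24, 32, 48) with one block per stage,
  `norm = "none"`, 30 epochs, Adam 2e-3 decayed to 4e-4, heading
  augmentation on;
* separation-monotonicity study: separations (0.1, 0.5, 1.2), 4
  sessions per room, 4 epochs, 3 seeds;
* ablation study: the `motion-confusable` scenario at ~600 segments
  (14 sessions per activity), MFN with 2 layers / 2 heads / 64-d
  features, fusion output 128-d at rank 4, stage-2 Adam 2e-3; the
  `light-only` scenario slightly smaller. Orderings between variants,
  not absolute accuracies, are the quantities of interest at this scale.

## Numerical and degenerate-input conventions

* Min-max of a constant series returns zeros rather than erroring
  (stationary-phone stretches are common).
* The recursive filter initializes at the first sample — no start-up
  transient; its output is always a convex combination of past inputs.
* Windows are emitted only when complete (`floor((n-len)/step)+1`); a
  session shorter than one window yields none.
* The LMF trailing-1 augmentation is on by default; with it off, any
  all-zero modality annihilates the fused feature to the bias exactly,
  and scaling one modality scales `Zm - b` linearly (multilinearity) —
  both are asserted as tests.
* Softmax ties resolve to the first index; all stochastic steps
  (shuffling, init, augmentation, simulation) run under explicit seeds.

## Known limitations

* The engine is pure R: fine at the scaled study sizes, not meant for
  full-size 300-epoch training.
* The ImageNet-adapted initialization is an adapter (mean-RGB fourth
  channel) for user-supplied weights; the package ships none.
* Checkpoints are R serialization files, not portable across frameworks.
* The simulator's separability knobs make the synthetic tasks honest but
  tunable; conclusions about real data require real recordings.
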