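# lmiar — position-aware indoor activity recognition from smartphone sensors

Compound indoor activities (eating, sleeping, using the bathroom, doing
laundry, cooking, desk work) are hard to tell apart from inertial
sensors alone, because they share the same low-level motions: eating and
desk work are both "walk to a table, sit down, put the phone down".
`lmiar` implements a recognizer that adds the missing context — *where*
the activity happens — using only sensors already in a phone:

* a **location branch** (LFN): 3-axis geomagnetic + ambient-light
  windows are encoded as 32x32x4 images and classified by a
  ResNet18-topology CNN into six rooms; its 128-d penultimate feature
  `Zl` is kept;
* a **motion branch** (MFN): each IMU axis of a 1024-sample window is
  tokenized into 16x64 and passed through a transformer encoder
  (6 layers, 8 heads by default), giving six 128-d features that
  concatenate into accelerometer/gyroscope features `Za`, `Zg` (384-d);
* **low-rank multimodal fusion** (LMF): the trilinear fusion
  `Zm = W (Za ⊗ Zg ⊗ Zl) + b` computed without materializing the
  tensor, via `r = 4` rank-one factors:
  `Zm = b + Σᵢ (waᵢ Za′) ∘ (wgᵢ Zg′) ∘ (wlᵢ Zl′)`;
* a softmax **activity head** on the fused 512-d feature, trained in a
  second stage with the LFN frozen.

The package is self-contained: it carries its own neural-network engine
(convolution, batch/layer norm, multi-head attention, Adam — all with
analytic gradients validated against finite differences), a brute-force
full-tensor oracle that pins down the LMF semantics, a synthetic
apartment/activity simulator so every stage is testable without private
recordings, file I/O for a per-sensor CSV dialect, an ablation harness
(`LM-IAR` vs `LM-IAR-nl` without light vs `M-IAR` motion-only), and a
command-line interface.

## Worked example

Simulate labeled recordings, preprocess them, train the location
network, then train and evaluate the full recognizer:

```r
library(lmiar)

## a scenario where eating and desk work share an identical motion script
sc  <- make_confusable_scenario("motion-confusable")
sim <- sim_config(seed = 1, sessions_per_activity = 14,
                  duration_range = c(26, 34))
sessions <- generate_dataset(sc$apartment, sc$activities, sim)
segments <- preprocess_sessions(sessions, preprocess_config())
split    <- split_dataset(segments, split_spec(0.8, "sequence", seed = 1))

## stage 1: pretrain the room classifier (scaled-down recipe)
set.seed(99)
lfn <- build_lfn(lfn_config(widths = c(8, 16, 32, 32), blocks = rep(1, 4),
                            norm = "none"))
lfn <- train_lfn(lfn, split$train, epochs = 8, lr = 0.002,
                 lr_final = 4e-4, seed = 1)$model

## stage 2: motion branch + fusion + head, LFN frozen
fit <- train_lm_iar(split$train, "LM-IAR", lfn = lfn,
                    mfn_opts    = list(layers = 2, heads = 2,
                                       feature_dim = 64, feedforward_dim = 128),
                    fusion_opts = list(output_dim = 128),
                    epochs = 10, lr = 0.002, seed = 1)
report <- evaluate_model(fit$model, split$test)
report$top1
#> [1] 0.7445255
report$confusion["eating", "desk_work"]
#> [1] 0
```

`top1` is the fraction of held-out windows whose argmax prediction
matches the label; the confusion matrix rows are true classes. On the
same split a motion-only model (`variant = "M-IAR"`) cannot separate
eating from desk work, since the two share an identical motion script
by construction: its top-1 accuracy drops to 0.547 — which is the point
of fusing location in.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/lmiar simulate --scenario motion-confusable --out data/ --seed 1 --sessions 14
Rscript inst/cli/lmiar ablate --scenario motion-confusable --seeds 3 --out ablation.csv
```

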