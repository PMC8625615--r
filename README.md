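# stressclip

Three-level stress recognition (neutral / low / high) from short facial
video clips, for affective-computing researchers who want a fully
inspectable, CPU-only reference implementation of a clip-level
spatial–temporal attention recognizer.

A clip is a fixed-length block of face crops — 48 frames of 112×112 RGB
by default (two seconds at 24 fps) — plus 68-point facial landmark
tracks from an external detector. The model has three parts:

* a from-scratch **ResNet-18 facial branch** whose 4×4×512 feature maps
  `F` pass through a spatial attention module,
  `M_sa = σ(conv7×7([AvgPool(F); MaxPool(F)]))`, and identity-mapped
  attention pooling `f_facial = GAP(F + M_sa ∘ F)` (512 values);
* a small **landmark branch**: landmarks are min–max normalized onto the
  canvas, rendered as white dots, Gaussian-blurred, and passed through a
  three-layer unpadded CNN (112 → 53 → 24 → 9, channels 64/128/256) and
  global average pooling (256 values);
* **temporal attention fusion**: per-frame concatenated features (768)
  are extended by the clip average (1536) and mapped through three fully
  connected layers to one weight per frame; the final feature is
  `f_final = (1/T) Σ w_i f_i`, classified by one linear layer + softmax.

Training minimizes three cross-entropies plus a subject-aware metric
loss: `MSE(f_anchor, f_positive) + max(0, m − MSE(f_anchor, f_negative))`
with margin `m = 2`, where the positive shares the anchor's class but not
its subject, and the negative shares the subject but not the class.
Evaluation is subject-disjoint 5-fold (3:1:1 train/validation/test by
subject), with clip metrics, macro one-vs-rest sensitivity/specificity,
and video-level threshold voting.

There is no deep-learning runtime dependency: forward *and* backward
passes are hand-written (R + compiled float32 convolution kernels), and
every layer's gradient is verified in the test suite. A seedable
synthetic clip generator with planted spatial/temporal cues makes the
whole pipeline testable without any external database.

## Worked example

```r
library(stressclip)

ds <- make_worked_fixture()          # 3 subjects x 3 classes x 2 clips, 8 frames
model <- build_stress_model(model_config(frames_per_clip = 8, seed = 7))
model
#> <stress_model>
#>   frames/clip 8, concat dim 768, 3 classes
#>   spatial attention TRUE | channel attention FALSE | landmark branch TRUE
#>   trainable parameters: 11645799

fwd <- model_forward(model, ds$clips[1:3])
round(fwd$scores, 4)
#>     [,1]   [,2]   [,3]
#> 1 0.0680 0.2056 0.7264
#> 2 0.0701 0.2055 0.7244
#> 3 0.0691 0.2048 0.7261
round(fwd$weights[[1]], 3)
#> [1] 0.466 0.467 0.466 0.467 0.466 0.467 0.466 0.467
```

Before training the scores are an arbitrary, initialization-dependent
constant across clips (the features barely differ yet), and the temporal
attention weights sit near 0.5 — the neutral point of their sigmoid head,
where they are initialized by design. The rows are clips; `fwd$weights`
holds the per-frame temporal attention weights and `fwd$amap` the
16-cell spatial attention map of every frame.
`run_separability_experiment()` performs the full study loop at desk
scale — generate synthetic subjects, train on a subject-disjoint fold,
evaluate held-out subjects, and measure where the spatial attention mass
sits relative to the planted cue cell and how temporal weights split
between cue and non-cue frames.

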