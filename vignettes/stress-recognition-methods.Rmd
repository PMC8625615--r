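---
title: "Clip-based facial stress recognition: model, training and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clip-based facial stress recognition: model, training and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stressclip)
```

## The problem

Stress leaves weak, distributed traces in facial video: brief changes
around the eyes and mouth, small head movements, moments of visible
effort. stressclip implements a clip-level recognizer for three stress
states — neutral, low and high — that consumes short fixed-length blocks
of face crops (by default 48 frames, two seconds at 24 fps, resized to
112×112) together with 68-point facial landmark tracks from an external
detector. Because the informative signal is sparse both spatially (a few
face regions) and temporally (a few frames per clip), the architecture
attaches explicit attention mechanisms on both axes.

## Model

**Facial branch.** A ResNet-18-style residual stack, always trained from
random initialization, maps a 112×112×3 crop to 4×4×512 feature maps
$F$: a 7×7/2 stem convolution, 3×3/2 max pooling, and four residual
stages with outputs 28×28×64, 14×14×128, 7×7×256 and 4×4×512. Stages
2–4 downsample with a 1×1 stride-2 projection shortcut; the printed
stage tables we follow list the stage-opening 3×3 convolution with
stride 1, which is inconsistent with the printed output sizes, so the
main path downsamples in that convolution (stride 2) — the filter
shapes, and hence the parameter count, are unaffected. A spatial
attention map

$$M_{sa} = \sigma\left(\mathrm{conv}_{7\times7}([\mathrm{AvgPool}(F);\,\mathrm{MaxPool}(F)])\right)$$

is computed from channel-wise mean and max maps (zero same-padding keeps
the 4×4 grid), and the facial image feature is the identity-mapped
attention pooling $f_{\text{facial}} = \mathrm{GAP}(F + M_{sa} \circ F)$,
a 512-vector. A squeeze-style channel attention module (shared two-layer
bottleneck, reduction 16) is available behind a configuration flag so
every attention combination of the ablation grid is constructible.

**Landmark branch.** Landmark coordinates are converted to images rather
than fed to dense layers: per-axis min–max normalization maps the
observed coordinate range onto the canvas (cancelling face-box jitter —
a common translation/scaling of all points), the 68 points are rendered
as single white pixels on black, and a truncated Gaussian blur (σ = 2 px,
4σ support, symmetric reflection, then max-rescaling to 1.0) spreads
each dot so residual per-point detector jitter moves mass gradually
instead of toggling pixels. A deliberately small CNN — three
Conv–BN–ReLU blocks, 7×7 kernels, stride 2, **no padding** (112 → 53 →
24 → 9) with 64/128/256 channels — and global average pooling produce a
256-length landmark feature. Normalization, blur, σ, the margin and the
joint (aspect-preserving) normalization variant are all configuration
keys; the paper-silent parameters (σ = 2, margin 4 px, single-pixel dots
before blur) are our choices, selected so a blurred dot spans a few
receptive fields and stays on canvas.

**Temporal fusion.** Per frame, facial and landmark features are
concatenated (768). The clip average feature is appended to each frame
feature (1536), and three fully connected layers (1536 → 1536 → 1536 →
1) yield one attention weight per frame — per frame, never jointly over
a stacked (T+1)-slice input. The final feature is
$f_{\text{final}} = \frac{1}{T}\sum_i w_i f^i_{\text{concat}}$ and one
fully connected layer plus softmax produces the class scores. The
printed equations name no activations inside the weight layers; we use
ReLU between layers and a sigmoid head (bounded weights, matching the
bar-chart visualizations of frame weights), and expose a linear head for
the literal reading. The softmax is likewise our choice: the
cross-entropy below needs scores that behave as probabilities. The
printed output width "3 or 4" we read as 3 classes plus an option,
surfaced as `n_classes`. With the landmark branch disabled every width
contracts (512/1024/512) and the pipeline runs unchanged.

A direct consequence of this construction, tested exactly: permuting the
frames of a clip permutes the weights identically and leaves
$f_{\text{final}}$ — hence the prediction — unchanged.

## Objective and triplet sampling

Within one subject, stress states look nearly alike; within one class,
subjects look very different. The objective therefore combines three
cross-entropies with two metric terms on the final features:

$$L = L_{CE}^{a} + L_{CE}^{p} + L_{CE}^{n}
  + \mathrm{MSE}(f_a, f_p) + \max(0,\, m - \mathrm{MSE}(f_a, f_n)),$$

where the positive $p$ shares the anchor's class but comes from a
*different* subject (pulled together), and the negative $n$ comes from
the *same* subject but a different class (pushed to the margin, m = 2).
MSE is the feature-dimension-averaged squared distance. The features
entering the metric terms are the $f_{\text{final}}$ vectors the
classifier consumes; the source text says only "features extracted
from" the clips, and the classifier input is the only feature shared by
all three clips at equal dimension. Cross-entropy uses an epsilon floor
(1e−12) on the true-class score; behaviorally invisible at test
tolerances. Standard contrastive and triplet losses on the same
features (class-constrained sampling without the subject constraint) are
available as `loss_variant` for the loss ablation.

Training uses SGD (momentum 0.9, weight decay 1e−4 on weight matrices,
not on biases or normalization parameters) with the reference schedule
1e−3 dropped ×0.1 every 15 epochs over 45 epochs. A batch is two
triplets — six clips — matching the memory budget the clip length was
chosen for. Batch statistics are computed over all frames of a batch;
evaluation uses running statistics (momentum 0.1).

## Evaluation protocol

Subjects are split 3:1:1 into train/validation/test by a seeded shuffle
and k-fold rotation (k = 5), so no subject contributes to two sets of a
fold and each subject is tested exactly once across folds — this is what
prevents the network from scoring by memorizing appearance. Clip-level
metrics: accuracy, per-class accuracy, macro one-vs-rest sensitivity and
specificity (the multiclass reduction is unstated in the source; we use
the unweighted macro average), and the 3×3 confusion matrix. Video-level
accuracy uses threshold voting: a video counts as correct when the
fraction of its correctly classified clips *strictly* exceeds the
threshold. Best-epoch selection uses validation accuracy.

## The training engine

No deep-learning runtime is assumed: forward and backward passes are
written in R over compiled float32 convolution, pooling and batch-norm
kernels (im2col + BLAS gemm), with all module-level mathematics —
attention, temporal fusion, losses — in double precision R. Gradients of
every layer are verified in the test suite against independent oracles
and finite differences. He (fan-in) initialization for ReLU layers,
Xavier for linear heads; all initialization, sampling and shuffling
flows from explicit seeds, so training runs are reproducible
bit-for-bit on one platform.

**Stability of the temporal attention head.** Multiplicative bounded
attention has a well-known failure mode that this architecture is
exposed to: early in training, when the per-frame features barely
separate the classes, the cheapest way to reduce the cross-entropy is to
shrink *all* frame weights toward zero — uniform scores cost ln 3,
confident wrong scores cost more — and once the sigmoid saturates at
zero the final feature vanishes and no gradient reaches any earlier
layer. Three standard counter-measures are built in. The weight head is
initialized near zero, so every frame starts at weight 0.5 (the neutral
point of the sigmoid) instead of a random saturation-prone value.
Gradients are averaged (not summed) over the triplets of a batch.
And `train_model()` offers `head_warmup_epochs`: the weight head is held
fixed (uniform pooling) for the first epochs while the backbone,
landmark network and classifier learn, and is released once the features
carry class signal, at which point its gradient differentiates frames
instead of uniformly killing them. The warmup defaults to 0 — the
reference 45-epoch schedule — and the desk-scale experiments use half
their epochs. Because the sigmoid can saturate at 1 late in a confident
run, temporal selectivity is also reported on the pre-sigmoid logit
scale, a strictly monotone transform of the weights.

## Synthetic data: what it emulates and what it does not

The generator produces procedural blob-composite faces, not rendered
humans; the networks consume pixel statistics, and procedural cues give
controllable ground truth. Per subject: a smooth face-like intensity
composite plus a random low-amplitude blob field and channel tints
(appearance variation, sd 0.05), and a deformed 68-point landmark
template. Class identity is encoded two ways: a Gaussian intensity patch
(amplitude 0.6) in a class-specific cell of a 3×3 grid — the spatial
cue — present only in a class-dependent fraction of frames (0.3 / 0.6 /
0.9) — the temporal cue; and a class-dependent mouth-landmark
displacement (1 / 2.5 / 4 px) on the same cue frames, giving the
landmark branch its own signal. Landmark detector noise has two
components scaled by one `landmark_jitter_sd` (default 1 px): a per-frame
offset common to all points (face-box jitter, which min–max
normalization cancels) and i.i.d. per-point noise (which blurring
absorbs). All randomness flows from one seed through named substreams
(appearance / cue / jitter / pixel), so individual factors can be
frozen. Clips of one subject and class share a video identifier,
standing in for the one-video-per-condition recording protocol.

What passing tests on this data do *not* show: robustness to real
illumination, pose, occlusion or identity diversity, or that the planted
cue sizes match the effect sizes of real stressed faces. The synthetic
results validate the *mechanics* — that the spatial attention can find a
localized cue, the temporal attention can find informative frames, the
preprocessing confers jitter robustness, and subject-disjoint
generalization is possible — not field performance.

## Study-scale experiments and numerical choices

The packaged experiments (`run_separability_experiment()`,
`run_jitter_experiment()`) run at a deliberately reduced scale chosen as
a desk-scale analogue of the full study. The separability experiment
uses 10 subjects × 3 classes × 2 clips of 8 frames, subject-disjoint
folds, the full triplet objective, and a 4-epoch constant-rate (0.005)
horizon with a 2-epoch attention warmup — the reference 45-epoch, 1e−3
schedule remains the default for full-scale runs; the short-horizon rate
was chosen once from the training-loss trajectory. It reports held-out
clip accuracy against the 33.3% chance level, video-level voting,
spatial-attention mass inside versus outside the planted cue cell, and
temporal selectivity for cue frames.

The jitter experiment measures what the landmark preprocessing actually
protects: robustness of the learned representation to detector jitter.
Its dataset disables the intensity patch so the class signal flows only
through the landmarks (a mouth displacement of 4/10/16 px in 80% of
frames — larger than the generator default so the task is learnable
within the short horizon); detector jitter is 2 px. Calibration showed
two things worth recording. First, the randomized triplet curriculum
cannot optimize this landmark-only task at desk scale (class-balanced
deterministic batches learn it; random triplet compositions plateau), so
this experiment trains with class-stratified cross-entropy batches
(`batch_scheme = "stratified"`), while the triplet objective is
exercised by the separability experiment. Second, a model trained on two
or three subjects memorizes subject-specific landmark geometry and does
not transfer to unseen subjects at all, so a subject-disjoint comparison
would compare chance with chance. Evaluation is therefore deliberately
within-subject, on held-out clips whose jitter draws are fresh: a
representation that memorized jittered dot patterns fails on them, one
that cancels the jitter transfers. Both configurations — normalization +
blur on, both off — see identical data and training; only the
preprocessing differs.

Numerical details fixed by the implementation: bilinear crop resizing is
center-aligned and edge-clamped; blur padding is symmetric reflection
including the edge pixel; coincident rendered landmarks collapse to one
dot; a degenerate landmark axis maps to the canvas center; remainder
frames beyond the last full clip of a video are discarded (the clip
count bookkeeping of the source is only consistent with per-video
remainder dropping); frame subsampling for long clips is a uniform
duplicate-free draw re-sorted into temporal order; video voting uses a
strict inequality; max pooling breaks ties toward the earliest pixel in
column-major order.

## Known limitations

Single-threaded CPU training bounds practical scale well below the
42,000-clip regime of the real database; the engine exists to make the
method fully testable, not to compete with GPU runtimes. The synthetic
faces carry no speech dynamics, so the neutral-vs-interview confound of
real recordings is not modeled. Channel attention and the contrastive /
triplet loss variants are implemented and tested for construction and
gradients, but the packaged experiments exercise only the default
configuration.
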