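---
title: "Counting dense small objects with a single-keypoint heatmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting dense small objects with a single-keypoint heatmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frycount)
```

## The counting model

`frycount` counts small, densely packed objects — fish fry on a plate,
shrimp larvae, cells — by modelling each object as a *single keypoint* at
the centre of its head. The pipeline has three parts:

1. **Target encoding.** Each annotated head point becomes a 2-D Gaussian
   bump of peak 1 and spread $\sigma$ (default 1 px) on an otherwise zero
   heatmap. Overlapping bumps combine by the element-wise **maximum**, not
   the sum: the training target must stay in $[0,1]$ (it is regressed
   through a sigmoid), and a sum would exceed 1 wherever two objects come
   within a few pixels of each other — exactly the crowded case this method
   exists for. The max rule also preserves a peak of exactly 1 at every
   annotated pixel, which is what the decoder looks for.

2. **Heatmap prediction.** A fully convolutional network maps an
   $H \times W \times 3$ image to an $H \times W$ score heatmap (head
   variant `"TDM"`). Training minimises the per-value mean squared error
   $\mathrm{Loss} = \frac{\lambda}{n}\sum_i (y_i - \hat y_i)^2$ with $n$
   the total number of heatmap values. Interpreting $n$ as the value count
   (rather than, say, the object count) is the only reading that makes
   $\lambda = 1$ scale-free across image sizes.

3. **Local-peak decoding.** A pixel is a detection iff its score equals
   the maximum of the $k \times k$ window centred on it (max-pooling with
   stride 1; the window clips at borders) *and* reaches the score
   threshold. The count is the number of detections; their coordinates
   locate the objects. Equal-valued plateau pixels inside one window are
   **all** kept — the equality test keeps every point of a flat maximum.
   This is a documented over-count source for genuinely flat regions, but
   with Gaussian-peaked targets plateaus essentially never arise.

### Why full resolution matters

Predicting the heatmap at $1/s$ of the input resolution quantises
coordinates: a keypoint at coordinate $c$ lands on heatmap cell
$\lfloor c/s \rfloor$ and maps back to $s\lfloor c/s \rfloor$, an error of
up to $s - 1$ pixels per axis (3 px at the common $s = 4$;
`quantizedCoordError()` demonstrates the bound exhaustively). For objects
a handful of pixels wide, 3 px is enough to merge neighbours. The head of
the network therefore restores full resolution with two stride-2
transposed convolutions before decoding.

## Architecture

The feature extractor keeps **two parallel branches at fixed resolutions**
instead of a low-to-high recovery path:

* a stem of two 3×3 stride-2 convolutions (to 1/4 resolution, 64
  channels), then four bottleneck residual blocks expanding to 256
  channels;
* a transition creating branch 1 (48 channels, 1/4 resolution) and branch
  2 (96 channels, 1/8 resolution — twice the channels at half the
  resolution);
* three dual-branch stages of four basic residual blocks per branch, with
  cross-branch fusion after each stage — bidirectional in the first two
  stages, into branch 1 only in the last.

The head then applies the configured number of 4×4 transposed-convolution
modules (each batch-normalised and rectified) and a 1×1 convolution with a
sigmoid:

| head variant | deconvolutions | heatmap size |
|---|---|---|
| `NONE` | 0 | H/4 × W/4 |
| `ODM1` | 1, stride 2 | H/2 × W/2 |
| `ODM2` | 1, stride 4 | H × W |
| `TDM`  | 2, stride 2 each | H × W |

With the default configuration the model has 3.32 million trainable
parameters (`countParameters(buildModel())`), small for this accuracy
class because high resolution is bought with depth-limited dual branches
rather than width.

### Design choices where the architecture description is open

* **Fusion operator.** The branch-fusion step is described as a
  concatenation, but no channel-reduction convolutions are specified, and
  concatenation would change branch widths after every stage. We implement
  HRNet-style *additive* fusion — 1×1 convolution + batch norm +
  nearest-neighbour upsampling for the high-resolution target, 3×3
  stride-2 convolution + batch norm for the low-resolution target,
  element-wise sum, then ReLU. The resulting total of 3,323,761 trainable
  parameters reproduces the published 3.32 M budget, which is the
  strongest available evidence for this reading.
* **Transposed-convolution geometry.** Only the strides are prescribed; we
  use kernel 4 with padding 1 (stride 2) and padding 0 (stride 4), the
  standard settings for exact 2× and 4× upsampling.
* **Output squashing.** The output activation is unnamed; a sigmoid is the
  natural choice since the regression targets live in $[0,1]$.
* **Bottleneck expansion 4** (64 → 256 across stage 1) and batch
  normalisation + ReLU after every convolution follow the residual-network
  conventions the block names refer to.
* **Initialisation.** Fan-in-scaled Gaussian weights; no pretrained
  backbone is loaded. The final 1×1 convolution starts with small weights
  and bias −4.6, so the initial heatmap sits near the empty background
  (sigmoid ≈ 0.01) — with targets that are ~99.9 % zeros this avoids a
  large wasteful first gradient step.

## Training protocol

Defaults mirror the published recipe: Adam at base learning rate
1.5×10⁻³ dropping to 1.5×10⁻⁴ and 1.5×10⁻⁵ at (0-based) epochs 20 and 60,
batch size 4, $\sigma = 1$, $\lambda = 1$, input scaled to the configured
square size, and augmentation by horizontal flip (p = 0.5), uniform random
scale in [0.75, 1.5] and rotation in [−30°, 30°]. Points undergo exactly
the image transform; points leaving the canvas are dropped. Two details
the recipe leaves open:

* **Augmentation order** is fixed as flip → scale → rotate (recorded so
  runs are reproducible; the listed operations commute only partially).
* **Targets are encoded after augmentation** from the transformed points,
  never by warping pre-built heatmaps — interpolating a heatmap attenuates
  its peaks below 1 and corrupts the decoder's plateau test.
* **Checkpoint selection**: when validation samples are supplied, the
  weights of the best validation-MAE epoch are restored at the end.
* **Score threshold**: the inference threshold is not part of the
  published recipe. The default is 0.5 (the midpoint of the score range,
  and the value under which exact encode→decode round trips hold);
  `calibrateThreshold()` selects it on validation data by minimum counting
  MAE (ties resolved toward the 0.5 default), which is how the evaluation
  protocol here fixes it.

## The synthetic scene generator

Real benchmarks in this domain (dense fry photographed on a bright plate)
are large downloads and need GPU-scale training. The simulator instead
emulates their variability axes so the whole pipeline is exercisable on a
laptop CPU: dark elongated capsule bodies with a distinctly darker round
head blob (the annotation point — the keypoint must be visually
identifiable, so the simulator renders the head, not the centroid, as the
distinctive landmark), a bright background with a random linear
illumination gradient (lighting variance), Gaussian pixel noise and a
turbidity blur (water variance), and free body overlap unless a minimum
head separation is requested (density variance). Scenes are bit-for-bit
reproducible from their seed.

What it does **not** model: perspective, specular reflections, partial
fish at frame borders, motion blur, and fry whose head is occluded by
another body. Passing the recovery test below therefore shows that the
architecture, losses, codec and training loop are correctly wired and can
fit this family of appearances — not that the desk-scale model would reach
the published accuracy on real photographs.

## Desk-scale problem sizes

The package's self-contained recovery experiment (see
`test-acceptance.R`) trains `reducedModelConfig()` — 16/32-channel
branches, two bottlenecks to 64 channels, one dual-branch stage, 16
channel head, ~0.14 M parameters — on 200 easy 160×160 scenes of 10–60
fry (high contrast, 8 px head separation, mild noise) for 10 epochs with
flip-only augmentation, calibrates the threshold on 40 validation scenes,
and requires relative-error accuracy ≥ 85 % on 40 held-out scenes. These
sizes were chosen so the whole experiment runs in minutes on a single CPU
core while keeping every architectural element (both branches, fusion,
both deconvolutions) in play. The full 1024×1024 / 48-channel / 500-epoch
configuration remains the default for GPU-scale use.

## Numerical notes and degenerate inputs

* Decoder borders: the neighbourhood maximum is computed with the window
  clipped at image edges — equivalent to padding with −∞ (or zero, since
  scores are non-negative).
* Detections are reported in row-major traversal order with 0-based
  (row, col) coordinates; continuous annotation coordinates are rounded to
  the nearest pixel centre at encode time.
* Gaussian bumps are truncated at `ceiling(3 * sigma)` pixels; beyond 3σ a
  bump contributes < 0.012, irrelevant to peak decoding.
* Counting accuracy is left **unclamped**: a prediction off by more than
  the ground truth contributes a negative term. Group reports always
  recompute the `Total` row from the concatenated pairs, never by
  averaging group metrics. The median of an even-length error list is the
  mean of the two central values.
* An empty point list encodes to an all-zero heatmap; an all-zero heatmap
  decodes to an empty result. Batch-norm running variance updates are
  skipped for single-value channels.
* Forward passes require height and width divisible by 8 (the deepest
  branch runs at 1/8 resolution); violations are reported with the
  required divisibility, not silently padded.

## Known limitations

* One keypoint class per model: categories cannot be counted separately
  in one pass.
* The keypoint must uniquely identify an object; objects with two
  indistinguishable landmark-like parts will be double-counted.
* Plateau decoding over-counts genuinely flat high-score regions.
* The native-R training loop is deliberately CPU-sized; the full
  1024×1024 configuration trains, but at GPU-framework speeds it does not.
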