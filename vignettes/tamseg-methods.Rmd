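---
title: "Segmenting single macrophages: models, losses and evaluation in tamseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting single macrophages: models, losses and evaluation in tamseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Tumor-associated macrophages (TAMs) in CD163/DAB-stained liver tissue appear
as brown, irregular, blurry-edged cells over a blue hematoxylin background.
Their morphology carries prognostic information — small and large TAMs behave
differently — so the quantity of interest is not just *where* macrophage
pixels are but the area of *each individual cell*. That turns a semantic
segmentation problem (pixel classification) into an instance segmentation
problem (pixel-to-cell assignment), and the failure mode that matters most is
merging adjacent, touching cells into one object.

`tamseg` implements and compares the three strategies built around small
encoder–decoder convolutional networks (UNet-, SegNet- and DeepLab-v3-style
families):

1. **Vanilla semantic segmentation** — per-pixel two-class cross-entropy;
   instances are the 8-connected components of the thresholded foreground.
   Touching cells necessarily merge.
2. **Per-pixel penalty semantic segmentation** — the same, but the
   cross-entropy is weighted by a per-pixel map that multiplies the penalty
   in narrow background corridors between nearby cells (default 3x for
   corridors where two distinct cells are both closer than 10 px) and
   discounts the blurry cell rims (default 0.5x on boundary pixels). The
   model is pushed to keep gaps open, at some cost in raw overlap quality.
3. **Pixel-embedding instance segmentation** — the decoder branch is
   duplicated; the second decoder emits an n-dimensional embedding per pixel,
   trained with a discriminative pull/push loss so pixels of one cell
   cluster tightly and different cells' clusters stay apart. At prediction
   time, mean-shift clustering of the foreground embeddings yields the
   instances; touching cells can be separated because they form distinct
   clusters even when their silhouettes are connected.

## Evaluation statistics

For a predicted foreground $P$ and ground truth $T$:

$$\mathrm{IoU} = \frac{|P \cap T|}{|P \cup T|}, \qquad
  \mathrm{Dice} = \frac{2|P \cap T|}{|P| + |T|} = \frac{2\,\mathrm{IoU}}{1 + \mathrm{IoU}}.$$

Instance agreement uses Best Dice: for label masks $L^a$ (M instances) and
$L^b$ (N instances),

$$\mathrm{BD}(L^a, L^b) = \frac{1}{M} \sum_{i=1}^{M} \max_{1 \le j \le N}
  \frac{2|L_i^a \cap L_j^b|}{|L_i^a| + |L_j^b|},$$

which is not symmetric (a prediction containing one perfect instance plus
spurious extras scores BD = 1 in one direction). The Symmetric Best Dice
takes the worse direction:

$$\mathrm{SBD} = \min\{\mathrm{BD}(X, Y),\ \mathrm{BD}(Y, X)\}.$$

`evaluate_dataset()` reports per-image IoU (always on the binarized
foreground, so all strategies share one IoU definition) and SBD, aggregated
as dataset mean and **per-image sample standard deviation** on the percent
scale. Whether published tables of this shape use per-image or per-run
dispersion is usually unstated; this package computes the per-image sample
standard deviation and says so.

Empty-mask conventions: two empty masks score 1 (predicting clean background
on an empty tile is not an error), one empty mask scores 0. Instance-level
Dice always uses pixel sets, never bounding boxes.

## The discriminative embedding loss

With embeddings $e_p$, instance pixel sets $S_k$ ($k = 1..M$) and centroids
$\mu_k$:

$$\mathcal{L} = \alpha \cdot \frac{1}{M} \sum_k \frac{1}{|S_k|} \sum_{p \in S_k}
  \max(0, \|e_p - \mu_k\| - \delta_v)^2
  + \beta \cdot \frac{1}{\binom{M}{2}} \sum_{j<k}
  \max(0, 2\delta_d - \|\mu_j - \mu_k\|)^2
  + \gamma \cdot \frac{1}{M} \sum_k \|\mu_k\|.$$

Defaults: $\delta_v = 0.5$, $\delta_d = 1.5$, $\alpha = \beta = 1$,
$\gamma = 0.001$. The loss is zero (at $\gamma = 0$) exactly when every
instance is contained in a $\delta_v$-ball and all centroid pairs are at
least $2\delta_d$ apart; $\delta_d > 2\delta_v$ guarantees clusters are
separable by any merge radius in $(\delta_v,\ 2\delta_d - \delta_v)$. A
single instance has no push term. The loss depends only on the pixel
partition, never on instance id values or pixel order.

Training computes the loss over ground-truth instances; clustering happens
only at prediction time. Mean shift (flat kernel) runs on foreground pixels
only; its bandwidth defaults to $\delta_v$, the pull margin. For the
desk-scale experiment below we pass bandwidth $1.5$ — still inside the
separability band $(\delta_v, 2\delta_d - \delta_v) = (0.5, 2.5)$ — because
partially converged embeddings have within-cluster spread well above
$\delta_v$, and every bandwidth in the band recovers the same partition
once training is converged. Clusters below `min_size` (default 10 px) are
treated as speckle and reassigned to the nearest surviving mode; the
optional spatial-coherence step additionally splits clusters into
8-connected components and absorbs sub-`min_size` fragments into the
neighbour with the longest shared boundary.

## Networks

All three families map an RGB patch to full-resolution class scores;
`base_channels` scales the width so a `base_channels = 4` network stays
under $10^5$ parameters and trains on one CPU. The DeepLab-style family uses
a stride-4 encoder with a three-rate (1/2/4) atrous pyramid, and bilinearly
upsamples its stride-4 head outputs to input resolution; a
MobileNet-v2-style backbone (inverted residual blocks with depthwise
convolutions, no pretrained weights) is available as an option. UNet uses
skip concatenations, SegNet max-unpooling with encoder argmax indices.

Two deliberate design choices where the design was genuinely open:

* **Coordinate channels.** The instance variant appends two normalized pixel
  coordinate channels to the input (off by default for semantic variants).
  A translation-invariant convolutional network cannot assign two
  identical-looking touching cells to different embedding clusters without
  positional information; with coordinates it can learn offset-like
  embeddings.
* **No normalization layers.** At these widths Adam with He initialization
  trains stably without batch/group norm, and omitting normalization keeps
  the hand-written backward pass small and exactly testable.

Checkpoints are RDS files with a JSON manifest of the `model_config`, so a
saved model rebuilds itself.

## Training

Adam with learning rate $10^{-4}$; the rate halves whenever the training
loss fails to improve by more than a relative $10^{-4}$ for 15 consecutive
optimizer steps ("iterations" are optimizer steps, not epochs). Training
stops early when the validation loss exceeds its running best by 5% on 10
consecutive validation checks — a concrete reading of "validation loss
diverges from training loss" — and the best-validation weights are returned.
Batch size defaults to 8 (2 in the desk-scale runs). Every random choice
(initialization, batch sampling, augmentation, patch offsets) sits behind
one seed; two runs with the same seed produce bit-identical loss traces.

Strategy losses: vanilla = mean pixel cross-entropy; weighted = weight-map
scaled cross-entropy (reduces exactly to vanilla under a unit map);
instance = cross-entropy plus `disc_weight` times the discriminative loss.
`disc_weight` defaults to 1 (unit weights between the terms). In the tiny
unnormalized networks the discriminative gradients reaching the shared
encoder are roughly two orders of magnitude larger than the cross-entropy
gradients, and at unit weight they destroy the semantic head (its IoU
collapses to ~0 while the embedding objective monopolizes the encoder). Two
measures keep joint training stable: the embedding head's final convolution
is initialized at 1/100 of He scale (embeddings start near-collapsed, so
early hinge violations are bounded), and the desk-scale experiment trains
with `disc_weight = 0.1`. Both are package-level engineering choices and do
not change the loss definition.

## Per-pixel weight maps

A background pixel is a *gap* pixel when its Euclidean distances to the
nearest pixels of its two nearest **distinct** instances are both strictly
below `proximity_px` (default 10) — the "pixels lying between cells" reading,
computed with one exact distance transform per instance. Gap pixels get
`gap_weight` (default 3) times the base weight. Foreground pixels 8-adjacent
to background (band depth 1, configurable) get `edge_weight` (default 0.5);
off-grid counts as background, so cells clipped by the tile border keep
their rim. The discount can optionally extend to background pixels abutting
cells (`edge_on_background`), the alternative reading of a blurred rim. The
map depends only on instance geometry and is invariant under relabeling.

## Augmentation and splitting

Geometric transforms (rotation at any angle; scaling and shear with factors
drawn from (0.8, 1.3); smooth elastic warp) are applied identically to
image, mask and weight map — bilinear with mirror padding for image and
weights, nearest-neighbour with background fill for labels, so fractional
instance ids cannot arise. Photometric transforms (per-channel color jitter,
contrast, hue rotation, exposure; amplitudes default ±10%, a package choice
the source protocol leaves open) touch the image only. Each enabled
transform fires independently with probability 0.5. A transform that wipes
out all instances is retried a bounded number of times.

Dataset splitting is at the **patient** level: whole patients are assigned
70/15/15 to train/validation/test (`round(fraction * n_patients)` for
validation and test, remainder to train), so tiles from one patient never
straddle partitions. `run_experiment()` refuses to run if any patient
appears in two splits.

## The synthetic tile generator

Real annotated slides cannot ship with a package, so `generate_tile()`
fabricates the geometry the methods care about, with exact ground truth:

* cells are ellipses with truncated-Fourier radial perturbation (harmonics
  2–5) — irregular borders; large cells get lighter "foamy" inclusions;
* a configurable fraction of cells is placed as adjacent pairs — half
  overlapping or touching outright (contested pixels resolved by normalized
  radial coordinate so instances never share pixels), half separated by a
  thin 1–2 px annotation-style gap whose corridor is nevertheless *rendered
  in foreground stain*: as in real material, the stain runs continuously
  across adjacent cells and only the ground-truth mask separates them. This
  is what makes adjacent cells genuinely hard for color-driven semantic
  models and gives the corridor penalty something to act on; other cells
  keep a minimum silhouette gap, and cells may clip the tile border as in
  real tiles;
* foreground is DAB-brown with per-cell tone jitter, background is
  hematoxylin blue-gray with darker nucleus-like blobs; the rendered image
  (never the mask) is Gaussian-blurred and noised, emulating blurry edges;
* everything derives from one integer seed; the same spec is bit-for-bit
  reproducible. `generate_dataset()` adds per-patient density and stain-tone
  jitter so patient-level splitting is meaningful, and
  `make_touching_fixture()` builds two-disc tiles with an exact closest-
  approach gap for corridor and merge/split tests.

What the generator does **not** emulate: real stain variability between
laboratories, out-of-focus regions, necrosis, other brown-ish cell types,
annotation error. Passing tests on synthetic tiles therefore demonstrates
that the pipeline's machinery works — losses shape what they should shape,
clustering separates what the loss separates, metrics measure what they
claim — not that any fixed hyperparameter set transfers to clinical slides.

## Desk-scale experiment sizes

The shipped end-to-end experiment (also what `scripts/acceptance.R` runs)
uses 67 synthetic patients x 3 tiles = 201 tiles of 128x128 px with 5 cells
per tile, radii 9–18 px (diameters ~18–36 px, within the tens-of-pixels
cell-diameter regime of 60x magnification source material),
`touching_pair_fraction = 0.3`, and tiny DeepLab models
(`base_channels = 8`, `embedding_dim = 8`, batch 2, full-tile 128-px
patches so the coordinate channels are scale-consistent between training
and prediction). These sizes are the package's chosen desk-scale study
conditions: large enough for the strategy differences to be measurable,
small enough to train all three strategies on one CPU in minutes.

## What the desk-scale comparison does and does not show

The shipped three-strategy comparison (UNet vanilla, UNet weighted with a
2-px edge band, DeepLab instance with push weight `beta = 4`, atrous rates
1/4/8, `disc_weight = 0.1`, extraction bandwidth 1.5 with a 40-px minimum
size and spatial cleanup) reproduces the *mechanisms*: the vanilla baseline
fuses touching cells into one component, the per-pixel penalty measurably
improves separation over the baseline at a small IoU cost, and the
embedding pipeline splits silhouette-connected pairs that no semantic
strategy can split (on the gap-0 two-cell fixture it returns two instances
where connected components return one).

It does **not** reproduce the full magnitude ordering seen on clinical
material, where instance segmentation dominates both semantic strategies
by a wide SBD margin. On synthetic tiles, color alone nearly solves the
semantic task, so both semantic strategies score far higher SBD (~79–81%)
than semantic models do on real slides, while the embedding pipeline's
matched-instance Dice is capped (~0.85) by mean-shift boundary raggedness
of the stride-4 embedding head. The result is a compressed comparison in
which the instance strategy clearly wins on adjacent-pair separation but
not on overall SBD. Real IHC tiles — where trivial color rules fail and
cells crowd densely — are exactly the regime in which the semantic scores
collapse and the embedding approach pulls ahead.

## Known limitations

* Mean shift is quadratic in foreground pixel count per seed set; very
  dense tiles should raise `max_seeds` subsampling or tile the prediction.
* The stride-4 DeepLab head bilinearly upsamples embeddings, which blurs
  them across instance boundaries in a ~4 px halo; with cells much smaller
  than ~20 px diameter this halo dominates the matched-instance Dice.
* The hand-written network engine is CPU-only and double-precision;
  full-size (224-px patch, wide) training is possible but slow — the
  architecture is faithful, the widths are desk-scale.
* `classify_by_area()` requires an explicit area cutoff; the package
  deliberately ships no clinical S/L threshold.
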