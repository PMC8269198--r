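# tamseg

Instance segmentation and morphometry of CD163-stained macrophages in
immunohistochemistry image tiles.

## The problem

In CD163/DAB-stained tissue, tumor-associated macrophages (TAMs) appear as
brown, irregular, blurry-edged cells over a blue hematoxylin background.
Because the *area of each individual cell* is the biologically meaningful
readout (small and large TAMs carry different prognoses), the computational
task is instance segmentation: not just classifying macrophage pixels, but
assigning every pixel to a single cell — and in particular *not* merging
adjacent, touching cells into one object, which is exactly where plain
semantic segmentation fails.

`tamseg` implements three trainable strategies on small encoder–decoder
convolutional networks (UNet-, SegNet- and DeepLab-v3-style families, with
an optional MobileNet-v2-style backbone):

* **vanilla** — per-pixel cross-entropy; instances are 8-connected
  components of the thresholded foreground;
* **weighted** — the same cross-entropy scaled by a per-pixel penalty map:
  background corridors where two distinct cells are both closer than 10 px
  get ~3x weight, blurry cell rims get 0.5x;
* **instance** — a duplicated decoder branch emits a pixel embedding
  trained with a discriminative pull/push loss
  (pull margin δv = 0.5, push margin δd = 1.5); mean-shift clustering of
  the foreground embeddings at prediction time yields the instances.

Around the strategies the package provides the full working apparatus: the
IoU / Dice / Best Dice / Symmetric Best Dice (SBD) evaluation suite with
dataset-level aggregation, per-pixel weight-map generation, geometric and
photometric augmentation, patient-level 70/15/15 splitting with a leakage
guard, per-instance morphometry (area, centroid, boundary length, S/L
classification by area), overlapped-tile prediction with seam-free
stitching, and a deterministic synthetic generator of stained-cell tiles
with exact ground-truth masks so everything is testable without clinical
material.

The evaluation centrepiece is the Symmetric Best Dice

    BD(La, Lb) = mean_i max_j  2 |Lai ∩ Lbj| / (|Lai| + |Lbj|)
    SBD(X, Y)  = min{ BD(X, Y), BD(Y, X) }

which scores instance *separation*: a model that finds all macrophage
pixels but fuses neighbouring cells has high IoU and low SBD.

The convolutional network engine (convolutions with stride, dilation and
groups; pooling/unpooling; bilinear resizing; backpropagation; Adam) is
implemented in the package itself (RcppArmadillo), verified by
finite-difference gradient checks in the test suite.

## A worked example

Train a tiny DeepLab-family instance-segmentation model on synthetic tiles
and evaluate it on a held-out patient split (a few minutes on one CPU):

```r
library(tamseg)

spec <- synthetic_tile_spec(height = 128, width = 128, n_cells = 5,
                            cell_radius_range = c(9, 18),
                            touching_pair_fraction = 0.3, min_gap_px = 6)
samples <- generate_dataset(n_patients = 20, tiles_per_patient = 3,
                            spec = spec, seed = 100)
split <- split_by_patient(samples, seed = 7)

cfg <- experiment_config(
  model_config("deeplabv3", base_channels = 8, embedding_dim = 8,
               aspp_rates = c(1, 4, 8)),
  train_config("instance", batch_size = 2, max_iters = 400,
               patch_size = 128, disc_weight = 0.1,
               disc_params = disc_loss_params(beta = 4),
               min_lr = 2.5e-5, seed = 42),
  evaluation = list(threshold = 0.5, bandwidth = 1.5, min_size = 40,
                    spatial_clean = TRUE))
res <- run_experiment(cfg, split)
res$report
#> Metric report (9 images) — deeplabv3 / instance
#>   IoU  81.5061 ± 3.69 %
#>   SBD  67.7458 ± 9.40 %
```

The report holds per-image IoU and SBD plus dataset mean ± per-image sample
standard deviation on the percent scale (the IoU row says "81.5% of
predicted ∪ true foreground is shared"; the SBD row scores how faithfully
single cells are separated). On a touching-cell fixture the semantic
baseline merges what the instance pipeline splits:

```r
fx <- make_touching_fixture(gap_px = 0, seed = 3)   # two cells, silhouettes touching
n_instances(fx$truth)                               # 2 by construction
# vanilla: connected components of the foreground -> the pair fuses into 1
# instance pipeline: mean-shift on embeddings     -> 2 instances recovered
```

Per-instance morphometry for downstream S/L-type analyses:

```r
pred <- predict_instances(res$model, samples[[1]]$image, "instance",
                          patch_size = 128, bandwidth = 1.5, min_size = 40,
                          spatial_clean = TRUE)
stats <- instance_stats(pred, um_per_px = 0.25)
head(classify_by_area(stats, cutoff_um2 = 40), 3)
#>   instance area_px area_um2 centroid_row centroid_col boundary_px size_class
#> 1        1     400  25.0000     11.36000      9.75500          81          S
#> 2        2     409  25.5625     60.86797     20.55990          89          S
#> 3        3    1042  65.1250     30.22361     68.69386         190          L
```

A thin command-line front end (`inst/cli/tamseg`) exposes
`synth | train | predict | evaluate | grid` over the same functions.

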