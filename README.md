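# lesionviz

Opening the black box of convolutional neural networks (CNNs) used for
image-based plant-disease diagnosis.

A CNN that classifies leaf photographs into disease categories reports *what*
it decided, never *why*.  For a plant pathologist the "why" is the whole
point: a trustworthy model should be looking at the lesion — its color,
texture, size and count — and not at the background or the leaf outline.
`lesionviz` implements, in plain R, the four families of visualization that
make this checkable, plus the infrastructure needed to exercise them end to
end on a single CPU:

* **a minimal layer-graph network engine** — conv / batchnorm / relu /
  pooling / global-average-pooling (GAP) / dense / concat / softmax layers
  with exact forward and backward evaluation, an InceptionV3-like builder
  with canonical parameter accounting, truncation surgery, and an Adam
  training loop with lowest-validation-loss model selection;
* **a synthetic leaf-lesion image generator** — single leaf on a uniform
  background, disease classes distinguished *only* by their lesions, with
  ground-truth lesion masks and a 6:2:2 train/validation/test split, so every
  visualization claim becomes a measurable overlap statistic;
* **four visualization families**
  1. hidden-layer output grids and Shannon-entropy scoring,
  2. feature visualization (activation maximization) by Adam ascent in a
     color-decorrelated Fourier parameterization,
  3. a *semantic dictionary* at the GAP layer: the pre-softmax class score
     decomposes exactly as `logit_j = Σ_k a_k W[k,j] + b_j`, so each GAP
     neuron carries a per-class contribution score, and top contributors are
     paired with their feature-visualization renders,
  4. eight attention-map algorithms — occlusion, LIME-style superpixel
     surrogate regression, vanilla / guided back-propagation, integrated
     gradients, Grad-CAM with free layer targeting, DeepLIFT (rescale rule),
     and a forward-only explanation map normalized against healthy-reference
     activation thresholds;
* **evaluation and layer shaving** — lesion-overlap metrics (sensitivity as
  heat mass on the lesion, specificity, IoU, pointing game),
  misclassification inspection with background-attention statistics, and the
  truncate-and-transfer-learn experiment that quantifies how many feature
  layers a task actually needs.

The headline arithmetic the engine reproduces exactly: the 38-class
InceptionV3-like model carries **21,880,646** parameters; cutting it after
`Mixed5` and attaching a fresh GAP + 38-class head leaves **5,167,878** — a
**76.4 %** reduction — while the GAP feature vector of the full model is
2048-dimensional and `Mixed10` sits at 7 × 7 for a 224 × 224 input.

## Worked example

Parameter accounting needs no data and runs in seconds:

```r
library(lesionviz)

g <- build_inception_v3_like(38, input_size = 224, init = "zeros")
count_parameters(g)
#> <param_report> total 21,880,646 (trainable 21,846,214, non-trainable 34,432)
g$shapes[["GAP"]]        # 2048
g$shapes[["Mixed10"]]    # 7 7 2048

shaved <- truncate_at(g, "Mixed5", 38)
count_parameters(shaved)
#> <param_report> total 5,167,878 (trainable 5,156,358, non-trainable 11,520)
param_reduction_pct(g, shaved)
#> [1] 76.38245
```

The non-trainable counts are the batchnorm moving statistics, which are
stored with the model and therefore included in the totals.

A full desk-scale experiment — generate the synthetic four-class task, train
the fixture classifier (~1–2 min on one CPU), and ask *where it looks*:

```r
splits <- make_dataset(default_class_specs(), n_per_class = 40, seed = 101)
splits
#> <dataset_splits> 4 classes, 64x64 px; train 96 / validation 32 / test 32

model <- make_fixture_model(splits)
attr(model, "test_metrics")[c("loss", "accuracy")]
#> $loss
#> [1] 0.02928071
#> $accuracy
#> [1] 1

sample <- Filter(function(s) s$label == 2, splits$test)[[1]]  # brown-spot leaf
cam <- grad_cam_map(model, sample$image, class = 2, layer = "Conv2")
overlap_metrics(cam, sample$mask)
#> # A tibble: 1 × 4
#>   sensitivity specificity   iou pointing_hit
#>         <dbl>       <dbl> <dbl> <lgl>
#> 1       0.813       0.990 0.637 TRUE
```

81 % of the Grad-CAM heat mass lands on lesions that cover ~7 % of the image,
and the map's maximum is inside the annotated lesion — the classifier looks
where a pathologist would.  Scanning the target layer shows the
characteristic profile: the *intermediate* layer localizes best, not the
deepest one:

```r
scan <- layer_scan(model, sample$image, "grad_cam",
                   c("Conv1", "Conv2", "Conv3"), class = 2,
                   mask = sample$mask)
scan$summary
#>   layer  h  w sensitivity specificity       iou pointing_hit
#> 1 Conv1 64 64   0.3344223   0.9113889 0.6756757         TRUE
#> 2 Conv2 32 32   0.8127428   0.9896955 0.6370107         TRUE
#> 3 Conv3 16 16   0.4639958   0.9537332 0.5281690         TRUE
```

`autoplot(cam, image = sample$image)` overlays the heatmap on the leaf;
`shave_series(model, c("Conv1","Conv2","Conv3"), splits)` runs the
truncation-plus-transfer-learning series and tabulates parameters against
test accuracy.  A thin command-line wrapper (`inst/cli/lesionviz`) scripts
the same steps: `synth`, `train`, `hidden`, `featviz`, `dict`, `attmap`,
`scan`, `shave`, `report`.

See the methods vignette (`vignettes/interpreting-cnns.Rmd`) for the models,
the propagation rules, every tunable default and the package's numerical
choices.

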