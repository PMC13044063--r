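# garlicnet

Two-stage detection of post-harvest garlic bulb damage from RGB images:
threshold-based foreground segmentation, then classification with a
ResNet34-family convolutional network that can be configured with depthwise
second convolutions, squeeze-and-excitation (SE) channel attention, SiLU
activation and a parameter-free nested residual skip — the combination known
as DH-GarlicNet. The package targets researchers and engineers in produce
quality inspection who need a fully reproducible, dependency-light reference
implementation of this pipeline, including its resource accounting.

## What it implements

**Segmentation.** Bulbs are photographed on near-black cloth, so a grayscale
conversion (Rec.601 luma), a fixed binarization threshold of 0.3, a pixelwise
mask multiply and largest-8-connected-component extraction isolate the bulb
with its contour and a tight bounding box.

**Classifier.** Basic residual blocks `y = act(BN(conv2(act(BN(conv1(x))))) +
shortcut)` in the classic (3, 4, 6, 3) stage plan. Toggles: the second 3×3
convolution of every block can be depthwise (parameters `K²C` instead of
`K²C²`), SE gates (`sigmoid(W2 relu(W1 gap(x)))`) rescale the branch
channels, SiLU `x·σ(x)` replaces ReLU, and a parameter-free inner identity
skip nests a second residual level inside each shape-preserving block.

**Accounting.** Closed-form parameter and multiply-accumulate (MAC) counts
per layer and per architecture: standard convolution `K²·C_in·C_out` params /
`K²·C_in·H·W·C_out` MACs, depthwise `K²·C_in` / `K²·C_in·H·W`, BN `2C`
params, linear `in·out` MACs. At 224×224 with a 1000-way head the baseline
counts 21,797,672 parameters (21.8 M) and 3.66 G MACs; the depthwise variant
10,514,408 (10.5 M) and 1.82 G.

**Pipeline.** Deterministic ×3 offline augmentation (noise + rotation),
6:2:2 and stratified k-fold split arithmetic, minibatch SGD training
(batch 8, lr 0.01, cross-entropy) with confusion-matrix / precision / recall
/ F1 evaluation, and Grad-CAM heatmaps over the final convolutional stage.
A seeded generator of garlic-like synthetic images (bright clove-ridged bulb
on dark background, class-dependent damage patch with ground-truth geometry)
makes every stage testable without any external data.

## Worked example

```r
library(garlicnet)

# resource accounting of the depthwise substitution
profile_arch("resnet34")
#> <garlic_profile> resnet34 @ 224x224, 1000 classes
#>   parameters: 21,797,672 (21.8 M)
#>   MACs:       3,663,761,408 (3.66 G)
#>   weights:    87,190,688 bytes at fp32
profile_arch("resnet34_dwconv")
#> <garlic_profile> resnet34_dwconv @ 224x224, 1000 classes
#>   parameters: 10,514,408 (10.5 M)
#>   MACs:       1,826,491,904 (1.82 G)
#>   weights:    42,057,632 bytes at fp32
```

The depthwise substitution halves both figures: per block it saves
`9C² − 9C` parameters, and the same times the output area in MACs.

```r
# synthetic data -> segmentation -> training -> evaluation
ds   <- generate_garlic_dataset(60, image_size = 64, seed = 42)  # 180 images
plan <- split_plan(ds, seed = 42)                                # 6:2:2

seg <- segment(ds$image[[1]])
seg$bbox
#> row_min col_min row_max col_max
#>      10      17      48      49

net <- build_model("dh_garlicnet", num_classes = 3, width = 8,
                   input_size = 64, seed = 42)
fit <- garlic_train(net,
                    plan[plan$partition == "train", ],
                    plan[plan$partition == "val", ],
                    train_config(input_size = 64, batch_size = 8,
                                 lr = 0.01, epochs = 5, seed = 42))
tidy(fit)
#>   epoch train_loss val_loss val_acc
#>       1      1.118    1.107   0.361
#>       2      0.841    3.668   0.389
#>       3      0.504    0.224   0.944
#>       4      0.264    0.273   0.861
#>       5      0.171    0.105   1.000

ev <- garlic_evaluate(fit$network, plan[plan$partition == "test", ])
ev$metrics$accuracy
#> [1] 1
```

The synthetic classes are separable by construction (colour- and
location-coded damage patches), so a reduced-width network reaches perfect
held-out accuracy within five epochs; this demonstrates the machinery, not
performance on real garlic. Grad-CAM then localizes the evidence — evaluated
fully convolutionally at 224 px for a 7×7 attention map:

```r
dmg <- plan[plan$partition == "test" & plan$class == "local_damage", ]
hm  <- grad_cam(fit$network, dmg$image[[1]], target_class = "local_damage",
                input_size = 224)
autoplot(hm)                  # blue (low) -> red (high) attention raster
```

A thin CLI over the same functions lives at `inst/cli/garlicnet.R`
(`synth`, `segment`, `profile`, `build`, `train`, `eval`, `gradcam`
subcommands).

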