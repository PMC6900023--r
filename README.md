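# msdseg

Bone segmentation of CT / cone-beam CT volumes affected by metal streak
artifacts, with a mixed-scale dense (MS-D) convolutional network — plus the
full evaluation chain such a segmenter needs: Dice overlap against gold
standards, leave-2-out cross-validation, mask-to-mesh conversion, binary STL
I/O, and signed surface-deviation statistics. A seeded synthetic phantom
simulator (parallel-beam radon transform, Poisson photon statistics with
beam hardening and photon starvation, filtered back-projection) generates
jaw-like volumes with realistic bright/dark streaks and artifact-free labels,
standing in for clinical scans that cannot be redistributed.

The intended users are medical-image-analysis researchers and engineers who
need a small, fully reproducible, dependency-light segmentation baseline for
artifact-corrupted CT — and a transparent reference implementation of the
MS-D architecture in R.

## The model

A depth-`d` MS-D network keeps every feature map at the input's size and
connects everything to everything. With `z_0` the normalized input slice,

    z_i = ReLU( sum_{j<i} D(z_j; h_ij, s_i) + b_i ),     s_i = ((i-1) mod 10) + 1

where `D(.; h, s)` is a 3×3 convolution with taps spaced `s` pixels apart
(reflective boundaries), and the output is a two-class softmax over 1×1
combinations of all `d+1` maps, thresholded at a cutoff to give the bone
mask. Depth 100 uses 45,754 trainable scalars — orders of magnitude fewer
than encoder–decoder CNNs, which is what makes it trainable on a handful of
scans. Training is batch-size-1 Adam on axial slices with per-pixel
cross-entropy.

## Worked example

```r
library(msdseg)

# six jaw phantoms, 8 axial 64x64 slices each, two metal fillings
spec <- phantom_spec(size = 64, n_slices = 8, metal_count = 2, seed = 7)
ds   <- generate_dataset(spec, n_volumes = 6, seed = 7)

# train on five volumes (40 slices), hold out the sixth
fit <- msd_fit(ds[1:5], depth = 20, epochs = 12, max_steps = 480,
               cutoff = 0.5, seed = 7)
fit
#> Mixed-scale dense segmentation network
#>   20 layers, dilation cycle 10, cutoff 0.50; 1954 parameters
#>   trained on 40 slices, 12 epochs (480 steps)
#>   cross-entropy: first epoch 0.4594, last epoch 0.0305

held <- ds[[6]]
mask <- predict(fit, held$image, type = "mask")
dice(confusion(mask, held$bone_mask))
#> [1] 0.8903913

# the intensity-only baseline is confounded by the streaks
best_threshold_dice(held$image, held$bone_mask)$dice
#> [1] 0.8094814

# geometric comparison via meshes
gold <- mask_to_mesh(held$bone_mask, spacing = 0.2)
pred <- mask_to_mesh(mask, spacing = 0.2)
signed_deviations(pred, gold, limit = 5)
```

The fitted network recovers bone the global threshold cannot: the Dice gap
(0.890 vs 0.809 here) comes from streak pixels that thresholding necessarily
mislabels. `aggregate_dice(dice_reference_table())` reproduces the published
18-scan benchmark summary this evaluation layout mirrors (means 0.78 /
0.87 / 0.87 / 0.86 for snake evolution, MS-D, U-Net, ResNet).

A command-line wrapper (`inst/cli/msdseg`) exposes the pipeline as
subcommands: `phantom`, `train`, `predict`, `dice`, `evaluate`,
`compare-stl`, `crossval`, `sweep`.

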