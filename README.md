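# mrisr

Single-image super-resolution for grayscale, MRI-like images with a
small convolutional network built from first principles, plus the
evaluation machinery around it. The package is aimed at people who want
a fully inspectable super-resolution stack — every gradient
hand-derived and oracle-tested — rather than a framework binding: image
analysts studying reconstruction behavior at desk scale, and anyone
teaching or auditing how these networks actually train.

## What it implements

* **Model**: a three-stage CNN (feature extraction, nonlinear mapping,
  reconstruction) in the pre-upsampling convention: the low-resolution
  image is spline-interpolated to the target grid, and the network
  `X_l = X_{l-1} ⊙ A_l + b_l` (cross-correlation, zero "same" padding,
  ReLU on hidden layers) refines it at constant size.
* **Training**: analytic backpropagation; mean-square-error,
  cross-entropy and log-likelihood losses; plain gradient descent,
  momentum, RMSProp, and Adam with bias correction
  (`ω ← ω − α·D̂/(√Ê + θ)`, β₁ = 0.9, β₂ = 0.999, θ = 1e-8).
* **Metrics**: PSNR `10·log10(L²/MSE)` and single-scale SSIM
  `L^α·C^β·S^γ` with the luminance/contrast/structure decomposition
  (k₁ = 0.01, k₂ = 0.03, c₃ = c₂/2; global window by default, 8×8
  sliding optional).
* **Data**: a seeded phantom generator (overlapping elliptical/annular
  plateaus, optional Gaussian/Rician noise) and a configurable
  blur → decimate → spline-reupsample degradation model, so nothing
  external is needed.
* **Harness**: patch extraction with dihedral augmentation, minibatch
  training with logged PSNR curves, a cubic-spline interpolation
  baseline, method comparison on held-out phantoms, and a kernel-count
  sweep.
* **Clinical tables**: Pearson chi-square homogeneity tests and
  half-up-rounded percentage summaries for small count tables; the
  package ships a 2×3 meniscus-injury grading table (arthroscopy vs
  MRI, 60 patients) and a 4-category treatment table as fixtures.

## Worked example

```r
library(mrisr)

deg <- degradation_spec(2)                       # ×2 downsampling model
train_pairs <- phantom_dataset(8, 48, 48, deg, seed = 100)
val_pairs   <- phantom_dataset(3, 48, 48, deg, seed = 900)
test_pairs  <- phantom_dataset(10, 48, 48, deg, seed = 500)
patches <- pairs_to_patches(train_pairs, 16, 8)  # 200 patch pairs

cfg <- training_config(
  loss_kind = "mse",
  optimizer = optimizer_config("adam", alpha = 2e-3),
  epochs = 40, batch_size = 8, patch_size = 16, stride = 8,
  kernels = c(5, 3, 3), channels = c(8, 4), seed = 11)

fit <- sr_train(cfg, patches, val_pairs)
tail(fit$history, 3)
#>     iteration         loss val_psnr
#> 99        980 0.0004341049 35.48607
#> 100       990 0.0005065667 35.56584
#> 101      1000 0.0005058705 35.41870

compare_methods(fit$model, test_pairs)
#>                method psnr_mean   psnr_sd ssim_mean  n
#> 1 cubic_interpolation  30.21234 0.8591060 0.9900215 10
#> 2               srcnn  36.49063 0.9473065 0.9977897 10
```

Validation PSNR climbs from the random-initialization floor and
plateaus in the mid-30 dB range; on ten held-out phantoms the trained
network beats cubic-spline interpolation by ~6 dB mean PSNR and in mean
SSIM. (Numbers are for this 48×48 phantom setup and seed; they
characterize the synthetic task, not clinical MRI.)

The clinical side:

```r
chi_square_homogeneity(meniscus_grading_table())[c("statistic", "df", "p_value")]
#> $statistic
#> [1] 2.62892
#> $df
#> [1] 2
#> $p_value
#> [1] 0.2686194

proportions_report(treatment_counts())
#>              category count percent
#> 1     meniscus_suture    17   28.33
#> 2 secondary_resection    39   65.00
#> 3   partial_resection     3    5.00
#> 4     total_resection     1    1.67
```

The grading distributions under arthroscopy and MRI do not differ
significantly (p = 0.269 > 0.05).

A thin command-line wrapper over these functions is included at
`inst/cli/mrisr.R` (subcommands `phantom`, `train`, `compare`,
`clinical-stats`); after installation:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mrisr.R", package = "mrisr"))')" phantom --out img.png --seed 7
```

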