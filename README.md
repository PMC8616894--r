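# mrcgan

Acquisition-parameter-conditioned MRI contrast synthesis with generative
adversarial networks, in R.

A clinical MR exam acquires several sequences whose tissue contrast is
governed by the acquisition parameters — echo time (TE, ms), repetition
time (TR, ms) and fat saturation (FS). Because sequence parameterizations
vary widely across sites and scanners, an image-synthesis model fixed to
one target sequence has narrow applicability. `mrcgan` implements a
contrast-*aware* image-to-image GAN: the generator is conditioned on both
the source image's and the requested target's acquisition parameters, so a
single trained model translates an image to any admissible contrast —
including continuous TE/TR interpolation and non-fat-saturated to
fat-saturated translation. The package is aimed at researchers studying
MR contrast synthesis, data harmonization and augmentation who want a
fully inspectable, CPU-scale reference implementation with an analytic
physics oracle for verification.

## The model

The conditioning vector is $y = (\mathrm{TE}/50,\ \mathrm{TR}/5000,\ FS)$.
A residual U-Net generator receives $y_{\mathrm{source}}$ in its encoder
and $y_{\mathrm{target}}$ in its decoder through adaptive instance
normalization,

$$\mathrm{AdaIN}(x, y) = \alpha(y)\,\frac{x-\mu(x)}{\sigma(x)} + \beta(y),$$

with $\alpha, \beta$ single affine maps per injection site. Training
combines a non-saturating adversarial loss with R1 regularization
($\gamma = 1$), the weighted reconstruction loss
$\omega\,(1-\mathrm{MS\text{-}SSIM}) + (1-\omega)\,L_1$ with
$\omega = 0.84$, and — for unpaired data — cycle consistency plus an
auxiliary-classifier conditioning loss ($\lambda_c = 10$). Six cumulative
model variants span the ablation from a pix2pix baseline (labels ignored)
to the full unpaired-capable model. Evaluation uses NMSE, PSNR (dynamic
range taken over the image pair) and SSIM.

Everything — convolutions, AdaIN, MS-SSIM and their gradients, Adam, EMA —
is implemented in the package (R with RcppArmadillo kernels), so training
and evaluation run on a single CPU. A spin-echo phantom simulator
($S = PD\,(1-e^{-TR/T1})\,e^{-TE/T2}$ over knee-like tissue maps) provides
paired data with analytic ground truth; DICOM-style curation rules
(TR $\le$ 5000 ms, TE $\le$ 50 ms, central-14 slice selection,
five-attribute pairing) build training pairs from metadata records. See
`vignettes/contrast-synthesis.Rmd` for the full methods account.

## Worked example

```r
library(mrcgan)

# simulate a small paired dataset of spin-echo knee phantoms
ds <- make_synthetic_dataset(seed = 7, n_subjects = 60, slices_per_subject = 2,
                             pair_fraction = 1)
#> <mr_dataset> 240 samples (240 paired, 0 unpaired), 64 x 64, 61 FS

# train model variant 5 (conditioned GAN, MS-SSIM/L1 loss, non-FS targets)
model <- train_gan(ds, variant_config(5, iterations = 1000, seed = 7))
#> <gan_model> variant 5, 1000 iterations; final d_loss 1.386, g_adv 0.820

# held-out evaluation vs. the identity-translator baseline
test_ds <- make_synthetic_dataset(seed = 8, n_subjects = 10,
                                  slices_per_subject = 2, pair_fraction = 1)
pairs <- dataset_pairs(test_ds)
evaluate_reconstruction(pairs, model$translator)
#> <evaluation_report> 20 pairs
#>   nmse               0.0782 +/- 0.1527
#>   psnr              21.2322 +/- 5.1738
#>   ssim               0.6338 +/- 0.2513
evaluate_reconstruction(pairs, function(im, ys, yt) im)
#> <evaluation_report> 20 pairs
#>   nmse               0.2048 +/- 0.3596
#>   psnr              20.2032 +/- 8.8607
#>   ssim               0.5684 +/- 0.2987
```

After about four minutes of single-CPU training the conditioned model
reconstructs held-out target contrasts far better than simply returning
the source image: NMSE drops from 0.20 to 0.08 and SSIM rises from 0.57
to 0.63. With `contrast_grid()` the same model renders one image under a
whole TE/TR lattice; muscle-region intensity falls with TE, as spin-echo
physics dictates.

A command-line front end wraps the same functions:

```sh
inst/exec/mrcgan simulate --seed 1 --n-subjects 60 --slices 2 --out data/
inst/exec/mrcgan train --data data/ --variant 5 --seed 1 --out model.rds
inst/exec/mrcgan evaluate --data data/ --model model.rds --out report.json
```

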