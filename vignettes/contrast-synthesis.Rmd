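---
title: "Acquisition-conditioned MR contrast synthesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acquisition-conditioned MR contrast synthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A clinical MR exam acquires several sequences whose tissue contrast is
controlled by acquisition parameters — most importantly the echo time (TE,
ms), the repetition time (TR, ms) and whether fat saturation (FS) is
applied. Because parameterizations vary across sites and scanners, a
synthesis model that can translate an acquired image into *any* requested
contrast, rather than into one fixed target sequence, is far more broadly
applicable. `mrcgan` implements such a model: an image-to-image generative
adversarial network whose generator is told, explicitly, which acquisition
parameters the input image has and which the output image should have.

## The model

**Conditioning.** TE and TR are scaled linearly to $[0,1]$ by the dataset
filter bounds (50 ms and 5000 ms; using the bounds rather than empirical
extrema keeps the scaling stable across dataset subsets), and FS enters as
a third binary component, giving label vectors $y = (TE/50,\ TR/5000,\ FS)$.
Labels are injected through adaptive instance normalization:

$$\mathrm{AdaIN}(x, y) = \alpha(y)\,\frac{x - \mu(x)}{\sigma(x)} + \beta(y),$$

where $\mu$ and $\sigma$ are the per-sample, per-channel spatial moments of
the feature map $x$ and $\alpha, \beta$ are *single* affine maps (no hidden
layers) from the label vector to one scale and one bias per channel. Each
injection site owns its projections (whether sites share them is an open
design point; separate projections are the more expressive choice and cost
little). Projections are initialized to the identity ($\alpha \equiv 1$,
$\beta \equiv 0$), so an untrained network behaves like an unconditioned
U-Net and, by construction, its output is independent of the labels at
initialization.

**Generator.** A residual U-Net: strided stem, one residual block per
encoder level with strided downsampling between levels, a bottleneck block,
and a mirrored decoder using nearest-neighbour upsampling + convolution
(avoiding checkerboard artifacts) with skip concatenation. Source labels
condition the encoder blocks, target labels the bottleneck and decoder
blocks; so the encoder can learn a contrast-invariant representation which
the decoder re-renders under the requested parameters. Residual blocks use
3x3 kernels and leaky-ReLU (slope 0.2). The output convolution is
zero-initialized and the clipped $\mathrm{atanh}$ of the input image is
added before the final $\tanh$, making the untrained generator exactly the
identity map — a standard identity-biased initialization for
image-to-image networks that also anchors early training.

**Discriminator.** A stack of strided residual blocks without
normalization, global average pooling and one linear score per image
(six blocks of 64–512 filters at full scale).

**Losses.** Training uses the non-saturating adversarial loss in its
numerically stable softplus form, with R1 regularization
$\tfrac{\gamma}{2}\,E\big[\lVert\nabla_x D(x)\rVert^2\big]$ on real samples
only, every discriminator step, with $\gamma = 1$. Reconstruction on paired
batches is the weighted mix

$$L^{\mathrm{Recon}} = \omega\,(1 - \mathrm{MS\text{-}SSIM}(x, x')) +
  (1-\omega)\,L^{L1}(x, x'), \qquad \omega = 0.84,$$

which balances perceptual structure against absolute intensity fidelity.
For the unpaired regime a cycle-consistency loss
$E\lVert G(F(g)) - g\rVert_1 + E\lVert F(G(t)) - t\rVert_1$ is applied with
one *shared* conditioned generator serving as both directions (invoked with
swapped source/target labels), plus a conditioning loss (weight
$\lambda_c = 10$) in which a separately pretrained auxiliary classifier
(AC) reads TE, TR (mean squared error on the scaled values, averaged over
the two parameters) and FS (binary cross-entropy) off the synthesized
image. The conditioning loss is applied on the unpaired branch only. The
weight between the adversarial and reconstruction terms is not prescribed
by the conditioning scheme itself; `lambda_recon = 100` follows the
pix2pix convention of letting reconstruction dominate.

**Variants.** Six cumulative model variants reproduce the ablation ladder:
(1) a pix2pix-style baseline that ignores labels, (2) + target labels in
the decoder, (3) + source labels in the encoder, (4) + the MS-SSIM/L1
reconstruction mix, (5) + pairs with non-FS targets, (6) + unpaired non-FS
data under cycle and conditioning losses. Style projections are always
built and only *gated*, so parameter counts are identical across variants
1–3 and the ablation isolates wiring, not capacity.

**Optimization.** Adam with $\beta_1 = 0$, $\beta_2 = 0.99$; batch 8 for
the GAN, 64 for the AC; an exponential moving average of generator
parameters is used at evaluation. At the full scale (200K iterations,
256 px) the learning rate is $10^{-4}$ and the EMA decay 0.999. The
package's desk-scale defaults compress the schedule about a hundredfold
(2000 iterations at 64 px, half-to-quarter-width networks), and the
schedule-dependent settings are rescaled accordingly: learning rates
$3\times10^{-4}$ (GAN) and $2\times10^{-3}$ with cosine decay (AC), EMA
decay 0.995 so that the
averaging window remains a small fraction of the run (a 0.999 decay would
average over half of a 2000-iteration run, dragging evaluation weights
back toward the initialization). The full-scale settings remain available
through `variant_config()` arguments.

## The phantom simulator

Real training data for this task are DICOM series with per-image
acquisition metadata. For development and verification at desk scale the
package generates 2D knee-like phantoms with known ground truth. Each
phantom is a union of random ellipses over five tissue classes
(fat, muscle, fluid, bone, cartilage) with proton density, T1 and T2 drawn
from standard 1.5 T literature ranges and modulated by a smooth field of at
most 5%. The geometry mirrors a knee slice: a subcutaneous fat rim always
surrounds a muscle body, and bone, cartilage and synovial fluid are placed
whenever the structure budget allows (a real knee slice contains all
five); extra structures are random interior ellipses. Without the
guaranteed rim, a fraction of images would carry no fat and the FS flag
would be physically unreadable from the image, breaking the property the
simulator exists to emulate (contrast, including fat suppression, must be
a function of the acquisition parameters); without a guaranteed long-T1
fluid pool, the repetition time would be near-unidentifiable in many
images.

Images are rendered with the classical spin-echo signal equation

$$S = PD\,(1 - e^{-TR/T1})\,e^{-TE/T2},$$

fat saturation as a multiplicative suppression of fat-class pixels (factor
0.05), optional Gaussian noise (default sd 0.01 of the dynamic range), a
clip to $[0, 1]$ — 1 being the phantom's proton-density ceiling, so the
intensity scale is absolute and consistent across images — and a linear
map to $[-1, 1]$. TE/TR labels are drawn from a mixture emulating clinical
archives: a non-FS cluster (TE 25–35, TR 2000–3500), an FS cluster
(TE 30–45, TR 2500–4500) and 10% uniform mass over the admissible box.
Paired samples render one tissue map under two labels (source always
non-FS; the target fat-saturated with probability 0.5, otherwise a second
non-FS contrast, so that variant 5's non-FS-target regime exists in the
data).

What the simulator does **not** model: k-space sampling and artifacts,
coil sensitivity profiles, Rician noise statistics, partial-volume
chemistry, flip-angle dependence, through-plane motion between paired
series, or realistic anatomy. Consequently, passing the package's tests
shows that the method is implemented correctly and learns genuine
TE/TR/FS-dependent contrast from images — it does not show that clinical
image quality (the full-scale PSNR/SSIM regime) is reached; that requires
real data and the full schedule.

## Numerical choices

- AdaIN stabilizes $\sigma$ as $\sqrt{\mathrm{var} + \varepsilon}$ with
  $\varepsilon = 10^{-5}$; moments use population (1/n) normalization.
- MS-SSIM uses the standard 5-scale exponents, an 11x11 Gaussian window
  (sd 1.5) over the valid region, and $c_1 = (0.01 L)^2$,
  $c_2 = (0.03 L)^2$ with $L = 2$ for $[-1,1]$ images. When the image side
  supports fewer than five dyadic scales the leading exponents are kept and
  renormalized to sum 1 (three scales at 64 px). Negative per-scale terms
  are clamped at $10^{-8}$ before exponentiation. Its analytic gradient is
  verified against central finite differences in the test suite.
- SSIM as a metric defaults to the windowed convention; a global-statistics
  mode evaluates the bare formula. PSNR's MAX is the *joint* range of the
  two images (not a fixed data range), and identical images report +Inf
  and are excluded from aggregates. NMSE normalizes by the first
  (ground-truth) argument; it is not symmetric.
- The R1 penalty *value* is exact (backpropagated input gradient). Its
  contribution to the discriminator's weight gradient is computed with a
  symmetric secant pass along the normalized input gradient
  ($\varepsilon = 10^{-3}$): for the piecewise-linear discriminators used
  here this equals the true second-order term away from activation kinks,
  and it avoids implementing general second-order autodifferentiation.
  All convolution GEMMs run in single precision, ample for stochastic
  gradient training; all user-facing arrays are double.
- Curation: filter bounds are inclusive (TE <= 50, TR <= 5000 — records
  *over* the limit are excluded); the central-slice window for a series of
  length $n$ is $[\lfloor n/2\rfloor - \lfloor k/2\rfloor,\ \lfloor
  n/2\rfloor - \lfloor k/2\rfloor + k)$; slice locations match within
  0.5 mm and orientation vectors element-wise within $10^{-3}$ (DICOM
  floats rarely match bitwise); constant images rescale to $-1$ everywhere
  (they carry no contrast and this avoids a 0/0); bilinear interpolation
  uses the half-pixel-centre convention, edge clamped.
- One discriminator update per generator update; augmentation (random
  shift up to 5% and zoom 0.9–1.1, reflection-padded, shared within a
  pair) applies to half the batches.
- A single experiment seed fans out to named substreams (phantom geometry,
  labels, noise, initialization, batch order, augmentation), so adding
  draws to one stream never perturbs another and all runs are bit
  reproducible on one machine.

## Study conditions used by the verification suite

The package's acceptance checks train at sizes chosen to exercise every
loss and pathway while remaining single-CPU friendly: the AC
parameter-recovery study uses 2000 noise-free 64 px phantoms for 2000
iterations (batch 64) with a subject-wise 10% validation split; the
end-to-end study trains variant 5 on 1000 synthetic pairs at 64 px for
2000 iterations (batch 8, generator filters 8-16-32, discriminator
8-16-32-64) and compares held-out reconstruction against the
identity-translator baseline, plus the TE-direction of a 3x3 contrast
grid in the muscle region. These sizes are the package's desk-scale study
conditions, also recomputed by `scripts/acceptance.R`.

## Limitations

- The phantom's simplicity means desk-scale quantitative results are not
  comparable to values obtained on clinical archives; only directions and
  orderings transfer.
- The phantom's flat, texture-free regions bound how precisely TE and TR
  can be read back from a single image: a bright interior ellipse may be
  synovial fluid or marrow fat, and the per-structure spread of the tissue
  parameter ranges is irreducible noise for any estimator. Acquisition
  parameters are therefore recoverable only up to a phantom-specific floor
  that real, textured anatomy does not share.
- Real-data mode consumes a tabular metadata manifest; DICOM binary
  parsing is delegated to an optional Python helper script
  (`inst/scripts/extract_dicom_headers.py`), and the fat-saturation flag
  of a DICOM series is a heuristic that the helper logs per file rather
  than asserts.
- The training engine is deliberately minimal (no GPU, no mixed precision,
  no multi-device); the full 200K-iteration, 256 px schedule is expressible
  but intended for ports of this model to GPU frameworks.
- Cycle training uses the forward cycle per unpaired batch with the shared
  generator; two-generator cycle topologies are out of scope.
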