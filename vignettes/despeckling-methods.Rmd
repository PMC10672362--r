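---
title: "Few-shot OCT despeckling: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot OCT despeckling: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octshot)
```

## The problem

Optical coherence tomography (OCT) B-scans are log-scaled intensity images of
coherently backscattered light. Scatterers spaced below the resolution cell
interfere, and the resulting speckle is not additive sensor noise: for fully
developed speckle the measured intensity $y$ at a pixel with mean (ground
truth) intensity $x$ follows the exponential density

$$p(y \mid x) = \frac{1}{x}\, e^{-y/x}, \qquad y > 0,$$

so the fluctuations are as large as the signal itself (contrast
$\sigma/\mu = 1$). Hardware suppression averages many independent speckle
realizations (angular compounding), which is rarely possible in vivo. This
package trains a supervised despeckler from a *single* image pair — one
speckled B-scan and one speckle-suppressed ground truth — and reasons
explicitly about how the acquisition system's resolution-to-sampling
relationship shapes what such a model learns.

## Imaging model and simulator

A tomogram is modelled as
$Y[m,n] = 10\log_{10} |f[m,n] \ast \alpha[m,n]|^2$, where $f$ is the complex
reflectivity and $\alpha$ the point spread function (PSF), separable into an
axial profile (magnitude of the FFT of a Hanning spectral window of
`n_spectral` points zero-padded to `n_fft`) and a lateral Gaussian beam
profile $\exp(-2x^2/\omega_x^2)$ with waist $\omega_x$. The speckle-free
ground truth is the incoherent mean
$X[m,n] = 10\log_{10}\left(|f[m,n]|^2 \ast |\alpha[m,n]|^2\right)$.

The simulator (`generate_phantom()`, `simulate_speckled_tomogram()`,
`ground_truth_tomogram()`, `make_pair()`) draws a nonnegative reflectivity
phantom — by default undulating tissue-like strata with multiplicative
log-normal scatterer texture — assigns i.i.d. uniform phases, convolves with
the PSF and takes the log intensity. Design choices worth knowing:

* **Sub-resolution scatterer grid.** Fully developed speckle statistics are
  the many-phasor limit. With exactly one scatterer per acquisition pixel and
  the compact PSFs of the shipped systems, the effective phasor count per
  resolution cell is only ~10, which measurably biases speckle contrast below
  one. `system_psf()` therefore samples the PSF on a twice-finer grid
  (`oversample = 2`) and the simulator places independent scatterers on that
  sub-resolution grid (amplitude $a/s$ per sub-pixel, preserving the pixel's
  mean intensity), reading the tomogram out at the acquisition pitch. Under
  this default, interior speckle contrast across seeds is 0.97–1.01 and
  single-pixel intensities pass a Kolmogorov–Smirnov exponentiality test at
  the 1% level. `oversample = 1` reproduces the plain per-pixel construction
  used in the algebraic unit tests.
* **Boundaries and floors.** Convolution uses reflected boundaries (no dark
  borders in training crops). Intensities are floored at $10^{-12}$ before
  the log, and each image records a display dynamic range of 45 dB below its
  peak, to which values are clipped — the standard display convention, and
  the range used for normalization and metrics.
* **What the phantom does not model.** Sensor (shot/thermal) noise, motion,
  refraction, attenuation, depth-dependent PSFs, polarization and catheter
  geometry are all out of scope. Passing the test suite therefore shows the
  methods work under the stated speckle physics, not that they transfer to
  any particular clinical dataset.

## Sampling-resolution ratios and domain adaptation

The *sampling-resolution ratio* of an axis is the PSF effective width over
the sampling space, rounded to the nearest integer:
$p_x = [\omega_x/\delta_x]$, $p_z = [\omega_z/\delta_z]$ — the speckle grain
size in pixels. A patch-based despeckler learns the grain size of its source
system; applied to a target system with a larger ratio it may hallucinate
detail, with a smaller ratio it blurs (`predict_output_regime()`).

`plan_resampling()` aligns systems by rationally resampling either side so
the integer ratios match: the factor is the best rational approximation of
$(\omega/\delta)/p_{\text{desired}}$ with denominator at most
`max_denominator` (default 3, covering the canonical factors 2, 4/3 and 8/3)
*subject to actually landing in the desired rounding band* — for a few
extreme system pairs no denominator-3 fraction does, and the planner then
grows the denominator until the post-resampling integer ratio equals the
counterpart's, which is the contract the rest of the package relies on.
`apply_resampling()` implements the factor as polyphase resampling with a
Hamming-windowed sinc filter (10 taps per branch per side), reflect-padded,
with output length $\mathrm{round}(n/\text{factor})$ (half away from zero)
and pitch metadata scaled accordingly. Rounding of the ratio itself is half
away from zero, floored at one pixel.

The axial PSF width cannot be recovered from `n_spectral`/`n_fft` alone by
any single standard width definition that reproduces the shipped systems'
axial ratio, so $\omega_z$ is an explicit spec field; the packaged YAML files
set $\omega_z = p_z\,\delta_z$, consistent with the published ratios.
`axial_psf()` is provided for simulation, truncated where the profile falls
below 1% of its peak (a visible support of roughly 7–9 pixels for the
shipped systems).

## The predictors

All four methods train on one pair. Images are mapped to $[0,1]$ by an
affine taken from robust quantiles (0.5% and 99.5%) of the noisy training
image; at inference a test image is normalized by its own quantile affine.
Quantiles rather than the raw min/max matter: the dB maximum of a speckled
image is an interference extreme that moves by several dB between
realizations, and an affine anchored to it misaligns training and test
scales.

* **RNN (patch-to-pixel).** The analysis patch at pixel $(i,j)$ is the
  $L_t \times N_x$ window whose bottom row is $i$ and whose columns reach
  $n_L$ left and $n_R$ right of $j$ ($n_L + n_R = N_x - 1$; defaults
  $15 \times 15$, symmetric). Its rows are fed as a sequence to a recurrent
  cell $z_t = \mathrm{ReLU}(W_{zy}^T y_t + W_{zz}^T z_{t-1} + b)$ with 1000
  hidden units and a linear head; training targets the clean depth segment,
  and at inference only the last output (the anchor pixel) is kept. Border
  anchors use replicate padding, so the output has full size. The default
  model has exactly 1,031,015 parameters.
* **DRNN.** Identical architecture; the input image is first blurred with a
  normalized $7\times7$ Gaussian ($\sigma = 1$), recasting despeckling as
  deblurring. The filter is stored in the model and re-applied at inference.
* **RNN-GAN (patch-to-patch with averaging).** The head emits $P = N_x$
  values per step, so each patch yields a full $L_t \times N_x$ prediction;
  overlapping predictions are averaged per pixel (`overlap_average_reconstruct()`),
  which improves SNR. After the MSE stage, an adversarial stage trains a
  deliberately tiny two-layer discriminator (hidden width 128, sigmoid
  output) on clean-vs-generated patches and adds
  $\lambda\,\mathcal{L}_{\mathrm{ADV}}$ (non-saturating log loss,
  $\lambda = 10^{-3}$, the SRGAN-style convention) to the generator's MSE.
* **U-Net.** A standard 4-level encoder–decoder (base 32 channels, double
  3×3 ReLU convolutions, 2×2 max pooling, transposed-convolution upsampling,
  skip concatenation, 1×1 output head; ~7.8 M parameters, within the
  published ~8.2 M regime) trained on random 64×64 crops of the pair and
  applied to whole images, reflect-padded to a multiple of $2^{\text{depth}}$.

All forward passes, backpropagation (including through time) and the Adam
optimizer are implemented in the package in plain R with BLAS-backed matrix
algebra; forward passes are deterministic and every source of training
randomness (initialization, shuffling, crop sampling) is threaded from one
seed, so identical configurations reproduce identical checkpoints.

## Training schedule and numerics

Defaults follow the few-shot regime: Adam with $\beta_1 = 0.5$,
$\beta_2 = 0.9$, initial learning rate $10^{-4}$, batches of 256 analysis
patches, 8 content epochs (useful range ≈ 5–12) and 20 adversarial epochs
(≈ 10–30), with early stopping once the epoch MSE improves by less than 1%
over two epochs — overtraining a single image overfits and blurs. The
recurrent weights are initialized uniformly at $\pm 1/\sqrt{\text{fan-in}}$
(small, keeping the 15-step recurrence stable); the U-Net convolutions use
He-scaled uniform init $\pm\sqrt{6/\text{fan-in}}$, which keeps activation
variance constant through the ReLU cascade. For the U-Net the published
recurrent-stage learning rate is not meaningful at small batch sizes — with
batch-one Adam steps the parameter displacement after a few thousand steps
is far below what the loss landscape requires — so the U-Net examples and
tests use $10^{-3}$; the rate is exposed in `train_config()`.

Degenerate inputs are handled explicitly: an all-zero phantom warns and
returns the dB floor; a diverging loss aborts with a diagnostic; a
discriminator whose loss sticks near zero triggers a saturation warning;
resampling that leaves an axis shorter than twice the patch dimension warns.

## Metrics

`psnr()` and `ssim()` (Gaussian window σ = 1.5, 11×11, $K_1 = 0.01$,
$K_2 = 0.03$) default their `data_range` to the *reference* image's recorded
dynamic-range span (45 dB for simulator output), so different estimates
compared against one reference share a scale; with an explicit `data_range`
both metrics are symmetric in their arguments. Identical images report the
99 dB cap instead of infinity. `evaluate_tiles()` tiles non-overlapping
256×256 squares from the top-left, excludes remainder strips, and averages
per-tile scores. Because the dynamic-range convention is a package choice,
absolute scores are not comparable to numbers computed under other
conventions; gains over the speckled input are.

## Test-scale study conditions

The test suite exercises the full pipeline at desk scale, chosen once as the
package's own study conditions: chicken-system fixtures of 120×200 pixels
(256×256 for U-Net training, matching its whole-image training protocol),
training on the first 60 columns with hidden width 200 and batch 64 for the
recurrent methods, and a depth-2, base-8 U-Net on 400 random 32×32 crops for
10 epochs. Five held-out same-system fixtures define the evaluation set; the
bars — mean PSNR gain ≥ 3 dB and mean SSIM gain ≥ 0.10 over the speckled
input for every method, and strictly higher SSIM after resampling adaptation
when a grain-3 model meets grain-1 data — are properties of the method, not
of the reduced sizes, and are asserted as such. The Monte-Carlo consistency
check between the speckled simulator and the incoherent ground truth uses
500 realizations and asserts the $3\sigma$ relative bound as coverage (at
least 99% of fully developed interior pixels inside it), the statistically
correct form of a per-pixel bound evaluated over thousands of pixels.

## Known limitations

* The simulator's phantoms are layered or blob-like; pathology-specific
  structure (vessels, drusen, guidewire shadows) is absent.
* Complementary PSFs linking two real systems exist only approximately; the
  rational resampling surrogate aligns integer grain sizes, not full PSF
  shapes.
* PNG export is 8-bit with a JSON sidecar affine (the lossless path is NPY;
  TIFF stores range-mapped 32-bit floats with a sidecar).
* Checkpoints and cached datasets are RDS + JSON manifest, R's native
  serialization.
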