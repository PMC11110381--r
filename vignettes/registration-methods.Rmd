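---
title: "Unsupervised deformable registration of 3D brain MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised deformable registration of 3D brain MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The registration problem

Deformable image registration (DIR) estimates a dense, non-rigid spatial
mapping that aligns a *moving* volume $I_m$ onto a *fixed* volume $I_f$,
voxel by voxel. For longitudinal glioma imaging the fixed image is
typically the pre-operative scan and the moving image a follow-up scan of
the same patient; surgery, tumor growth and tissue relaxation deform the
anatomy between the two.

`deformreg` implements the learning-based formulation: a fully
convolutional U-Net takes the concatenated pair $(I_f, I_m)$ as a
two-channel 3D image and predicts a dense displacement field
$s : \Omega \to \mathbb{R}^3$ in voxel units. The warp is
$\phi(x) = x + s(x)$, and a differentiable spatial transformer evaluates
$I_m \circ \phi$ by trilinear interpolation, so the whole pipeline trains
end to end by gradient descent — *unsupervised*, from image pairs alone,
with no ground-truth correspondences.

## Loss

Training minimizes

$$\mathrm{Loss} = L_{sim}(I_f, I_m \circ \phi) + \lambda\, L_{smooth}(s),$$

with the following conventions (each a deliberate choice where the
formulation family leaves latitude):

* **Similarity.** $L_{sim} = -\mathrm{NCC}(I_f, I_m\circ\phi)$, the
  negative local normalized cross-correlation over $9^3$ windows. We use
  the *squared* local correlation
  $CC = \left(\textstyle\sum (a-\bar a)(b - \bar b)\right)^2 /
  \left(\sum(a-\bar a)^2 \sum(b-\bar b)^2 + \epsilon\right)$,
  the convention of the open-source learning-based registration
  ecosystem: it is invariant to local affine intensity maps (including
  contrast inversion) and bounded in $[0,1]$. Window sums are box
  filters with zero padding and a fixed divisor $n = 9^3$ everywhere,
  including at borders. $\epsilon$ (default $10^{-5}$) sits in the
  denominator only; its practical effect is that *flat* windows — the
  zero background of skull-stripped volumes — score 0 rather than an
  unstable 0/0. A consequence worth knowing when reading numbers: the
  self-similarity $\mathrm{NCC}(I,I)$ of a skull-stripped volume is well
  below 1 (≈ 0.7 for our phantoms), because background windows
  contribute zeros. Aligned textured regions still score ≈ 1.
* **Smoothness.** $L_{smooth}$ is the diffusion regularizer
  $\sum \lVert \nabla s \rVert^2$ with forward differences between
  neighbouring voxels. We reduce by *mean* (per axis, then across the
  three axes) rather than sum, so $\lambda$ is independent of grid
  resolution and the sweep $\lambda \in \{0, 0.1, 0.2, 0.5, 1\}$
  compares like with like at any volume size. Default $\lambda = 1$,
  the value that registers best in this family.

Gradients of both terms are derived analytically (the NCC gradient via
the windowed-moment chain rule, the warp's coordinate gradient from the
trilinear weights, with zero gradient for border-clamped samples) and
verified against central finite differences in the test suite.

## Networks

All variants are 3D fully convolutional encoder–decoders with $3^3$
kernels and LeakyReLU (slope 0.2) hidden activations:

* **ConvUNet-DIR** — four stride-2 encoder convolutions, a
  two-convolution bottleneck, four decoder levels (nearest-neighbour
  $2\times$ upsampling, concatenation with the matching encoder feature
  map — the 2-channel input at full resolution — then a stride-1
  convolution), three full-resolution refinement convolutions, and a
  final *linear* convolution to 3 channels. Default widths: encoder
  (16, 32, 32, 32), bottleneck (32, 32), decoder (32, 32, 32, 32),
  refinement (16, 16, 16). The published description of this
  architecture does not state its per-level widths legibly, so these
  defaults mirror the VoxelMorph family scale; they are configuration
  (`network_config()`), not structure, and the resulting parameter count
  (336,019) is documented as an approximation of the original model's
  328,227.
* **VM1 / VM2 baselines** — the two standard VoxelMorph configurations,
  built exactly: both share the (16, 32, 32, 32) encoder; VM1's decoder
  is (32, 32, 32, 32) plus an 8-filter half-resolution and an 8-filter
  full-resolution convolution after concatenating the input; VM2 widens
  the tail (extra 32-filter half-resolution convolution, then
  16/16-filter full-resolution convolutions). These reproduce the
  published trainable-parameter counts **259,675** and **300,547**
  exactly, which is also the arithmetic the acceptance checks pin.

Design choices the text of the formulation leaves open, resolved here:
upsampling is nearest-neighbour followed by a stride-1 convolution (no
transposed convolutions — and the only reading under which the VM1/VM2
parameter counts come out right); skip concatenation happens *before*
the level's convolution in all variants; the flow head is
zero-initialized so an untrained network predicts exactly the identity
transform, the standard stabilization for unsupervised registration.

The numerical engine (3D convolution forward/backward, upsampling, the
spatial transformer and its gradients) is implemented in
Rcpp/RcppArmadillo with convolutions evaluated one kernel tap at a time
as GEMMs over a shifted channel buffer; Adam (β₁ = 0.9, β₂ = 0.999,
ε = 10⁻⁸) with bias correction performs the updates.

## Preprocessing

`preprocess_volume()` applies the standard chain for skull-stripped
brain MR: crop (centred on the nonzero bounding box — the informative
region — falling back to the geometric centre per axis when the box
exceeds the crop), trilinear resize (pixel-centre-aligned coordinates),
then per-volume z-score normalization followed by min–max rescaling to
$[0,1]$. Normalization statistics are **per volume**, not per dataset:
the point of the step is harmonizing scans from different
scanners/protocols, which a dataset-level affine would not do. A
constant volume has no intensity scale and returns all zeros.
`split_dataset()` partitions subject ids with `round(f·n)` (half away
from zero) for the validation and test fractions and the remainder to
training, reproducing the 102/26/32 split of 160 subjects at
64 %/16 %/20 %.

## The synthetic phantom

Everything downstream is testable without imaging data via
`make_registration_pair()`:

* **Anatomy** (`generate_phantom()`): an ellipsoidal "brain" (semi-axes
  ≈ 0.38 of the grid, jittered per seed) with a smooth radial intensity
  profile in $[0.2, 1]$ over an exactly-zero background, internal
  ellipsoidal structures of distinct intensity, one low-intensity
  lesion sphere, and — importantly — a smooth random *parenchymal
  texture* (Gaussian-smoothed white noise, sd `texture_amp` = 0.1,
  correlation length ≈ 2 voxels) baked into the tissue. The texture is
  what makes a dense deformation identifiable from intensities: a
  piecewise-flat phantom suffers the aperture problem (any sliding
  along an isophote is invisible to an intensity loss), and no training
  scheme could then recover the true field in flat interiors.
* **Deformation** (`sample_smooth_field()`): per-component white noise
  convolved with a Gaussian (sd `smooth_sigma`), zeroed on a 2-voxel
  boundary shell (no sample ever leaves the grid), rescaled so the
  maximum displacement magnitude equals `amplitude` exactly.
* **Pair construction**: the stored `true_field` is, by convention, the
  field that registers *moving onto fixed*. The moving image is
  produced by resampling the noiseless fixed anatomy through the
  fixed-point inverse of that field (10 iterations of
  $s^{-1}(x) = -s(x + s^{-1}(x))$, a refinement of the small-deformation
  approximation $s^{-1} \approx -s$), so `warp(moving, true_field)`
  reproduces `fixed` up to interpolation error (mean absolute error
  < 0.02 at amplitude 2 with no noise). Acquisition noise
  (`noise_sd`, default 0.02) is then drawn *independently* for each
  image of the pair, inside the brain mask only.

What the phantom does **not** emulate: multi-modal intensity
relationships, bias fields, resection cavities, tumor mass effect,
partial-volume anatomy at 1 mm detail. Tests passing on phantoms
therefore demonstrate the correctness of the machinery and the
learnability of smooth, intensity-preserving deformations — not clinical
performance on BraTS-Reg-scale data.

## Evaluation

* **Dice** of the warped moving brain mask against the fixed mask,
  $2|A\cap B| / (|A| + |B|)$; masks are warped with nearest-neighbour
  lookup to preserve binarity (trilinear + 0.5 threshold is available);
  two empty masks score 1 by convention, empty vs non-empty 0.
* **SSIM** per the standard formula with $C_1 = (0.01 L)^2$,
  $C_2 = (0.03 L)^2$, $L = 1$ for normalized volumes. Statistics are
  computed over sliding uniform $7^3$ windows (biased moments, full
  interior windows only) and averaged; `global = TRUE` computes the
  literal single-window form instead.
* **Endpoint error** — mean Euclidean distance between predicted and
  true displacement vectors over the brain mask — exists only for
  synthetic pairs and is the sharpest test that the *field*, not just
  the warped appearance, is right.

## Scaled-down study conditions

The end-to-end checks train ConvUNet-DIR on 8 synthetic $32^3$ pairs
(true-field amplitude 3 voxels, `smooth_sigma` 6, noise sd 0.02) with
one held-out pair, batch size 1, for 30 epochs of Adam at learning rate
$10^{-3}$, and compare a $\lambda = 1$ against a $\lambda = 0$ run under
identical seeds. These sizes are the package's chosen desk-scale study:
large enough for the training loss to fall, for Dice on the held-out
pair to improve over the unregistered baseline, for the fitted fields'
mean endpoint error over the training pairs (brain-masked) to beat the
zero-displacement baseline, and for the $\lambda$ effect (smoother
predicted fields with regularization, the qualitative analogue of the
published $\lambda$ sweep) to be visible — small enough to run on one
CPU in minutes. The learning rate is larger than the full-scale default
($10^{-4}$, 150 epochs at $128^3$) because the epoch budget is an order
of magnitude smaller; the full-scale defaults remain the package
defaults (`train_config()`). At a few hundred gradient steps the model
is still underfit in the field-recovery sense — generalization of the
*field* to unseen pairs keeps improving well beyond this budget, which
is why the endpoint-error statement is about the pairs the model was
fit to, while the overlap (Dice) statement, which saturates much
earlier, is made on the held-out pair. An optional global
gradient-norm ceiling (`grad_clip`) tames the occasional large
similarity gradients of batch-size-1 training; it is off by default.

Known limitations: single-modality NCC only (no mutual information);
no diffeomorphic integration or inverse-consistency constraints; batch
size 1 Adam training; R-level training loop intended for desk-scale
experiments rather than GPU-scale datasets.
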