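---
title: "Dual-network registration of serial-section EM images: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-network registration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the two-stage registration model, the unsupervised losses, the synthetic
deformation generator, and every numerical or design choice that the code
had to make where more than one reasonable option existed.

## The registration model

Registration estimates a deformation that warps a *source* section image
onto a *reference* section. The package represents deformations in two
forms:

* `affine_params` — six scalars `(a11, a12, a21, a22, tx, ty)` of the map
  `x -> A x + t` on the normalized grid;
* `dense_field` — a per-pixel displacement `(dx, dy)`, also in
  normalized units.

**Coordinate convention.** The image grid spans [−1, 1] in each axis with
pixel centers on the endpoints (align-corners). This makes affine
parameters and displacement bounds resolution-free: the residual
network's ±0.1 output bound means "up to 5% of the image extent"
regardless of pixel count. Displacements are *backward*: the output pixel
at grid position `x` samples the source at `x + d(x)`, the spatial
transformer convention, so warping is differentiable in the field.
Samples falling outside the image replicate the border value —
zero-padding would manufacture dark borders that the intensity loss would
then try to "register". Field channel order is `(dx, dy)` with `x`
horizontal (along matrix columns); this is asserted by tests since
nothing else in the data model fixes it.

The deformation is split into a global linear part and a local residual:

1. **LinearNet** sees the pair downsampled (block mean) to its input
   resolution and regresses the affine parameters as
   `identity + 0.01 * pooled_output`. The encoder is eight convolutions
   (7×7 then 3×3; five stride-2 stages with ReLU, three stride-1 stages
   with no activation so negative outputs are reachable) followed by
   global average pooling to six values.
2. The source is warped by the *dense expansion* of that affine at full
   resolution — the affine and the residual field go through one and the
   same sampler, which also makes the near-identity penalty on the
   expanded field literal.
3. **NonlinearNet** sees the affinely warped source concatenated with the
   reference and regresses the residual field: four stride-2 encoder
   stages (batch norm + LeakyReLU 0.2), three stride-1 decoder stages fed
   by 2× nearest-neighbour upsampling combined with the matching encoder
   feature, and a final `0.1 * tanh` output stage.
4. The final registered image warps the affinely warped source by the
   residual field. (The alternative reading — apply the residual to the
   *raw* source — is available as `residual_on_source = TRUE`; the
   composed-field semantics differ only by interpolation error when the
   affine is small.)

**Skip connections.** At reference widths the upsampled decoder branch
and the encoder branch have unequal channel counts (e.g. 512 against
256), so element-wise addition is not defined. The package inserts a 1×1
channel projection on the upsampled branch before the addition
(`skip = "project_add"`); concatenation is available as
`skip = "concat"`. This is the one place where the published layer table
under-determines the architecture.

**Identity start.** The ×0.01 output damping makes any small final-layer
initialization start near the identity transform. `final_init = "zero"`
makes the start *exactly* the identity, but a zero final layer also
makes the output constant and blocks all gradient into the seven earlier
layers until the final layer has moved off zero; in short training runs
the affine branch then never learns input-dependent features at all (we
verified this with a directly supervised regression probe). The default
is therefore Kaiming initialization everywhere — still identity-inclined
through the damping, but trainable from step one.

## The unsupervised losses

All four terms are per-element means, so the weights keep their meaning
across image resolutions:

* `intensity_loss` — `mean|I_t − I˙_s| + mean|I_t − I¨_s|`, both stages
  compared to the reference;
* `ssim_loss` — `(1 − SSIM)/2` per stage, using the same 3×3 patchwise
  SSIM machinery as the evaluation metric (single implementation, two
  call sites). The halving maps SSIM ∈ [−1, 1] to a loss in [0, 1] per
  stage; `halved = FALSE` gives the other reading of an ambiguous
  rendering;
* `linear_constraint` — `mean|F_l|` of the dense affine expansion; keeps
  an early affine estimate from drifting into implausible scalings;
* `smoothness_constraint` — mean L1 of first plus second forward finite
  differences of the residual field, valid region only (padding would
  bias the boundary).

Default weights are (0.15, 0.85, 1, 0.1). Whether the near-identity
penalty applies to the dense field or to the raw parameter vector is not
determined by its definition; both vanish at identity, and the package
evaluates it on the dense field, which is what the "every value of the
field near zero" motivation describes.

**Gradient routing.** Each stage is supervised by its own image terms:
the affine-stage L1/SSIM gradients flow through the differentiable warp
into LinearNet (together with the near-identity penalty), the
residual-stage gradients into NonlinearNet (with the smoothness
penalty). The fully end-to-end alternative — additionally propagating
the residual stage's gradients into LinearNet through NonlinearNet's
input — is available (`detach_stages = FALSE`) but is not the default:
with batch-size-2 batch-norm statistics that cross path is noise-
dominated and empirically makes the affine estimate oscillate without
converging in short runs.

## Synthetic data

`synth_texture()` emulates a serial-section EM texture: a Voronoi
tessellation into `n_cells` cell bodies (the label image, values exactly
1..n), rendered with per-cell gray levels, dark membranes along the
boundaries, multi-octave smoothed Gaussian noise inside the cells, and
pixel noise. The multi-octave texture matters: real EM is texture-dense
at all scales, and image-loss gradients exist everywhere; with flat cell
interiors the unsupervised losses carry almost no long-range signal and
no registration method of this family can recover an affine.

`make_pair()` applies a random deformation to a base texture: an affine
drawn as identity plus N(0, `affine_sigma`²) on all six entries, composed
with a thin-plate-spline field whose control points are uniform over the
grid and whose displacements are N(0, `tps_sigma`²) per component
(radial basis `r² log r²` plus affine term, solved exactly per
component; `tps_reg` adds optional ridge regularization). The source is
the reference warped by the total field — bilinear for intensity,
nearest-neighbour for labels (anything else is meaningless for integer
labels) — and the drawn ground truth is stored for recovery tests.

Defaults `affine_sigma = 0.05`, `n_control_points = 10`,
`tps_sigma = 0.03` are declared assumptions, not published values: they
make deformations visibly nontrivial (several pixels at 128²) while the
residual after affine removal stays within the network's ±0.1
representable range. Datasets are expanded by re-deforming a small set of
base textures (`n_base`, default 1 — serial sections all come from one
volume) and split 0.8/0.1/0.1 by pair index under a fixed split seed.

What the generator does **not** emulate: section folds, staining
variation, lost sections, charging artefacts, or anisotropic blur.
Passing the desk-scale tests shows the estimator and its training loop
work; it does not certify performance on real acquisition artefacts.

## Evaluation metrics

`ssim()` is the three-factor form (luminance × contrast × structure) over
dense stride-1 3×3 windows with window means, unbiased standard
deviations and covariance, and the conventional stabilizers
`C1 = (0.01 L)², C2 = (0.03 L)², C3 = C2/2` at dynamic range `L = 1`.
Dense windows are used because 3×3 disjoint tiling would be
noise-dominated. `mean_dice_over_largest()` ranks reference regions by
pixel count (ties by label id), scores each selected region's Dice
`2|A∩B| / (|A|+|B|)` against the warped label, and averages; regions
absent from the warped label score 0, and both-empty masks score 1.
Matching is by identical integer id (labels are co-registered in the
emulated protocol); maximal-overlap matching is available via
`dice_config(match = "overlap")`.

## Training

`train_config()` defaults follow the full published schedule: Adam,
learning rate 0.001, batch size 2, 20 epochs, halving at epochs 10 and
15 (one reading of a rate "halved twice at the 10th epoch"; the halving
epochs are configurable), LinearNet at 256², NonlinearNet at 512².

`desk_train_config()` is the CPU preset used by the tests and the
acceptance script: 128² pairs, 64² LinearNet inputs, width multiplier
0.25, LinearNet output scale 0.05, learning rate 0.003. The choices are
scaling arguments, not magic: desk runs take ~10²–10³ optimization steps
instead of ~10⁴, so the affine branch must be able to traverse the
plausible parameter range (±0.15) in that many steps — under Adam each
weight moves ≈ lr per step, so travel is roughly
`output_scale × lr × steps × Σ|activations|`, and 0.01 × 0.001 × 10³ is
far too slow while 0.05 × 0.003 × 10³ is adequate. The rate itself sits
below the stability threshold of the *un-normalized* LinearNet encoder:
at lr ≥ 0.01 a single Adam step perturbs all weights coherently enough
to blow up the 8-layer forward (verified by a supervised-regression
probe that diverges at 0.01 and converges cleanly at 0.002–0.005).
Problem sizes in the tests — 16 pure-affine pairs at 100 epochs, 32
affine+TPS pairs at 50 epochs — are the package's desk-scale study
conditions.

Numerical details: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) with bias
correction; Kaiming fan-in init; batch-norm uses biased batch variance
in training and running statistics (momentum 0.1) in evaluation;
training aborts with a diagnostic on a non-finite loss; checkpoints
round-trip all weights, running statistics and optimizer moments
bit-identically.

## Known limitations

* **The bilinear kink at the identity.** At the exact identity start all
  sampling positions sit on grid nodes where bilinear interpolation is
  non-differentiable; the sampler returns the right-sided slope there.
  This biases the very first gradient steps and disappears as soon as
  the estimate moves off-grid.
* **The near-identity constraint is resolution-sensitive at desk
  scale.** Its gradient with respect to the affine (~0.5 in normalized
  units) does not depend on resolution, while image-loss gradients scale
  with (W−1)/2. At 512² the image terms dominate comfortably; at 128²
  the constraint is ~4× stronger relative to them and holds the affine
  short of full alignment. One measurable consequence: at desk scale the
  intensity-only loss subset can score *higher* held-out SSIM than the
  full loss — the opposite of the full-scale ordering, where the
  constraints' benefits (rescuing a random initialization, regularizing
  across ~10³ training pairs) actually bind. The package reports both
  configurations rather than reweighting the published loss.
* Dense fields are not guaranteed diffeomorphic and no field inversion
  is provided; 3-D (volumetric) fields are out of scope.
* Large sections are handled by downsampling to the working resolution;
  a crop/tile strategy for very large images is left to the caller.
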