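# dualreg

Unsupervised deformable registration of serial-section electron microscopy
(EM) image pairs with a two-stage dual network, plus the synthetic
deformation protocol and evaluation metrics needed to train and test it
without any external data.

Reconstructing a tissue volume from serially cut EM sections requires
aligning each section to its neighbour. The deformation between two
sections decomposes naturally into a global linear part (the pose of the
section on the support film, well modelled by a 6-parameter affine map)
and a residual nonlinear part (local distortion from cutting), and the
package estimates the two parts with two small convolutional networks:

* **LinearNet** — an eight-stage stride-2 encoder that regresses the six
  affine parameters from a low-resolution concatenation of the source and
  reference images. Its pooled output `v` enters as
  `(a11, a12, a21, a22, tx, ty) = identity + 0.01 · v`, so the network
  starts near the identity transform.
* **NonlinearNet** — a shallow encoder-decoder with skip connections that
  regresses a dense residual displacement field from the affinely warped
  source and the reference at full resolution; a final `0.1 · tanh`
  bounds every displacement to (−0.1, 0.1) in normalized coordinates.

Both are trained **jointly and unsupervised** through a differentiable
bilinear warping layer against

```
L_total = 0.15 · L_I + 0.85 · L_SSIM + 1 · L_lc + 0.1 · L_nc
```

where `L_I` is the L1 intensity difference of both warped stages against
the reference, `L_SSIM = (1 − SSIM)/2` summed over both stages (3×3
patchwise SSIM), `L_lc = ‖F_l‖₁` keeps the dense expansion of the affine
deformation near zero, and `L_nc = ‖∇F_n‖₁ + ‖∇²F_n‖₁` keeps the residual
field smooth.

There is no deep-learning framework dependency: convolution, batch norm,
warping and their gradients are implemented in RcppArmadillo/R with
manual reverse-mode differentiation, verified by finite-difference tests.

## Worked example

Everything below runs on synthetic data generated by the package itself —
Voronoi "cell" textures deformed by a random affine plus a thin-plate
spline, the same protocol used to evaluate the method.

```r
library(dualreg)

# 16 pairs: one 128^2 neuron-like base texture, randomly re-deformed
ds <- make_dataset(16, resolution = 128,
                   spec = deformation_spec(affine_sigma = 0.05,
                                           n_control_points = 10,
                                           tps_sigma = 0.03),
                   seed = 101)

# desk-scale joint unsupervised training (CPU, a few minutes)
model <- train_dualnet(ds, desk_train_config(epochs = 100, seed = 202))
model
#> <dualreg_model> 622,712 params, 700 steps; final val SSIM 0.4595

res <- register_pair(model, ds$pairs[[2]])
res$metrics$ssim_before; res$metrics$ssim_after
#> [1] 0.3072523
#> [1] 0.7152062
res$metrics$dice_before; res$metrics$dice_after
#> [1] 0.8301605
#> [1] 0.9420664
```

`register_pair()` returns the estimated affine, the residual field, their
composition, both warped intermediates, and SSIM/Dice scores against the
reference. The SSIM rise (0.31 unregistered → 0.72 registered) and the Dice rise
(0.83 → 0.94 over the largest cells) say the network recovered most of
the applied deformation for this pair.

Individual pieces are usable on their own:

```r
p <- affine_params(tx = 0.06, ty = -0.04)      # normalized units
warped <- apply_affine(img, p)                  # == warp by its dense field
f <- random_tps_field(deformation_spec(), 128, 128, seed = 1)
total <- compose_fields(f, affine_to_field(p, 128, 128))
ssim(warped, img); dice(maskA, maskB)
```

A thin command-line front end covers the same workflow
(`simulate`, `train`, `register`, `evaluate`, `ablate`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/dualreg.R", package="dualreg"))') \
    simulate --out data/ --n-pairs 16 --resolution 128 --seed 1
```

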