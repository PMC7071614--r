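#' Training configuration
#'
#' Settings of the joint unsupervised training loop. Defaults follow the
#' published schedule: 20 epochs of Adam at learning rate 0.001, batch
#' size 2, the rate halved at epoch 10 and again at epoch 15, LinearNet
#' fed 256^2 downsamples and NonlinearNet 512^2 pairs.
#'
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Pairs per optimization step.
#' @param lr Adam learning rate.
#' @param lr_halve_epochs Epochs at whose start the rate is halved;
#'   `NULL` picks `ceiling(epochs/2)` and `ceiling(3*epochs/4)`.
#' @param seed RNG seed for weight init and batch shuffling.
#' @param linear_res LinearNet input side length (power of 2, >= 32).
#' @param nonlinear_res NonlinearNet input side length (a power of 2, at
#'   least 64, and a multiple of `linear_res`).
#' @param width_mult Channel width multiplier for both networks (1 =
#'   reference widths).
#' @param linear_output_scale Output scaling of LinearNet (see
#'   [linearnet_spec()]). The 0.01 default calibrates the affine update
#'   rate for full-schedule runs (~10^4 steps); short desk runs may raise
#'   it so the affine can travel the same distance in fewer steps.
#' @param linear_lr_mult Learning-rate multiplier for the LinearNet
#'   branch. Under Adam every weight moves about `lr` per step whatever
#'   the gradient scale, so at full schedule 1 is appropriate; short desk
#'   runs may raise it to let the affine branch's features evolve within
#'   the available steps.
#' @param weights A [loss_weights()]; zero a weight to ablate its term.
#' @param ssim_cfg [ssim_config()] used inside the SSIM loss.
#' @param halved Use the `(1 - SSIM)/2` per-term convention in the loss.
#' @param residual_on_source Apply the residual field to the raw source
#'   instead of the affinely warped source (the alternative dataflow
#'   reading; default FALSE warps the affinely warped image).
#' @param detach_stages Route each stage's supervision to its own branch
#'   (default): LinearNet receives the gradients of the affine-stage image
#'   terms (through the differentiable warp) plus the near-identity
#'   constraint, NonlinearNet those of the residual-stage terms plus the
#'   smoothness constraint. `FALSE` additionally propagates the residual
#'   stage's gradients into LinearNet through NonlinearNet's input and the
#'   second warp; with small batches that cross path is dominated by
#'   batch-norm noise and destabilizes the affine estimate.
#' @param skip NonlinearNet skip-combination mode (see
#'   [nonlinearnet_spec()]).
#' @param lrelu_slope LeakyReLU negative slope.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20, batch_size = 2, lr = 0.001,
                         lr_halve_epochs = NULL, seed = 1,
                         linear_res = 256, nonlinear_res = 512,
                         width_mult = 1, linear_output_scale = 0.01,
                         linear_lr_mult = 1, weights = loss_weights(),
                         ssim_cfg = ssim_config(), halved = TRUE,
                         residual_on_source = FALSE, detach_stages = TRUE,
                         skip = "project_add", lrelu_slope = 0.2) {
  is_pow2 <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0
  if (epochs < 1) stop("train_config: epochs must be >= 1")
  if (!is_pow2(linear_res) || linear_res < 32) {
    stop("train_config: linear_res must be a power of 2 >= 32")
  }
  if (!is_pow2(nonlinear_res) || nonlinear_res < 64 ||
      nonlinear_res %% linear_res != 0) {
    stop("train_config: nonlinear_res must be a power of 2 >= 64 and a",
         " multiple of linear_res")
  }
  if (is.null(lr_halve_epochs)) {
    lr_halve_epochs <- unique(pmax(2, c(ceiling(epochs / 2),
                                        ceiling(3 * epochs / 4))))
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_halve_epochs = as.integer(lr_halve_epochs),
                 seed = as.integer(seed),
                 linear_res = as.integer(linear_res),
                 nonlinear_res = as.integer(nonlinear_res),
                 width_mult = width_mult,
                 linear_output_scale = linear_output_scale,
                 linear_lr_mult = linear_lr_mult, weights = weights,
                 ssim_cfg = ssim_cfg, halved = halved,
                 residual_on_source = residual_on_source,
                 detach_stages = detach_stages,
                 skip = skip, lrelu_slope = lrelu_slope),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' A small-footprint preset for CPU experiments and tests: 128^2 pairs,
#' 64^2 LinearNet inputs, quarter-width networks, LinearNet output scale
#' 0.05 (so the affine branch can cover the plausible parameter range in
#' around a thousand optimization steps instead of the full schedule's
#' tens of thousands), and learning rate 0.003 -- above the full
#' schedule's 0.001 to speed up short runs, but below the threshold at
#' which the un-normalized affine encoder becomes unstable under Adam.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 100, lr = 0.003, linear_res = 64,
                   nonlinear_res = 128, width_mult = 0.25,
                   linear_output_scale = 0.05)
  do.call(train_config, utils::modifyList(defaults, args))
}

build_nets <- function(cfg) {
  dualnet(
    linearnet_spec(input_res = cfg$linear_res,
                   width_mult = cfg$width_mult,
                   output_scale = cfg$linear_output_scale %||% 0.01),
    nonlinearnet_spec(input_res = cfg$nonlinear_res,
                      width_mult = cfg$width_mult, skip = cfg$skip,
                      lrelu_slope = cfg$lrelu_slope))
}

pair_at_res <- function(pair, res) {
  f <- nrow(pair$source) / res
  if (f == 1) return(pair)
  if (f != round(f)) stop("pair resolution not divisible by target")
  image_pair(downsample_image(pair$source, f),
             downsample_image(pair$reference, f))
}

# Batched forward through the two-stage pipeline. Pairs must be at the
# NonlinearNet resolution. Returns everything the backward pass needs.
pipeline_fwd <- function(nets, pairs, cfg, training = FALSE) {
  R <- cfg$nonlinear_res
  ds <- R / cfg$linear_res
  B <- length(pairs)
  is_l <- lapply(pairs, function(p) p$source)
  it_l <- lapply(pairs, function(p) p$reference)
  xlin <- cat_batch(lapply(seq_len(B), function(i) {
    stack_batch(downsample_image(is_l[[i]], ds),
                downsample_image(it_l[[i]], ds))
  }))
  P <- linear_net_fwd(nets$linear, xlin)
  fl <- lapply(seq_len(B), function(i) {
    affine_to_field(as_affine_params(P[, i]), R, R)
  })
  warped_lin <- lapply(seq_len(B), function(i) {
    .warp_bilinear(is_l[[i]], field_dx(fl[[i]]), field_dy(fl[[i]]))
  })
  xnl <- cat_batch(lapply(seq_len(B), function(i) {
    stack_batch(warped_lin[[i]], it_l[[i]])
  }))
  Fn <- nonlinear_net_fwd(nets$nonlinear, xnl, training)
  warp_base <- if (cfg$residual_on_source) is_l else warped_lin
  warped_nonlin <- lapply(seq_len(B), function(i) {
    .warp_bilinear(warp_base[[i]], Fn[, , 1, i], Fn[, , 2, i])
  })
  list(P = P, fl = fl, Fn = Fn, warped_lin = warped_lin,
       warped_nonlin = warped_nonlin, warp_base = warp_base,
       is_l = is_l, it_l = it_l, B = B, R = R)
}

# One optimization step on a batch; returns the averaged loss report.
train_step <- function(nets, pairs, cfg, lr, t) {
  detach <- isTRUE(cfg$detach_stages)
  fw <- pipeline_fwd(nets, pairs, cfg, training = TRUE)
  B <- fw$B; R <- fw$R
  g_Fn <- array(0, dim = dim(fw$Fn))
  g_warped_lin <- vector("list", B)
  reports <- vector("list", B)
  lw <- vector("list", B)
  for (i in seq_len(B)) {
    fn_i <- dense_field(fw$Fn[, , 1, i], fw$Fn[, , 2, i])
    lo <- losses_with_grads(fw$it_l[[i]], fw$warped_lin[[i]],
                            fw$warped_nonlin[[i]], fw$fl[[i]], fn_i,
                            cfg$weights, cfg$ssim_cfg, cfg$halved)
    reports[[i]] <- lo$report
    r1 <- .warp_bilinear_bwd(fw$warp_base[[i]], fw$Fn[, , 1, i],
                             fw$Fn[, , 2, i], lo$g_warped_nonlin / B,
                             !detach)
    g_Fn[, , 1, i] <- lo$g_fn[, , 1] / B + r1$gdx
    g_Fn[, , 2, i] <- lo$g_fn[, , 2] / B + r1$gdy
    g_warped_lin[[i]] <- lo$g_warped_lin / B +
      (if (cfg$residual_on_source || detach) 0 else r1$gimg)
    lw[[i]] <- lo
  }
  zero_grads(all_layers(nets))
  gx_nl <- nonlinear_net_bwd(nets$nonlinear, g_Fn, need_gx = !detach)
  g <- norm_grid(R, R)
  gP <- matrix(0, 6, B)
  for (i in seq_len(B)) {
    gwl <- g_warped_lin[[i]] +
      (if (detach) 0 else gx_nl[, , 1, i])
    r2 <- .warp_bilinear_bwd(fw$is_l[[i]], field_dx(fw$fl[[i]]),
                             field_dy(fw$fl[[i]]), gwl, FALSE)
    gflx <- r2$gdx + lw[[i]]$g_fl[, , 1] / B
    gfly <- r2$gdy + lw[[i]]$g_fl[, , 2] / B
    gP[, i] <- c(sum(gflx * g$x), sum(gflx * g$y),
                 sum(gfly * g$x), sum(gfly * g$y),
                 sum(gflx), sum(gfly))
  }
  linear_net_bwd(nets$linear, gP)
  adam_step(nets$nonlinear$layers, lr, t)
  adam_step(nets$linear$layers, lr * (cfg$linear_lr_mult %||% 1), t)
  avg <- function(f) mean(vapply(reports, `[[`, numeric(1), f))
  structure(list(intensity = avg("intensity"), ssim = avg("ssim"),
                 linear = avg("linear"), smooth = avg("smooth"),
                 total = avg("total"), weights = cfg$weights),
            class = "loss_report")
}

#' Run the registration pipeline on one image pair
#'
#' The two-stage dataflow: the pair is downsampled to the LinearNet input
#' resolution and the six affine parameters are regressed; the source is
#' warped by the dense expansion of that affine at full resolution; the
#' warped source concatenated with the reference feeds NonlinearNet, whose
#' bounded residual field warps the affinely warped source into the final
#' registered image.
#'
#' @param pair An [image_pair()] at the NonlinearNet resolution (or an
#'   integer multiple of it, in which case it is block-downsampled).
#' @param nets A [dualnet()].
#' @param cfg A [train_config()] (resolutions must match `nets`).
#' @return An object of class `registration_result`: estimated
#'   `affine`, `fl_field`, `fn_field`, `total_field` (composition of the
#'   two), the warped intermediates `warped_lin` and `warped_nonlin`, and
#'   the input pair.
#' @export
forward_pipeline <- function(pair, nets, cfg) {
  labs <- list(src = pair$source_label, ref = pair$reference_label)
  pr <- pair_at_res(pair, cfg$nonlinear_res)
  fw <- pipeline_fwd(nets, list(pr), cfg, training = FALSE)
  fn_field <- dense_field(fw$Fn[, , 1, 1], fw$Fn[, , 2, 1])
  structure(list(
    affine = as_affine_params(fw$P[, 1]),
    fl_field = fw$fl[[1]],
    fn_field = fn_field,
    total_field = compose_fields(fn_field, fw$fl[[1]]),
    warped_lin = fw$warped_lin[[1]],
    warped_nonlin = fw$warped_nonlin[[1]],
    pair = pr, labels = labs), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> %d^2, affine (%s), max |Fn| = %.4f\n",
    nrow(x$warped_nonlin),
    paste(sprintf("%.3f", unclass(x$affine)), collapse = ", "),
    max(abs(x$fn_field))))
  invisible(x)
}

#' Jointly train the dual network, unsupervised
#'
#' Optimizes both networks end to end against the weighted unsupervised
#' loss with Adam; gradients of the image-space losses flow through both
#' warping layers into both networks. Logs per-step loss terms and
#' per-epoch validation SSIM. Aborts with a diagnostic if the loss goes
#' non-finite.
#'
#' @param dataset A `synthetic_dataset` (see [make_dataset()]) or a plain
#'   list of [image_pair()]s (then split 0.8/0.1/0.1 by index).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `dualreg_model`: trained `nets`, `cfg`,
#'   per-step `history` and per-epoch `validation` tibbles.
#' @export
train_dualnet <- function(dataset, cfg = train_config(), verbose = FALSE) {
  if (!inherits(dataset, "synthetic_dataset")) {
    n <- length(dataset)
    set.seed(99)
    tags <- sample(rep(c("train", "val", "test"),
                       times = round_split(n, c(0.8, 0.1, 0.1))))
    dataset <- structure(
      list(pairs = dataset,
           split = factor(tags, levels = c("train", "val", "test"))),
      class = "synthetic_dataset")
  }
  pairs <- lapply(dataset$pairs, pair_at_res, res = cfg$nonlinear_res)
  idx_train <- which(dataset$split == "train")
  idx_val <- which(dataset$split == "val")
  if (length(idx_train) == 0) stop("train_dualnet: empty training split")

  set.seed(cfg$seed)
  nets <- build_nets(cfg)
  lr <- cfg$lr
  t <- 0
  hist <- list()
  val <- list()
  for (ep in seq_len(cfg$epochs)) {
    if (ep %in% cfg$lr_halve_epochs) lr <- lr / 2
    ord <- sample(idx_train)
    nb <- ceiling(length(ord) / cfg$batch_size)
    for (b in seq_len(nb)) {
      take <- ord[((b - 1) * cfg$batch_size + 1):
                    min(b * cfg$batch_size, length(ord))]
      t <- t + 1
      rep_b <- train_step(nets, pairs[take], cfg, lr, t)
      if (!is.finite(rep_b$total)) {
        stop(sprintf(
          "train_dualnet: non-finite loss at epoch %d step %d (LI=%g, LSSIM=%g, Llc=%g, Lnc=%g)",
          ep, t, rep_b$intensity, rep_b$ssim, rep_b$linear, rep_b$smooth))
      }
      hist[[t]] <- tibble::tibble(epoch = ep, step = t, lr = lr,
                                  intensity = rep_b$intensity,
                                  ssim = rep_b$ssim, linear = rep_b$linear,
                                  smooth = rep_b$smooth,
                                  total = rep_b$total)
    }
    vs <- if (length(idx_val) > 0) {
      mean(vapply(idx_val, function(i) {
        fw <- pipeline_fwd(nets, pairs[i], cfg, training = FALSE)
        ssim(fw$warped_nonlin[[1]], pairs[[i]]$reference, cfg$ssim_cfg)
      }, numeric(1)))
    } else NA_real_
    val[[ep]] <- tibble::tibble(epoch = ep, val_ssim = vs)
    if (verbose) {
      message(sprintf("epoch %d/%d: total %.4f, val SSIM %.4f", ep,
                      cfg$epochs, hist[[t]]$total, vs))
    }
  }
  structure(list(nets = nets, cfg = cfg,
                 history = do.call(rbind, hist),
                 validation = do.call(rbind, val)),
            class = "dualreg_model")
}

#' @export
print.dualreg_model <- function(x, ...) {
  v <- x$validation$val_ssim
  cat(sprintf(
    "<dualreg_model> %s params, %d steps; final val SSIM %.4f\n",
    format(n_params(x$nets), big.mark = ","), nrow(x$history),
    v[length(v)]))
  invisible(x)
}

#' Glance at a trained model
#' @param x A `dualreg_model`.
#' @param ... Unused.
#' @return One-row tibble: parameter count, steps, final losses and
#'   validation SSIM.
#' @exportS3Method generics::glance
glance.dualreg_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(n_params = n_params(x$nets), steps = nrow(x$history),
                 total = last$total,
                 val_ssim = x$validation$val_ssim[nrow(x$validation)])
}

#' Tidy training history
#' @param x A `dualreg_model`.
#' @param ... Unused.
#' @return The per-step loss tibble.
#' @exportS3Method generics::tidy
tidy.dualreg_model <- function(x, ...) x$history

#' Register an image pair with a trained model
#'
#' Runs the pipeline in evaluation mode and scores the result: SSIM of the
#' registered image against the reference (with the unregistered baseline)
#' and, when labels are present, mean Dice over the largest reference
#' regions for the source label warped by the composed estimated field.
#'
#' @param model A `dualreg_model`.
#' @param pair An [image_pair()].
#' @param dice_cfg A [dice_config()].
#' @return A `registration_result` with a `metrics` list attached.
#' @export
register_pair <- function(model, pair, dice_cfg = dice_config()) {
  res <- forward_pipeline(pair, model$nets, model$cfg)
  m <- list(
    ssim_before = ssim(res$pair$source, res$pair$reference,
                       model$cfg$ssim_cfg),
    ssim_after = ssim(res$warped_nonlin, res$pair$reference,
                      model$cfg$ssim_cfg))
  if (!is.null(res$labels$src) && !is.null(res$labels$ref)) {
    f <- nrow(res$labels$src) / model$cfg$nonlinear_res
    slab <- res$labels$src; rlab <- res$labels$ref
    if (f > 1) { # nearest-subsample labels to the working resolution
      ii <- seq(1, nrow(slab), by = f)
      slab <- slab[ii, ii]; rlab <- rlab[ii, ii]
    }
    warped_lab <- warp_image(slab, res$total_field, mode = "nearest")
    m$dice_before <- mean_dice_over_largest(slab, rlab, dice_cfg)$mean_dice
    m$dice_after <- mean_dice_over_largest(warped_lab, rlab,
                                           dice_cfg)$mean_dice
    res$warped_label <- warped_lab
  }
  res$metrics <- m
  res
}

#' Evaluate a model on a set of pairs
#'
#' @param model A `dualreg_model`.
#' @param pairs List of [image_pair()]s.
#' @param dice_cfg A [dice_config()].
#' @return Tibble with one row per pair (SSIM and, when labels exist,
#'   Dice, before and after registration).
#' @export
evaluate_model <- function(model, pairs, dice_cfg = dice_config()) {
  rows <- lapply(seq_along(pairs), function(i) {
    m <- register_pair(model, pairs[[i]], dice_cfg)$metrics
    tibble::tibble(pair = i, ssim_before = m$ssim_before,
                   ssim_after = m$ssim_after,
                   dice_before = m$dice_before %||% NA_real_,
                   dice_after = m$dice_after %||% NA_real_)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Loss-subset and resolution ablation harness
#'
#' Trains one model per configuration and scores each on the test split,
#' mirroring the structure of a loss-ablation table (cumulative subsets of
#' the four terms) and/or an input-resolution grid.
#'
#' @param dataset A `synthetic_dataset`.
#' @param loss_subsets Named list; each element is a character vector of
#'   active loss terms (subset of `c("intensity", "ssim", "linear",
#'   "smooth")`). Defaults to the cumulative ladder.
#' @param resolutions Optional data frame with columns `linear_res` and
#'   `nonlinear_res`; each row is crossed with each loss subset.
#' @param cfg Base [train_config()].
#' @return Tibble with one row per configuration: the subset name,
#'   resolutions, and mean test SSIM/Dice after registration.
#' @export
ablate <- function(dataset,
                   loss_subsets = list(
                     "LI" = "intensity",
                     "LI+LSSIM" = c("intensity", "ssim"),
                     "LI+LSSIM+Llc" = c("intensity", "ssim", "linear"),
                     "LI+LSSIM+Llc+Lnc" = c("intensity", "ssim", "linear",
                                            "smooth")),
                   resolutions = NULL, cfg = desk_train_config()) {
  if (is.null(resolutions)) {
    resolutions <- data.frame(linear_res = cfg$linear_res,
                              nonlinear_res = cfg$nonlinear_res)
  }
  idx_test <- which(dataset$split == "test")
  if (length(idx_test) == 0) idx_test <- seq_along(dataset$pairs)
  rows <- list()
  for (r in seq_len(nrow(resolutions))) {
    for (nm in names(loss_subsets)) {
      w <- loss_weights()
      for (term in names(w)) {
        w[[term]] <- if (term %in% loss_subsets[[nm]]) {
          cfg$weights[[term]]
        } else 0
      }
      cfg_i <- cfg
      cfg_i$weights <- w
      cfg_i$linear_res <- resolutions$linear_res[r]
      cfg_i$nonlinear_res <- resolutions$nonlinear_res[r]
      model <- train_dualnet(dataset, cfg_i)
      ev <- evaluate_model(model, dataset$pairs[idx_test])
      rows[[length(rows) + 1]] <- tibble::tibble(
        loss = nm, linear_res = cfg_i$linear_res,
        nonlinear_res = cfg_i$nonlinear_res,
        ssim = mean(ev$ssim_after), dice = mean(ev$dice_after))
    }
  }
  do.call(rbind, rows)
}

#' Save / load a model checkpoint
#'
#' One archive holding both networks' weights, batch-norm running
#' statistics, optimizer moments, architecture specs and the full training
#' configuration. Loading rebuilds the networks and restores state
#' bit-identically.
#'
#' @param model A `dualreg_model`.
#' @param path Destination file (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `dualreg_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "dualreg-checkpoint-1",
               linear_spec = model$nets$linear$spec,
               nonlinear_spec = model$nets$nonlinear$spec,
               linear_state = layers_state(model$nets$linear$layers),
               nonlinear_state = layers_state(model$nets$nonlinear$layers),
               cfg = model$cfg, history = model$history,
               validation = model$validation),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "dualreg-checkpoint-1")) {
    stop("load_checkpoint: not a dualreg checkpoint")
  }
  nets <- dualnet(ck$linear_spec, ck$nonlinear_spec)
  layers_restore(nets$linear$layers, ck$linear_state)
  layers_restore(nets$nonlinear$layers, ck$nonlinear_state)
  structure(list(nets = nets, cfg = ck$cfg, history = ck$history,
                 validation = ck$validation), class = "dualreg_model")
}

#' Mean endpoint error of a deformation against a known affine
#'
#' For a synthetic pair built by warping the reference with ground-truth
#' affine map `x -> A x + t`, the perfectly recovered warp of the source
#' is the inverse map. This measures the mean Euclidean distance (in
#' normalized units) between the estimated map `x + d(x)` and
#' `A^{-1}(x - t)` over all grid points. With `field = NULL` (identity,
#' no registration) it gives the unregistered baseline.
#'
#' @param field A `dense_field` (the estimated total deformation), or
#'   `NULL` for the identity baseline.
#' @param gt_affine The ground-truth [affine_params()] used to deform the
#'   reference into the source.
#' @param h,w Grid size (defaults to the field's).
#' @return Mean endpoint error in normalized units.
#' @export
endpoint_error <- function(field, gt_affine, h = nrow(field),
                           w = ncol(field)) {
  p <- as_affine_params(gt_affine)
  A <- matrix(p[1:4], 2, 2, byrow = TRUE)
  t_ <- p[5:6]
  Ai <- solve(A)
  g <- norm_grid(h, w)
  tx <- Ai[1, 1] * (g$x - t_[1]) + Ai[1, 2] * (g$y - t_[2])
  ty <- Ai[2, 1] * (g$x - t_[1]) + Ai[2, 2] * (g$y - t_[2])
  if (is.null(field)) {
    ex <- g$x; ey <- g$y
  } else {
    field <- as_dense_field(field)
    ex <- g$x + field_dx(field)
    ey <- g$y + field_dy(field)
  }
  mean(sqrt((ex - tx)^2 + (ey - ty)^2))
}
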