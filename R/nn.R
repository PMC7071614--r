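# Minimal layer stack with manual reverse-mode gradients. Layers are
# environments holding parameters, Adam moments and forward caches; the
# network definitions in nets.R wire them into fixed graphs. Feature maps
# are H x W x C x N arrays throughout.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

kaiming_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  array(stats::rnorm(kh * kw * cin * cout, 0, sd), dim = c(kh, kw, cin, cout))
}

layer_conv <- function(kh, kw, cin, cout, stride = 1, pad = NULL,
                       init = c("kaiming", "zero")) {
  init <- match.arg(init)
  if (is.null(pad)) pad <- kh %/% 2
  w <- if (init == "zero") {
    array(0, dim = c(kh, kw, cin, cout))
  } else {
    kaiming_init(kh, kw, cin, cout)
  }
  new_layer("conv", w = w, b = numeric(cout), stride = as.integer(stride),
            pad = as.integer(pad))
}

conv_fwd <- function(e, x) {
  e$x <- x
  .conv2d_fwd(x, e$w, e$b, e$stride, e$pad)
}

conv_bwd <- function(e, g, need_gx = TRUE) {
  r <- .conv2d_bwd(e$x, e$w, g, e$stride, e$pad, need_gx)
  e$gw <- if (is.null(e$gw)) r$gw else e$gw + r$gw
  e$gb <- if (is.null(e$gb)) r$gb else e$gb + r$gb
  r$gx
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", gamma = rep(1, c), beta = rep(0, c),
            run_mean = rep(0, c), run_var = rep(1, c),
            momentum = momentum, eps = eps)
}

# broadcast a per-channel vector over an [H, W, C, N] array
bcast_c <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

bn_fwd <- function(e, x, training) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3]) # (H*W*N) x C
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2 # biased, standard for BN batch stats
    e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * mu
    e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * va
  } else {
    mu <- e$run_mean
    va <- e$run_var
  }
  inv <- 1 / sqrt(va + e$eps)
  xhat <- (x - bcast_c(mu, d)) * bcast_c(inv, d)
  e$xhat <- xhat
  e$inv <- inv
  e$training <- training
  xhat * bcast_c(e$gamma, d) + bcast_c(e$beta, d)
}

bn_bwd <- function(e, g) {
  d <- dim(g)
  m <- d[1] * d[2] * d[4]
  gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = d[3])
  xh <- matrix(aperm(e$xhat, c(1, 2, 4, 3)), ncol = d[3])
  e$ggamma <- (if (is.null(e$ggamma)) 0 else e$ggamma) + colSums(gm * xh)
  e$gbeta <- (if (is.null(e$gbeta)) 0 else e$gbeta) + colSums(gm)
  dxhat <- g * bcast_c(e$gamma, d)
  if (!isTRUE(e$training)) {
    return(dxhat * bcast_c(e$inv, d))
  }
  dxm <- matrix(aperm(dxhat, c(1, 2, 4, 3)), ncol = d[3])
  s1 <- colSums(dxm)
  s2 <- colSums(dxm * xh)
  gx <- (dxhat - bcast_c(s1 / m, d) - e$xhat * bcast_c(s2 / m, d)) *
    bcast_c(e$inv, d)
  gx
}

layer_act <- function(kind, slope = 0.2) new_layer("act", kind = kind,
                                                   slope = slope)

act_fwd <- function(e, x) {
  out <- switch(e$kind,
    relu = pmax(x, 0),
    lrelu = pmax(x, 0) + e$slope * pmin(x, 0),
    tanh = tanh(x))
  if (is.null(dim(out))) dim(out) <- dim(x)
  e$cache <- if (e$kind == "tanh") out else x
  out
}

act_bwd <- function(e, g) {
  switch(e$kind,
    relu = g * (e$cache > 0),
    lrelu = g * ((e$cache > 0) + e$slope * (e$cache <= 0)),
    tanh = g * (1 - e$cache^2))
}

# global average pooling: [H, W, C, N] -> C x N
gap_fwd <- function(x) {
  d <- dim(x)
  out <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  attr(out, "in_dim") <- d
  out
}

gap_bwd <- function(g, in_dim) {
  d <- in_dim
  array(rep(as.vector(g), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}

# 2x nearest-neighbour upsampling and its adjoint (sum over 2x2 blocks)
up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

up2_bwd <- function(g) {
  d <- dim(g)
  ih <- seq(1, d[1], by = 2)
  iw <- seq(1, d[2], by = 2)
  g[ih, iw, , , drop = FALSE] + g[ih + 1, iw, , , drop = FALSE] +
    g[ih, iw + 1, , , drop = FALSE] + g[ih + 1, iw + 1, , , drop = FALSE]
}

# ---- parameter plumbing ----------------------------------------------------

layer_params <- function(e) {
  switch(e$type,
    conv = list(w = "w", b = "b"),
    bn = list(gamma = "gamma", beta = "beta"),
    list())
}

layer_n_params <- function(e) {
  sum(vapply(layer_params(e), function(nm) length(get(nm, envir = e)),
             numeric(1)))
}

zero_grads <- function(layers) {
  for (e in layers) {
    e$gw <- NULL; e$gb <- NULL; e$ggamma <- NULL; e$gbeta <- NULL
  }
  invisible(NULL)
}

grad_name <- function(p) switch(p, w = "gw", b = "gb", gamma = "ggamma",
                                beta = "gbeta")

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (e in layers) {
    for (p in names(layer_params(e))) {
      g <- get0(grad_name(p), envir = e)
      if (is.null(g)) next
      mslot <- paste0("adam_m_", p)
      vslot <- paste0("adam_v_", p)
      m <- get0(mslot, envir = e, ifnotfound = 0) * beta1 + (1 - beta1) * g
      v <- get0(vslot, envir = e, ifnotfound = 0) * beta2 + (1 - beta2) * g^2
      assign(mslot, m, envir = e)
      assign(vslot, v, envir = e)
      val <- get(p, envir = e) - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      assign(p, val, envir = e)
    }
  }
  invisible(NULL)
}

# snapshot/restore of all learnable state (weights, BN running stats,
# optimizer moments) as plain lists, used by checkpointing
layers_state <- function(layers) {
  lapply(layers, function(e) {
    nm <- setdiff(ls(e), c("type", "x", "xhat", "inv", "cache", "training",
                           "gw", "gb", "ggamma", "gbeta"))
    s <- mget(nm, envir = e)
    s$type <- e$type
    s
  })
}

layers_restore <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    s <- state[[i]]
    stopifnot(identical(layers[[i]]$type, s$type))
    for (nm in setdiff(names(s), "type")) {
      assign(nm, s[[nm]], envir = layers[[i]])
    }
  }
  invisible(layers)
}

stack_batch <- function(...) {
  # stack same-size H x W matrices channel-wise into [H, W, C, 1]
  ms <- list(...)
  d <- dim(ms[[1]])
  array(unlist(ms), dim = c(d[1], d[2], length(ms), 1L))
}

cat_batch <- function(xs) {
  # concatenate [H, W, C, 1] arrays along the batch axis
  d <- dim(xs[[1]])
  array(unlist(xs), dim = c(d[1], d[2], d[3], length(xs)))
}
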