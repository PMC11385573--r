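# Compact UNet encoder-decoder and its training machinery.
#
# The network is a standard skip-connected encoder-decoder: each encoder
# block is a 3x3 convolution + ReLU followed by 2x2 mean pooling; the
# bottleneck is one more conv; each decoder block upsamples (nearest
# neighbour), concatenates the matching encoder feature map, and convolves
# down the configured decoder channel ladder; a 1x1 head produces one logit
# per pixel. Depth equals length(decoder_channels); encoder channels are the
# reversed ladder. Forward and backward passes are written out explicitly on
# top of the compiled im2col/GEMM conv kernels, and the gradients are checked
# against finite differences in the test suite.
#
# Activations are H x W x C x N arrays throughout.

conv_param <- function(k, cin, cout, group, norm = TRUE) {
  # He-normal initialization, drawn from the current RNG stream. Every
  # interior block is conv -> channel normalization -> ReLU; the 1x1 head
  # has no normalization and its bias is initialized at the prior log-odds
  # of a fossil pixel so training starts from the base rate rather than
  # from p = 0.5.
  w <- array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  p <- list(w = w, b = numeric(cout), group = group, norm = norm)
  if (norm) {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
  }
  p
}

# Per-channel normalization over the current batch (all pixels and samples),
# the batch-statistics form of batch normalization. Statistics always come
# from the input being processed, so inference is deterministic and
# independent of any training-time running averages.
bn_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), m, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  out <- aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = out, xhat = xhat, istd = istd)
}

bn_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), m, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, `*`)
  # dx = istd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat * xhat))
  t1 <- sweep(dxhat, 2, colSums(dxhat) / m)
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / m, `*`)
  dxm <- sweep(t1 - t2, 2, cache$istd, `*`)
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

unet_init <- function(in_channels, decoder_channels) {
  ps_assert(length(decoder_channels) >= 1L && all(diff(decoder_channels) < 0) ||
              length(decoder_channels) == 1L,
            "paleoseg_config_error", "decoder_channels must be strictly decreasing")
  D <- length(decoder_channels)
  ec <- rev(decoder_channels)
  layers <- list()
  cin <- in_channels
  for (d in seq_len(D)) {
    layers[[paste0("enc", d)]] <- conv_param(3L, cin, ec[d], "encoder")
    cin <- ec[d]
  }
  layers[["bottleneck"]] <- conv_param(3L, ec[D], ec[D], "encoder")
  prev <- ec[D]
  for (d in seq_len(D)) {
    skip <- ec[D - d + 1L]
    layers[[paste0("dec", d)]] <- conv_param(3L, prev + skip, decoder_channels[d], "decoder")
    prev <- decoder_channels[d]
  }
  layers[["head"]] <- conv_param(1L, prev, 1L, "decoder", norm = FALSE)
  layers[["head"]]$b <- stats::qlogis(0.1) # prior log-odds of a fossil pixel
  list(layers = layers, depth = D, in_channels = as.integer(in_channels),
       decoder_channels = as.integer(decoder_channels))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

meanpool2 <- function(x) {
  d <- dim(x)
  ro <- seq.int(1L, d[1], 2L); co <- seq.int(1L, d[2], 2L)
  (x[ro, co, , , drop = FALSE] + x[ro + 1L, co, , , drop = FALSE] +
     x[ro, co + 1L, , , drop = FALSE] + x[ro + 1L, co + 1L, , , drop = FALSE]) / 4
}

meanpool2_bwd <- function(dy, H, W) {
  d <- dim(dy)
  dx <- array(0, c(H, W, d[3], d[4]))
  q <- dy / 4
  ro <- seq.int(1L, H, 2L); co <- seq.int(1L, W, 2L)
  dx[ro, co, , ] <- q
  dx[ro + 1L, co, , ] <- q
  dx[ro, co + 1L, , ] <- q
  dx[ro + 1L, co + 1L, , ] <- q
  dx
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  ro <- seq.int(1L, d[1], 2L); co <- seq.int(1L, d[2], 2L)
  dy[ro, co, , , drop = FALSE] + dy[ro + 1L, co, , , drop = FALSE] +
    dy[ro, co + 1L, , , drop = FALSE] + dy[ro + 1L, co + 1L, , , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# One conv(-norm)-ReLU block.
block_forward <- function(layer, a, keep_cache) {
  cc <- if (keep_cache) list(input = a) else list()
  z <- conv_fwd(a, layer$w, layer$b)
  if (layer$norm) {
    bn <- bn_forward(z, layer$gamma, layer$beta)
    z <- bn$y
    if (keep_cache) cc$bn <- bn[c("xhat", "istd")]
  }
  act <- relu(z)
  if (keep_cache) cc$act <- act
  list(act = act, cache = cc)
}

block_backward <- function(layer, cc, da) {
  da <- da * (cc$act > 0)
  g <- list()
  if (layer$norm) {
    bb <- bn_backward(da, cc$bn, layer$gamma)
    da <- bb$dx
    g$gamma <- bb$dgamma
    g$beta <- bb$dbeta
  }
  bw <- conv_bwd(cc$input, layer$w, da)
  g$w <- bw$dw; g$b <- bw$db
  list(grads = g, dx = bw$dx)
}

# Forward pass; returns logits and (optionally) the cache needed by the
# backward pass.
unet_forward <- function(net, x, keep_cache = FALSE) {
  D <- net$depth
  dims <- dim(x)
  ps_assert(dims[1] %% 2^D == 0 && dims[2] %% 2^D == 0,
            "paleoseg_geometry_error",
            "input %d x %d is not divisible by 2^depth = %d", dims[1], dims[2], 2^D)
  cache <- list(blocks = list(), skips = list())
  a <- x
  for (d in seq_len(D)) {
    nm <- paste0("enc", d)
    blk <- block_forward(net$layers[[nm]], a, keep_cache)
    a <- blk$act
    cache$blocks[[nm]] <- blk$cache
    cache$skips[[d]] <- a
    a <- meanpool2(a)
  }
  blk <- block_forward(net$layers$bottleneck, a, keep_cache)
  a <- blk$act
  cache$blocks[["bottleneck"]] <- blk$cache
  for (d in seq_len(D)) {
    nm <- paste0("dec", d)
    a <- upsample2(a)
    a <- concat_ch(a, cache$skips[[D - d + 1L]])
    blk <- block_forward(net$layers[[nm]], a, keep_cache)
    a <- blk$act
    cache$blocks[[nm]] <- blk$cache
  }
  if (keep_cache) cache$head_input <- a
  z <- conv_fwd(a, net$layers$head$w, net$layers$head$b)
  if (keep_cache) list(logits = z, cache = cache) else list(logits = z)
}

# Backward pass given d(loss)/d(logits); returns per-layer gradients.
unet_backward <- function(net, cache, dz) {
  D <- net$depth
  grads <- list()
  bw <- conv_bwd(cache$head_input, net$layers$head$w, dz)
  grads$head <- list(w = bw$dw, b = bw$db)
  da <- bw$dx
  skip_grads <- vector("list", D)
  for (d in rev(seq_len(D))) {
    nm <- paste0("dec", d)
    bb <- block_backward(net$layers[[nm]], cache$blocks[[nm]], da)
    grads[[nm]] <- bb$grads
    dcat <- bb$dx
    sk <- D - d + 1L
    n_skip <- dim(cache$skips[[sk]])[3]
    n_up <- dim(dcat)[3] - n_skip
    skip_grads[[sk]] <- dcat[, , n_up + seq_len(n_skip), , drop = FALSE]
    da <- upsample2_bwd(dcat[, , seq_len(n_up), , drop = FALSE])
  }
  bb <- block_backward(net$layers$bottleneck, cache$blocks$bottleneck, da)
  grads$bottleneck <- bb$grads
  da <- bb$dx
  for (d in rev(seq_len(D))) {
    nm <- paste0("enc", d)
    hw <- dim(cache$skips[[d]])[1:2]
    da <- meanpool2_bwd(da, hw[1], hw[2]) + skip_grads[[d]]
    bb <- block_backward(net$layers[[nm]], cache$blocks[[nm]], da)
    grads[[nm]] <- bb$grads
    da <- bb$dx
  }
  grads
}

# --- AdamW -------------------------------------------------------------

layer_param_names <- function(layer) {
  if (isTRUE(layer$norm)) c("w", "b", "gamma", "beta") else c("w", "b")
}

adamw_init <- function(net) {
  state <- list(t = 0L, m = list(), v = list())
  for (nm in names(net$layers)) {
    layer <- net$layers[[nm]]
    z <- lapply(layer_param_names(layer), function(p) {
      d <- dim(layer[[p]])
      if (is.null(d)) numeric(length(layer[[p]])) else array(0, d)
    })
    names(z) <- layer_param_names(layer)
    state$m[[nm]] <- z
    state$v[[nm]] <- z
  }
  state
}

# Decoupled-weight-decay Adam update. `lr_by_group` maps parameter group
# ("encoder"/"decoder") to the learning rate for this step; weight decay is
# applied multiplicatively with the group learning rate and skips biases.
adamw_step <- function(net, grads, state, lr_by_group, weight_decay,
                       betas = c(0.9, 0.999), eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(net$layers)) {
    lr <- lr_by_group[[net$layers[[nm]]$group]]
    for (p in layer_param_names(net$layers[[nm]])) {
      g <- grads[[nm]][[p]]
      state$m[[nm]][[p]] <- b1 * state$m[[nm]][[p]] + (1 - b1) * g
      state$v[[nm]][[p]] <- b2 * state$v[[nm]][[p]] + (1 - b2) * g^2
      mhat <- state$m[[nm]][[p]] / bc1
      vhat <- state$v[[nm]][[p]] / bc2
      upd <- mhat / (sqrt(vhat) + eps)
      if (p == "w" && weight_decay > 0) {
        upd <- upd + weight_decay * net$layers[[nm]][[p]]
      }
      net$layers[[nm]][[p]] <- net$layers[[nm]][[p]] - lr * upd
    }
  }
  list(net = net, state = state)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable mean binary cross-entropy computed from logits.
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}
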