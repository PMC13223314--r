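# Minimal 1-D neural-network engine -------------------------------------------
#
# Tensors are dense base-R arrays, batch-first: signals are N x T x C, flat
# features N x F. Convolutions use an im2col/col2im formulation so the inner
# products run through BLAS. Padding follows a "same"-style rule for strided
# layers: a convolution with kernel k and stride s (k >= s, T divisible by s)
# pads k - s samples in total and maps T -> T/s; the transposed convolution
# with the same (k, s) is its exact adjoint and maps T' -> T' * s, which is
# what makes a mirrored encoder/decoder restore the input shape exactly.

conv_geometry <- function(T_in, k, s) {
  if (k < s) stop(sprintf("kernel (%d) must be >= stride (%d)", k, s), call. = FALSE)
  if (T_in %% s != 0) {
    stop(sprintf("temporal length %d is not divisible by stride %d", T_in, s), call. = FALSE)
  }
  pad <- k - s
  list(T_out = T_in %/% s, pad_l = pad %/% 2L, pad_r = pad - pad %/% 2L)
}

conv1d_fwd <- function(x, w, b, s) {
  d <- dim(x)
  k <- dim(w)[1L]
  geo <- conv_geometry(d[2L], k, s)
  xcol <- cpp_conv_gather(x, d[1L], d[2L], d[3L], k, s, geo$T_out, geo$pad_l)
  wmat <- w; dim(wmat) <- c(k * dim(w)[2L], dim(w)[3L])
  y <- xcol %*% wmat
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(d[1L], geo$T_out, dim(w)[3L])
  list(y = y, cache = list(xcol = xcol, dims = d, geo = geo, k = k, s = s))
}

conv1d_bwd <- function(dy, w, cache) {
  d <- cache$dims; geo <- cache$geo
  c_out <- dim(w)[3L]; c_in <- dim(w)[2L]; k <- cache$k
  dym <- dy; dim(dym) <- c(d[1L] * geo$T_out, c_out)
  wmat <- w; dim(wmat) <- c(k * c_in, c_out)
  db <- colSums(dym)
  dw <- crossprod(cache$xcol, dym); dim(dw) <- dim(w)
  dx <- cpp_conv_scatter(dym %*% t(wmat), d[1L], d[2L], c_in, k, cache$s,
                         geo$T_out, geo$pad_l)
  list(dx = dx, dw = dw, db = db)
}

# transposed convolution: exact adjoint of conv1d under the same (k, s)
# geometry; weights are k x C_out x C_in.
tconv1d_fwd <- function(z, w, b, s) {
  d <- dim(z) # N x T' x C_in
  k <- dim(w)[1L]; c_out <- dim(w)[2L]; c_in <- dim(w)[3L]
  T_full <- d[2L] * s
  geo <- conv_geometry(T_full, k, s)
  zm <- z; dim(zm) <- c(d[1L] * d[2L], c_in)
  wmat <- w; dim(wmat) <- c(k * c_out, c_in)
  y <- cpp_conv_scatter(zm %*% t(wmat), d[1L], T_full, c_out, k, s, d[2L], geo$pad_l)
  y <- y + rep(b, each = d[1L] * T_full)
  list(y = y, cache = list(zm = zm, dims = d, geo = geo, k = k, s = s,
                           c_out = c_out, c_in = c_in, T_full = T_full))
}

tconv1d_bwd <- function(dy, w, cache) {
  d <- cache$dims
  k <- cache$k; s <- cache$s; geo <- cache$geo
  wmat <- w; dim(wmat) <- c(k * cache$c_out, cache$c_in)
  db <- as.numeric(colSums(dy, dims = 2L))
  dycol <- cpp_conv_gather(dy, d[1L], cache$T_full, cache$c_out, k, s, d[2L], geo$pad_l)
  dz <- dycol %*% wmat
  dim(dz) <- d
  dw <- crossprod(dycol, cache$zm); dim(dw) <- dim(w)
  list(dx = dz, dw = dw, db = db)
}

lrelu_fwd <- function(x, alpha) {
  slope <- 1 + (alpha - 1) * (x < 0)
  list(y = x * slope, cache = list(slope = slope))
}

lrelu_bwd <- function(dy, cache) {
  dy * cache$slope
}

# Latent feature standardization layer ("featnorm"): each latent filter is
# z-scored with statistics fitted on the training-set latents (pooled over
# samples and time, like the input scaler) and then passed through a learned
# per-filter affine. The statistics are frozen buffers, never updated by any
# optimizer step, so normalization addresses inter-trial and inter-subject
# variance without erasing the within-window activation envelope that
# distinguishes movements.
featnorm_fwd <- function(x, g, b, mu, sigma) {
  d <- dim(x) # N x T x D
  xm <- x; dim(xm) <- c(d[1L] * d[2L], d[3L])
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(1 / sigma, each = nrow(xm))
  y <- xhat * rep(g, each = nrow(xm)) + rep(b, each = nrow(xm))
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, sigma = sigma, g = g, dims = d))
}

featnorm_bwd <- function(dy, cache) {
  d <- cache$dims
  dym <- dy; dim(dym) <- c(d[1L] * d[2L], d[3L])
  dg <- colSums(dym * cache$xhat)
  db <- colSums(dym)
  dx <- dym * rep(cache$g / cache$sigma, each = nrow(dym))
  dim(dx) <- d
  list(dx = dx, dg = dg, db = db)
}

# additive (tanh) self-attention pooling over the time axis:
# e_t = v' tanh(W h_t + b), a = softmax(e), context = sum_t a_t h_t
attnpool_fwd <- function(h, w, b, v) {
  d <- dim(h) # N x T x D
  hm <- h; dim(hm) <- c(d[1L] * d[2L], d[3L])
  u <- hm %*% w
  u <- tanh(u + rep(b, each = nrow(u)))
  e <- as.numeric(u %*% v)
  dim(e) <- d[1:2]
  e <- e - apply(e, 1L, max)
  a <- exp(e)
  a <- a / rowSums(a)
  ha <- h * as.numeric(a) # recycles a over the feature axis
  ctx <- colSums(aperm(ha, c(2L, 1L, 3L))) # N x D
  list(y = ctx, cache = list(hm = hm, u = u, a = a, dims = d),
       weights = a)
}

attnpool_bwd <- function(dctx, w, b, v, cache) {
  d <- cache$dims
  a <- cache$a
  # expand dctx (N x D) along time
  dctx_t <- aperm(array(dctx, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  dh1 <- dctx_t * as.numeric(a)
  hsd <- array(cache$hm, dim = d) * dctx_t
  dim(hsd) <- c(d[1L] * d[2L], d[3L])
  s <- rowSums(hsd); dim(s) <- d[1:2] # da
  de <- a * (s - rowSums(a * s))
  de_v <- as.numeric(de)
  dv <- as.numeric(crossprod(cache$u, de_v))
  dpre <- (de_v %o% v) * (1 - cache$u^2)
  dw <- crossprod(cache$hm, dpre)
  db <- colSums(dpre)
  dh2 <- dpre %*% t(w)
  dim(dh2) <- d
  list(dx = dh1 + dh2, dw = dw, db = db, dv = dv)
}

dense_fwd <- function(x, w, b) {
  y <- x %*% w
  y <- y + rep(b, each = nrow(y))
  list(y = y, cache = list(x = x))
}

dense_bwd <- function(dy, w, cache) {
  list(dx = dy %*% t(w), dw = crossprod(cache$x, dy), db = colSums(dy))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# single-layer LSTM over N x T x C, emitting the final hidden state N x H
lstm_fwd <- function(x, wx, wh, b) {
  d <- dim(x)
  hsz <- nrow(wh)
  n <- d[1L]
  h <- matrix(0, n, hsz); cs <- matrix(0, n, hsz)
  steps <- vector("list", d[2L])
  for (t in seq_len(d[2L])) {
    xt <- x[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, nrow = n)
    z <- xt %*% wx + h %*% wh
    z <- z + rep(b, each = n)
    i <- sigmoid(z[, 1:hsz, drop = FALSE])
    f <- sigmoid(z[, (hsz + 1):(2 * hsz), drop = FALSE])
    g <- tanh(z[, (2 * hsz + 1):(3 * hsz), drop = FALSE])
    o <- sigmoid(z[, (3 * hsz + 1):(4 * hsz), drop = FALSE])
    c_prev <- cs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, tc = tc)
    h <- o * tc
  }
  list(y = h, cache = list(steps = steps, dims = d, hsz = hsz))
}

lstm_bwd <- function(dh_last, wx, wh, cache) {
  d <- cache$dims; hsz <- cache$hsz
  dwx <- matrix(0, nrow(wx), ncol(wx))
  dwh <- matrix(0, nrow(wh), ncol(wh))
  db <- numeric(4 * hsz)
  dx <- array(0, dim = d)
  dh <- dh_last
  dc <- matrix(0, d[1L], hsz)
  for (t in rev(seq_len(d[2L]))) {
    st <- cache$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    df <- dc * st$c_prev
    di <- dc * st$g
    dg <- dc * st$i
    dc <- dc * st$f
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dwx <- dwx + crossprod(st$xt, dz)
    dwh <- dwh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(wx)
    dh <- dz %*% t(wh)
  }
  list(dx = dx, dwx = dwx, dwh = dwh, db = db)
}

# Layer graph ------------------------------------------------------------------

nn_layer <- function(name, type, ...) {
  structure(c(list(name = name, type = type), list(...)), class = "nn_layer")
}

he_normal <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

# He-Normal initialization of every parameter under a single seed; parameter
# names are "<layer>_<slot>".
nn_init <- function(layers, seed) {
  with_seed(seed, {
    params <- list()
    for (ly in layers) {
      p <- switch(ly$type,
        conv = list(
          W = he_normal(c(ly$k, ly$in_ch, ly$out_ch), ly$k * ly$in_ch),
          b = numeric(ly$out_ch)
        ),
        tconv = list(
          W = he_normal(c(ly$k, ly$out_ch, ly$in_ch), ly$k * ly$in_ch),
          b = numeric(ly$out_ch)
        ),
        dense = list(
          W = he_normal(c(ly$n_in, ly$n_out), ly$n_in),
          b = numeric(ly$n_out)
        ),
        featnorm = list(g = rep(1, ly$dim), b = numeric(ly$dim),
                        mu = numeric(ly$dim), sigma = rep(1, ly$dim)),
        attnpool = list(
          W = he_normal(c(ly$dim, ly$attn_dim), ly$dim),
          b = numeric(ly$attn_dim),
          v = he_normal(ly$attn_dim, ly$attn_dim)
        ),
        lstm = list(
          Wx = he_normal(c(ly$n_in, 4 * ly$hidden), ly$n_in),
          Wh = he_normal(c(ly$hidden, 4 * ly$hidden), ly$hidden),
          b = { b0 <- numeric(4 * ly$hidden); b0[(ly$hidden + 1):(2 * ly$hidden)] <- 1; b0 }
        ),
        NULL # lrelu / flatten carry no parameters
      )
      if (!is.null(p)) {
        names(p) <- paste0(ly$name, "_", names(p))
        params <- c(params, p)
      }
    }
    params
  })
}

nn_forward <- function(layers, params, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  extras <- list()
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    nm <- ly$name
    r <- switch(ly$type,
      conv = conv1d_fwd(x, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]], ly$stride),
      tconv = tconv1d_fwd(x, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]], ly$stride),
      lrelu = lrelu_fwd(x, ly$alpha),
      featnorm = featnorm_fwd(x, params[[paste0(nm, "_g")]], params[[paste0(nm, "_b")]],
                              params[[paste0(nm, "_mu")]], params[[paste0(nm, "_sigma")]]),
      attnpool = attnpool_fwd(x, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]],
                              params[[paste0(nm, "_v")]]),
      dense = dense_fwd(x, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]]),
      lstm = lstm_fwd(x, params[[paste0(nm, "_Wx")]], params[[paste0(nm, "_Wh")]],
                      params[[paste0(nm, "_b")]]),
      flatten = {
        d <- dim(x)
        y <- x; dim(y) <- c(d[1L], prod(d[-1L]))
        list(y = y, cache = list(dims = d))
      },
      stop("unknown layer type: ", ly$type)
    )
    x <- r$y
    if (keep_cache) caches[[li]] <- r$cache
    if (!is.null(r$weights)) extras[[nm]] <- r$weights
  }
  list(out = x, caches = caches, extras = extras)
}

nn_backward <- function(layers, params, caches, dout) {
  grads <- list()
  dy <- dout
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    nm <- ly$name
    cache <- caches[[li]]
    if (ly$type == "conv") {
      r <- conv1d_bwd(dy, params[[paste0(nm, "_W")]], cache)
      grads[[paste0(nm, "_W")]] <- r$dw; grads[[paste0(nm, "_b")]] <- r$db
      dy <- r$dx
    } else if (ly$type == "tconv") {
      r <- tconv1d_bwd(dy, params[[paste0(nm, "_W")]], cache)
      grads[[paste0(nm, "_W")]] <- r$dw; grads[[paste0(nm, "_b")]] <- r$db
      dy <- r$dx
    } else if (ly$type == "lrelu") {
      dy <- lrelu_bwd(dy, cache)
    } else if (ly$type == "featnorm") {
      r <- featnorm_bwd(dy, cache)
      grads[[paste0(nm, "_g")]] <- r$dg; grads[[paste0(nm, "_b")]] <- r$db
      dy <- r$dx
    } else if (ly$type == "attnpool") {
      r <- attnpool_bwd(dy, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]],
                        params[[paste0(nm, "_v")]], cache)
      grads[[paste0(nm, "_W")]] <- r$dw; grads[[paste0(nm, "_b")]] <- r$db
      grads[[paste0(nm, "_v")]] <- r$dv
      dy <- r$dx
    } else if (ly$type == "dense") {
      r <- dense_bwd(dy, params[[paste0(nm, "_W")]], cache)
      grads[[paste0(nm, "_W")]] <- r$dw; grads[[paste0(nm, "_b")]] <- r$db
      dy <- r$dx
    } else if (ly$type == "lstm") {
      r <- lstm_bwd(dy, params[[paste0(nm, "_Wx")]], params[[paste0(nm, "_Wh")]], cache)
      grads[[paste0(nm, "_Wx")]] <- r$dwx; grads[[paste0(nm, "_Wh")]] <- r$dwh
      grads[[paste0(nm, "_b")]] <- r$db
      dy <- r$dx
    } else if (ly$type == "flatten") {
      dim(dy) <- cache$dims
    }
  }
  list(grads = grads, dx = dy)
}

# analytic parameter / cost accounting used by model_cost_report()
layer_param_count <- function(ly) {
  switch(ly$type,
    conv = ly$k * ly$in_ch * ly$out_ch + ly$out_ch,
    tconv = ly$k * ly$in_ch * ly$out_ch + ly$out_ch,
    dense = ly$n_in * ly$n_out + ly$n_out,
    featnorm = 4 * ly$dim,
    attnpool = ly$dim * ly$attn_dim + 2 * ly$attn_dim,
    lstm = 4 * ly$hidden * (ly$n_in + ly$hidden + 1),
    0
  )
}
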