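# Internal neural-network engine for the pair comparator.
#
# Activations are numeric arrays of dim (H*W, C, B): H = EEG channels of a
# 31 x 37 signal image, W = time bins, C = feature maps, B = batch.  The
# heavy convolutions run through the compiled im2col kernel; batch-norm,
# activations, dense layers, dropout, softmax and Adam are plain (vectorized)
# R.  Batch-norm uses batch statistics in training and exponential running
# averages at evaluation (momentum 0.9, epsilon 1e-3; the lower momentum keeps
# evaluation statistics usable after the short training runs the package's
# desk-scale benchmarks use).

bn_eps <- 1e-3
bn_momentum <- 0.9

bn_forward <- function(x, gamma, beta, running, training) {
  out <- .bn_fwd(x, gamma, beta, running$mean, running$var, training,
                 bn_eps, want_xhat = training)
  out$running <- if (training) {
    list(mean = bn_momentum * running$mean + (1 - bn_momentum) * out$mean,
         var = bn_momentum * running$var + (1 - bn_momentum) * out$var)
  } else {
    running
  }
  out
}

bn_backward <- function(dy, xhat, inv, gamma) {
  .bn_bwd(dy, xhat, inv, gamma)
}

lrelu <- function(x, slope) .lrelu_fwd(x, slope)
lrelu_grad_mul <- function(dy, x, slope) .lrelu_bwd(dy, x, slope)

cat_channels <- function(a, b) .cat_channels(a, b)

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# ---- parameter construction -------------------------------------------------

init_params <- function(spec) {
  nb <- length(spec$filters)
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  kk <- kh * kw
  p <- list()
  r <- list()
  c_in <- spec$input_maps
  p$bn0_gamma <- rep(1, c_in)
  p$bn0_beta <- rep(0, c_in)
  r$bn0 <- list(mean = rep(0, c_in), var = rep(1, c_in))
  c_prev <- c_in
  for (i in seq_len(nb)) {
    f <- spec$filters[i]
    p[[paste0("conv_w_", i)]] <- glorot(c_prev * kk, f,
                                        c_prev * kk, f * kk)
    p[[paste0("conv_b_", i)]] <- rep(0, f)
    c_cat <- c_prev + f
    p[[paste0("bn_gamma_", i)]] <- rep(1, c_cat)
    p[[paste0("bn_beta_", i)]] <- rep(0, c_cat)
    r[[paste0("bn", i)]] <- list(mean = rep(0, c_cat), var = rep(1, c_cat))
    c_prev <- c_cat
  }
  p$red_w <- glorot(c_prev * kk, spec$reduction_filters,
                    c_prev * kk, spec$reduction_filters * kk)
  p$red_b <- rep(0, spec$reduction_filters)
  widths <- c(prod(spec$spatial_shape) * spec$reduction_filters,
              spec$dense_widths, spec$output_units)
  for (i in seq_len(length(widths) - 1L)) {
    p[[paste0("fc_w_", i)]] <- glorot(widths[i + 1L], widths[i],
                                      widths[i], widths[i + 1L])
    p[[paste0("fc_b_", i)]] <- rep(0, widths[i + 1L])
  }
  list(params = p, running = r)
}

# ---- forward / backward -----------------------------------------------------

# x: (HW, input_maps, B).  Returns list(probs, cache); cache is NULL unless
# training (backward needs the intermediate activations).
nn_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  p <- model$params
  nb <- length(spec$filters)
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  H <- spec$spatial_shape[1]; W <- spec$spatial_shape[2]
  B <- dim(x)[3]
  cache <- if (training) list(x = x, blocks = vector("list", nb)) else NULL

  bn0 <- bn_forward(x, p$bn0_gamma, p$bn0_beta, model$running$bn0, training)
  if (training) {
    model$running$bn0 <- bn0$running
    cache$bn0 <- bn0[c("xhat", "inv")]
  }
  h <- bn0$y
  for (i in seq_len(nb)) {
    z <- .conv2d_fwd(h, H, W, p[[paste0("conv_w_", i)]],
                     p[[paste0("conv_b_", i)]], kh, kw)
    a <- lrelu(z, spec$leaky_slope)
    cc <- cat_channels(a, h)
    bn <- bn_forward(cc, p[[paste0("bn_gamma_", i)]],
                     p[[paste0("bn_beta_", i)]],
                     model$running[[paste0("bn", i)]], training)
    if (training) {
      model$running[[paste0("bn", i)]] <- bn$running
      cache$blocks[[i]] <- list(h_in = h, z = z,
                                xhat = bn$xhat, inv = bn$inv)
    }
    h <- bn$y
  }
  zr <- .conv2d_fwd(h, H, W, p$red_w, p$red_b, kh, kw)
  ar <- lrelu(zr, spec$leaky_slope)
  flat <- ar
  dim(flat) <- c(H * W * spec$reduction_filters, B)
  if (training) {
    cache$h_last <- h
    cache$zr <- zr
  }

  n_fc <- length(spec$dense_widths) + 1L
  keep <- 1 - spec$dropout
  hfc <- flat
  if (training) {
    cache$fc <- vector("list", n_fc)
  }
  for (i in seq_len(n_fc)) {
    z <- p[[paste0("fc_w_", i)]] %*% hfc + p[[paste0("fc_b_", i)]]
    if (i < n_fc) {
      a <- lrelu(z, spec$leaky_slope)
      if (training && spec$dropout > 0) {
        mask <- matrix(runif(length(a)) < keep, nrow(a), ncol(a)) / keep
        out <- a * mask
      } else {
        mask <- NULL
        out <- a
      }
      if (training) cache$fc[[i]] <- list(input = hfc, z = z, mask = mask)
      hfc <- out
    } else {
      if (training) cache$fc[[i]] <- list(input = hfc)
      probs <- softmax_cols(z)
    }
  }
  list(probs = probs, cache = cache)
}

# labels: integer vector in 1..output_units; returns list(grads, loss, acc)
nn_backward <- function(model, probs, cache, labels) {
  spec <- model$spec
  p <- model$params
  nb <- length(spec$filters)
  kh <- spec$kernel[1]; kw <- spec$kernel[2]
  H <- spec$spatial_shape[1]; W <- spec$spatial_shape[2]
  B <- ncol(probs)
  g <- list()

  dz <- probs
  dz[cbind(labels, seq_len(B))] <- dz[cbind(labels, seq_len(B))] - 1
  dz <- dz / B
  n_fc <- length(spec$dense_widths) + 1L
  for (i in rev(seq_len(n_fc))) {
    fc <- cache$fc[[i]]
    g[[paste0("fc_w_", i)]] <- dz %*% t(fc$input)
    g[[paste0("fc_b_", i)]] <- rowSums(dz)
    dh <- t(p[[paste0("fc_w_", i)]]) %*% dz
    if (i > 1L) {
      prev <- cache$fc[[i - 1L]]
      if (!is.null(prev$mask)) dh <- dh * prev$mask
      dz <- lrelu_grad_mul(dh, prev$z, spec$leaky_slope)
    } else {
      dflat <- dh
    }
  }

  dar <- dflat
  dim(dar) <- c(H * W, spec$reduction_filters, B)
  dzr <- lrelu_grad_mul(dar, cache$zr, spec$leaky_slope)
  cb <- .conv2d_bwd(cache$h_last, dzr, p$red_w, H, W, kh, kw)
  g$red_w <- cb$dw
  g$red_b <- cb$db
  dh <- cb$dx

  for (i in rev(seq_len(nb))) {
    blk <- cache$blocks[[i]]
    bnb <- bn_backward(dh, blk$xhat, blk$inv, p[[paste0("bn_gamma_", i)]])
    g[[paste0("bn_gamma_", i)]] <- bnb$dgamma
    g[[paste0("bn_beta_", i)]] <- bnb$dbeta
    f <- spec$filters[i]
    sp <- .split_channels(bnb$dx, f)
    dz <- lrelu_grad_mul(sp$first, blk$z, spec$leaky_slope)
    dh_skip <- sp$rest
    cb <- .conv2d_bwd(blk$h_in, dz, p[[paste0("conv_w_", i)]], H, W, kh, kw)
    g[[paste0("conv_w_", i)]] <- cb$dw
    g[[paste0("conv_b_", i)]] <- cb$db
    dh <- cb$dx + dh_skip
  }

  bnb <- bn_backward(dh, cache$bn0$xhat, cache$bn0$inv, p$bn0_gamma)
  g$bn0_gamma <- bnb$dgamma
  g$bn0_beta <- bnb$dbeta

  loss <- -mean(log(pmax(probs[cbind(labels, seq_len(B))], 1e-12)))
  acc <- mean(apply(probs, 2, which.max) == labels)
  list(grads = g, loss = loss, acc = acc)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- model$adam
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (k in names(model$params)) {
    gk <- grads[[k]]
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * gk
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * gk^2
    model$params[[k]] <- model$params[[k]] -
      lr * (st$m[[k]] / c1) / (sqrt(st$v[[k]] / c2) + eps)
  }
  model$adam <- st
  invisible(model)
}
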