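# Internal CNN machinery: batch-norm bookkeeping, forward/backward over
# conv blocks, softmax head, Adam. Tensors are R arrays (H, W, C, N); the
# heavy per-pixel work lives in src/convnet.cpp.

bn_fwd <- function(z, gamma, beta, rmean, rvar, train, eps = 1e-5,
                   momentum = 0.9) {
  d <- dim(z)
  m <- d[1] * d[2] * d[4]
  if (train) {
    st <- nn_bn_stats(z)
    mu <- st$sum / m
    va <- st$sumsq / m - mu^2
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * va
  } else {
    mu <- rmean
    va <- rvar
  }
  invstd <- 1 / sqrt(va + eps)
  scale <- gamma * invstd
  y <- nn_scale_shift(z, scale, beta - scale * mu)
  list(y = y, mu = mu, invstd = invstd, rmean = rmean, rvar = rvar)
}

softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# full forward pass; x: array (H, W, 1, N)
cnn_forward <- function(model, x, train = FALSE, cache = FALSE,
                        dropout = TRUE, bn_momentum = 0.9) {
  cfg <- model$config
  p <- model$params
  L <- cfg$n_conv
  caches <- if (cache) vector("list", L) else NULL
  A_last <- NULL
  for (l in seq_len(L)) {
    xin <- x
    z <- nn_conv_fwd(x, p$conv_w[[l]], p$conv_b[[l]])
    bn <- bn_fwd(z, p$gamma[[l]], p$beta[[l]], model$bn_mean[[l]],
                 model$bn_var[[l]], train = train, momentum = bn_momentum)
    if (train) {
      model$bn_mean[[l]] <- bn$rmean
      model$bn_var[[l]] <- bn$rvar
    }
    a_pre <- bn$y
    x <- nn_relu(a_pre)
    pool <- NULL
    if (l %in% cfg$pool_after) {
      prepool_dim <- dim(x)
      pl <- nn_pool_fwd(x)
      x <- pl$y
      pool <- list(idx = pl$idx, xdim = prepool_dim)
    }
    if (l == L) A_last <- a_pre
    if (cache)
      caches[[l]] <- list(xin = xin, z = z, mu = bn$mu, invstd = bn$invstd,
                          a_pre = a_pre, pool = pool)
  }
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  feat <- matrix(.colMeans(matrix(x, nrow = HW), HW, C * N), C, N)
  drop_mask <- NULL
  if (train && dropout && cfg$dropout > 0) {
    drop_mask <- matrix((runif(C * N) >= cfg$dropout) / (1 - cfg$dropout),
                        C, N)
    feat_d <- feat * drop_mask
  } else feat_d <- feat
  logits <- p$fc_w %*% feat_d + matrix(p$fc_b, cfg$n_classes, N)
  probs <- softmax_cols(logits)
  list(logits = logits, probs = probs, feat = feat, feat_d = feat_d,
       drop_mask = drop_mask, A_last = A_last, last_dim = d,
       caches = caches, model = model)
}

# backward pass from dlogits; returns grads in the same structure as params
cnn_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  L <- cfg$n_conv
  g <- list(conv_w = vector("list", L), conv_b = vector("list", L),
            gamma = vector("list", L), beta = vector("list", L))
  g$fc_w <- dlogits %*% t(fwd$feat_d)
  g$fc_b <- rowSums(dlogits)
  dfeat <- t(p$fc_w) %*% dlogits
  if (!is.null(fwd$drop_mask)) dfeat <- dfeat * fwd$drop_mask
  d <- fwd$last_dim
  HW <- d[1] * d[2]
  dx <- array(rep(as.numeric(dfeat), each = HW) / HW, dim = d)
  for (l in rev(seq_len(L))) {
    cc <- fwd$caches[[l]]
    if (!is.null(cc$pool))
      dx <- nn_pool_bwd(dx, cc$pool$idx, cc$pool$xdim)
    dx <- nn_relu_bwd(dx, cc$a_pre)
    bb <- nn_bn_bwd(dx, cc$z, cc$mu, cc$invstd, p$gamma[[l]])
    g$gamma[[l]] <- bb$dgamma
    g$beta[[l]] <- bb$dbeta
    cv <- nn_conv_bwd(cc$xin, p$conv_w[[l]], bb$dx)
    g$conv_w[[l]] <- cv$dw
    g$conv_b[[l]] <- cv$db
    dx <- cv$dx
  }
  g
}

flatten_grads <- function(g) {
  c(g$conv_w, g$conv_b, g$gamma, g$beta, list(g$fc_w, g$fc_b))
}

flatten_params <- function(p) {
  c(p$conv_w, p$conv_b, p$gamma, p$beta, list(p$fc_w, p$fc_b))
}

unflatten_params <- function(flat, L) {
  list(conv_w = flat[seq_len(L)],
       conv_b = flat[L + seq_len(L)],
       gamma = flat[2 * L + seq_len(L)],
       beta = flat[3 * L + seq_len(L)],
       fc_w = flat[[4 * L + 1]], fc_b = flat[[4 * L + 2]])
}

adam_init <- function(p) {
  flat <- flatten_params(p)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0)
}

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fp <- flatten_params(p)
  fg <- flatten_grads(g)
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(fp)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * fg[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * fg[[i]]^2
    fp[[i]] <- fp[[i]] - lr * (state$m[[i]] / bc1) /
      (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = unflatten_params(fp, length(p$conv_w)), state = state)
}

# Recompute the batch-norm inference statistics with frozen weights by
# averaging batch statistics over passes through the (un-augmented)
# training images. The training-time exponential moving average lags the
# parameters, which distorts inference-mode activations in deep stacks;
# recalibration makes the running statistics consistent with the final
# weights.
bn_recalibrate <- function(model, images, batch_size = 64) {
  L <- model$config$n_conv
  model$bn_mean <- lapply(model$config$channels, function(c0) numeric(c0))
  model$bn_var <- lapply(model$config$channels, function(c0) numeric(c0))
  n <- length(images)
  t <- 0
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, n)
    t <- t + 1
    fwd <- cnn_forward(model, as_image_array(images[ids]), train = TRUE,
                       dropout = FALSE, bn_momentum = (t - 1) / t)
    model <- fwd$model
  }
  model
}

# head-only forward: pre-ReLU last-conv activations A (Hl, Wl, C) -> score
# of class `class_idx` (logit or softmax probability), dropout off.
# This is the function the channel gradients differentiate.
head_forward <- function(model, A, class_idx, score = c("logit", "prob")) {
  score <- match.arg(score)
  p <- model$params
  x <- pmax(A, 0)
  feat <- apply(x, 3, mean)
  logits <- as.numeric(p$fc_w %*% feat + p$fc_b)
  if (score == "logit") return(logits[class_idx])
  z <- exp(logits - max(logits))
  (z / sum(z))[class_idx]
}
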