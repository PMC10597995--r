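#' CNN architecture configuration
#'
#' Configurable stack of convolutional blocks, each `conv -> batch norm ->
#' ReLU`, with 2x2 max pooling after the layers listed in `pool_after`,
#' followed by global average pooling, a dropout layer and a fully
#' connected softmax head over two classes. The default is a seven-layer
#' design at desk-scale width.
#'
#' @param n_conv_layers number of convolutional blocks.
#' @param channels integer vector of output channels, one per block.
#' @param kernel_size odd kernel side (same padding).
#' @param pool_after indices of blocks followed by 2x2 max pooling.
#' @param input_size input image side in pixels.
#' @param dropout_rate drop probability of the dropout layer (on the
#'   pooled features).
#' @param n_classes number of output classes.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_conv_layers = 7,
                         channels = c(8, 8, 16, 16, 32, 32, 32),
                         kernel_size = 3, pool_after = c(1, 2, 3),
                         input_size = 128, dropout_rate = 0.5,
                         n_classes = 2) {
  stopifnot(n_conv_layers >= 1, dropout_rate >= 0, dropout_rate < 1,
            kernel_size %% 2 == 1, n_classes >= 2)
  if (length(channels) != n_conv_layers)
    stop("channels must have one entry per convolutional layer (",
         n_conv_layers, ")", call. = FALSE)
  stopifnot(all(pool_after %in% seq_len(n_conv_layers)))
  sz <- input_size / 2^length(pool_after)
  if (sz != round(sz) || sz < 1)
    stop("input_size not divisible by the pooling stages", call. = FALSE)
  structure(list(n_conv = n_conv_layers, channels = as.integer(channels),
                 kernel = as.integer(kernel_size),
                 pool_after = as.integer(pool_after),
                 input_size = as.integer(input_size),
                 dropout = dropout_rate, n_classes = as.integer(n_classes)),
            class = "model_config")
}

#' Training configuration
#'
#' Adam with a step-decayed learning rate: `lr0 * lr_decay^(epoch %/%
#' decay_every)`. Defaults are the desk-scale protocol (30 epochs, batch
#' 32); the clinical-scale protocol (1000 epochs, batch 100) is available
#' by configuration.
#'
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay factor, in (0, 1].
#' @param decay_every epochs between decay steps.
#' @param epochs number of training epochs (>= 0; 0 leaves the model
#'   untouched).
#' @param batch_size minibatch size.
#' @param augment logical; apply seeded augmentation during training.
#' @param seed master seed; shuffling, dropout and augmentation streams
#'   are derived from it.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-3, lr_decay = 0.95, decay_every = 100,
                         epochs = 30, batch_size = 32, augment = TRUE,
                         seed = 1) {
  stopifnot(lr0 > 0, lr_decay > 0, lr_decay <= 1, decay_every >= 1,
            epochs >= 0, batch_size >= 1)
  structure(list(lr0 = lr0, lr_decay = lr_decay, decay_every = decay_every,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr = lr0 * lr_decay^floor(epoch / decay_every)` (epoch counted from 0).
#'
#' @param epoch epoch index (0-based), vectorized.
#' @param config a [train_config()].
#' @return learning rate(s).
#' @examples
#' lr_schedule(200, train_config())  # 1e-3 * 0.95^2
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  stopifnot(all(epoch >= 0))
  config$lr0 * config$lr_decay^(epoch %/% config$decay_every)
}

#' Build (initialize) the CNN
#'
#' He-initialized weights, unit batch-norm scales. The returned model
#' exposes the last convolutional layer's activations through the forward
#' pass used by the saliency module, and reports its total parameter
#' count.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @param classes character vector of class labels (length `n_classes`);
#'   the second level is the "positive" (Class II) class.
#' @return an object of class `ceph_cnn`.
#' @export
build_model <- function(config = model_config(), seed = 1,
                        classes = c("classI", "classII")) {
  stopifnot(inherits(config, "model_config"),
            length(classes) == config$n_classes)
  k <- config$kernel
  chans <- c(1L, config$channels)
  params <- with_seed(seed, {
    p <- list(conv_w = vector("list", config$n_conv),
              conv_b = vector("list", config$n_conv),
              gamma = vector("list", config$n_conv),
              beta = vector("list", config$n_conv))
    for (l in seq_len(config$n_conv)) {
      fan_in <- k * k * chans[l]
      p$conv_w[[l]] <- array(rnorm(k * k * chans[l] * chans[l + 1],
                                   0, sqrt(2 / fan_in)),
                             dim = c(k, k, chans[l], chans[l + 1]))
      p$conv_b[[l]] <- numeric(chans[l + 1])
      p$gamma[[l]] <- rep(1, chans[l + 1])
      p$beta[[l]] <- numeric(chans[l + 1])
    }
    cl <- config$channels[config$n_conv]
    p$fc_w <- matrix(rnorm(config$n_classes * cl, 0, sqrt(2 / cl)),
                     config$n_classes, cl)
    p$fc_b <- numeric(config$n_classes)
    p
  })
  model <- structure(list(config = config, params = params,
                          bn_mean = lapply(config$channels, function(c0)
                            numeric(c0)),
                          bn_var = lapply(config$channels, function(c0)
                            rep(1, c0)),
                          classes = classes, trained = FALSE,
                          log = NULL),
                     class = "ceph_cnn")
  model$n_params <- count_params(config)
  model
}

#' Total trainable parameter count of a configuration
#'
#' Sums kernel weights and biases, batch-norm scale/shift pairs and the
#' fully connected head.
#'
#' @param config a [model_config()].
#' @return integer parameter count.
#' @export
count_params <- function(config) {
  k <- config$kernel
  chans <- c(1L, config$channels)
  n <- 0
  for (l in seq_len(config$n_conv))
    n <- n + k * k * chans[l] * chans[l + 1] + chans[l + 1] +  # conv w + b
      2 * chans[l + 1]                                          # BN gamma/beta
  n + config$channels[config$n_conv] * config$n_classes + config$n_classes
}

#' @export
print.ceph_cnn <- function(x, ...) {
  cat("ceph_cnn:", x$config$n_conv, "conv blocks (",
      paste(x$config$channels, collapse = "-"), "channels ),",
      x$n_params, "parameters;",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation splits
#'
#' Per class, each fold's test set holds exactly `floor(n_class / k)`
#' samples; remainder samples are always assigned to training. Test sets
#' are pairwise disjoint.
#'
#' @param labels vector/factor of class labels.
#' @param k number of folds.
#' @param seed integer seed for the per-class shuffles.
#' @return list of `k` lists with elements `fold`, `train`, `test`
#'   (integer indices into `labels`).
#' @export
make_cv_splits <- function(labels, k = 5, seed = 1) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("each class needs at least k = ", k, " samples", call. = FALSE)
  assign_fold <- with_seed(seed, {
    out <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      per <- length(idx) %/% k
      f <- rep(NA_integer_, length(idx))
      f[seq_len(per * k)] <- rep(seq_len(k), each = per)
      out[idx] <- f  # NA = remainder, always trains
    }
    out
  })
  lapply(seq_len(k), function(f)
    list(fold = f,
         train = which(is.na(assign_fold) | assign_fold != f),
         test = which(!is.na(assign_fold) & assign_fold == f)))
}

as_image_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  }
  stopifnot(is.list(images), length(images) >= 1)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  array(unlist(images, use.names = FALSE), dim = c(h, w, 1, length(images)))
}

#' Train the CNN
#'
#' Minibatch Adam with the step-decayed learning rate, cross-entropy loss,
#' batch normalization in training mode, dropout on the pooled features
#' and (optionally) seeded augmentation applied to each training image at
#' every epoch. Fully deterministic given `config$seed`.
#'
#' @param model an untrained (or previously trained) `ceph_cnn`.
#' @param images list of preprocessed square matrices (side
#'   `model$config$input_size`).
#' @param labels factor/character vector with the model's two classes;
#'   both classes must be present.
#' @param config a [train_config()].
#' @param augment_config a [preproc_config()] used for train-time
#'   augmentation (its `target_size` must match the model input size).
#' @param verbose print per-epoch progress.
#' @return the trained model; the per-epoch log (epoch, lr, loss, acc) is
#'   in `model$log`.
#' @export
train_classifier <- function(model, images, labels,
                             config = train_config(),
                             augment_config = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ceph_cnn"), inherits(config, "train_config"))
  labels <- factor(as.character(labels), levels = model$classes)
  if (any(is.na(labels)))
    stop("labels outside model classes", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("training set must contain both classes", call. = FALSE)
  if (config$epochs == 0) {
    model$log <- data.frame(epoch = integer(0), lr = numeric(0),
                            loss = numeric(0), acc = numeric(0))
    return(model)
  }
  if (is.null(augment_config))
    augment_config <- preproc_config(target_size = model$config$input_size)
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  n <- length(images)
  stopifnot(length(labels) == n)
  y <- as.integer(labels)
  state <- adam_init(model$params)
  log <- vector("list", config$epochs)
  with_seed(derive_seed(config$seed, 1), {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_schedule(epoch - 1, config)
      perm <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        ids <- perm[start:min(start + config$batch_size - 1, n)]
        batch <- lapply(ids, function(i) {
          if (config$augment)
            img_augment(images[[i]], augment_config, seed = NULL)
          else images[[i]]
        })
        xb <- as_image_array(batch)
        fwd <- cnn_forward(model, xb, train = TRUE, cache = TRUE)
        model <- fwd$model  # updated BN running stats
        nb <- length(ids)
        pick <- cbind(y[ids], seq_len(nb))
        tot_loss <- tot_loss - sum(log(pmax(fwd$probs[pick], 1e-12)))
        tot_correct <- tot_correct + sum(apply(fwd$probs, 2, which.max) ==
                                           y[ids])
        onehot <- matrix(0, model$config$n_classes, nb)
        onehot[pick] <- 1
        dlogits <- (fwd$probs - onehot) / nb
        grads <- cnn_backward(model, fwd, dlogits)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
      }
      log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                 loss = tot_loss / n, acc = tot_correct / n)
      if (verbose)
        message(sprintf("epoch %3d lr %.2e loss %.4f acc %.3f",
                        epoch, lr, tot_loss / n, tot_correct / n))
    }
  })
  # make inference-mode batch-norm statistics consistent with the final
  # weights (the training EMA lags the parameters)
  model <- bn_recalibrate(model, images)
  model$trained <- TRUE
  model$log <- do.call(rbind, log)
  model
}

#' Evaluate the CNN on a labeled or unlabeled image set
#'
#' Runs the model in inference mode (running batch-norm statistics, no
#' dropout) and returns per-image predictions with the softmax score of
#' the predicted class (the prediction score retained for saliency), plus
#' the accuracy when labels are given.
#'
#' @param model a `ceph_cnn`.
#' @param images list of preprocessed matrices.
#' @param labels optional true labels.
#' @param batch_size forward-pass batch size.
#' @return list with `predictions` (data frame: index, predicted, score,
#'   and the per-class probabilities) and `accuracy` (or `NA`).
#' @export
evaluate_classifier <- function(model, images, labels = NULL,
                                batch_size = 64) {
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  n <- length(images)
  probs <- matrix(NA_real_, model$config$n_classes, n)
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, n)
    xb <- as_image_array(images[ids])
    probs[, ids] <- cnn_forward(model, xb, train = FALSE)$probs
  }
  pred_idx <- apply(probs, 2, which.max)
  preds <- data.frame(index = seq_len(n),
                      predicted = model$classes[pred_idx],
                      score = probs[cbind(pred_idx, seq_len(n))],
                      stringsAsFactors = FALSE)
  for (j in seq_along(model$classes))
    preds[[paste0("p_", model$classes[j])]] <- probs[j, ]
  acc <- NA_real_
  if (!is.null(labels))
    acc <- mean(preds$predicted == as.character(labels))
  list(predictions = preds, accuracy = acc)
}
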