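#' Last-convolutional-layer activations
#'
#' Runs the model in inference mode on one image and returns the
#' activations of the last convolutional block (after batch norm, before
#' the ReLU), the tensor the class-activation equations operate on.
#'
#' @param model a trained `ceph_cnn`.
#' @param image preprocessed square matrix of side
#'   `model$config$input_size`.
#' @return array (Hl, Wl, C) of activations, with the class probabilities
#'   in `attr(, "probs")`.
#' @export
last_conv_activations <- function(model, image) {
  check_model_image(model, image)
  fwd <- cnn_forward(model, as_image_array(list(image)), train = FALSE)
  A <- fwd$A_last
  out <- array(A, dim = dim(A)[1:3])
  attr(out, "probs") <- as.numeric(fwd$probs)
  out
}

check_model_image <- function(model, image) {
  if (!inherits(model, "ceph_cnn")) stop("not a ceph_cnn model", call. = FALSE)
  if (!model$trained)
    stop("model is untrained; train it before computing saliency",
         call. = FALSE)
  if (nrow(image) != model$config$input_size ||
      ncol(image) != model$config$input_size)
    stop("image shape does not match the model input size", call. = FALSE)
  invisible(TRUE)
}

#' Channel gradients of the prediction score
#'
#' Gradients of the target-class prediction score with respect to the
#' last-convolutional-layer activations, computed by backpropagation
#' through the ReLU, global-average-pooling and fully connected head. The
#' score is the pre-softmax logit by default (the CAM-literature
#' convention) or the softmax probability.
#'
#' @param model a trained `ceph_cnn`.
#' @param image preprocessed matrix.
#' @param target_class class label or index; default = predicted class.
#' @param score `"logit"` or `"prob"`.
#' @return array of gradients, same shape as the activations; attributes
#'   `activations`, `target_class`, `Sc` carry the matched activations,
#'   the resolved class index and the score value.
#' @export
channel_gradients <- function(model, image, target_class = NULL,
                              score = c("logit", "prob")) {
  score <- match.arg(score)
  check_model_image(model, image)
  fwd <- cnn_forward(model, as_image_array(list(image)), train = FALSE)
  A <- array(fwd$A_last, dim = dim(fwd$A_last)[1:3])
  cls <- resolve_class(model, target_class, fwd$probs[, 1])
  d <- dim(A)
  HW <- d[1] * d[2]
  if (score == "logit") {
    dfeat <- model$params$fc_w[cls, ]
    Sc <- fwd$logits[cls, 1]
  } else {
    p <- fwd$probs[, 1]
    dlog <- -p[cls] * p
    dlog[cls] <- dlog[cls] + p[cls]
    dfeat <- as.numeric(t(model$params$fc_w) %*% dlog)
    Sc <- p[cls]
  }
  G <- array(rep(dfeat, each = HW) / HW, dim = d) * (A > 0)
  attr(G, "activations") <- A
  attr(G, "target_class") <- cls
  attr(G, "Sc") <- Sc
  G
}

resolve_class <- function(model, target_class, probs) {
  if (is.null(target_class)) return(which.max(probs))
  if (is.character(target_class)) {
    cls <- match(target_class, model$classes)
    if (is.na(cls)) stop("unknown class: ", target_class, call. = FALSE)
    return(cls)
  }
  as.integer(target_class)
}

#' Gradient-weighted activations
#'
#' Elementwise `Mi = Gi * ReLU(Ai)`: channel gradients times the rectified
#' activations.
#'
#' @param Gi gradient array from [channel_gradients()].
#' @param Ai activation array of the same shape.
#' @return array `Mi` of the same shape.
#' @export
weighted_activations <- function(Gi, Ai) {
  if (!identical(dim(Gi), dim(Ai)) && !identical(length(Gi), length(Ai)))
    stop("shape mismatch between gradients and activations", call. = FALSE)
  Gi * pmax(Ai, 0)
}

#' Combine weighted activations into a saliency map
#'
#' Per channel, the weight `alpha_i` is the spatial mean of `Mi`
#' (global average pooling); the raw map is the weighted sum
#' `S = sum_i alpha_i * Mi`, rectified, bilinearly upsampled to the input
#' resolution and min-max normalized to \[0, 1\] (an all-zero map stays
#' zero).
#'
#' @param Mi array (Hl, Wl, C) of weighted activations (C >= 1).
#' @param out_size optional output side length; `NULL` keeps the
#'   activation resolution.
#' @return saliency matrix in \[0, 1\].
#' @export
combine_channels <- function(Mi, out_size = NULL) {
  d <- dim(Mi)
  if (is.null(d) || length(d) != 3 || d[3] < 1)
    stop("Mi must be a (H, W, C) array with at least one channel",
         call. = FALSE)
  alpha <- .colMeans(matrix(Mi, nrow = d[1] * d[2]), d[1] * d[2], d[3])
  S <- matrix(matrix(Mi, ncol = d[3]) %*% alpha, d[1], d[2])
  S <- pmax(S, 0)
  if (!is.null(out_size) && out_size != d[1])
    S <- matrix(as.numeric(EBImage::resize(S, out_size, out_size)),
                out_size, out_size)
  minmax(pmax(S, 0))
}

#' Per-image saliency map
#'
#' Default method `"grad-cam"` follows the gradient-weighted equations:
#' `Gi = dSc/dAi`, `Mi = Gi * ReLU(Ai)`, `alpha = GlobalAvgPool(Mi)`,
#' `S = sum(alpha * Mi)`, then rectification, bilinear upsampling to input
#' resolution and per-map min-max normalization. `"score-cam"` delegates
#' to the gradient-free [scorecam_map()].
#'
#' @inheritParams channel_gradients
#' @param method `"grad-cam"` (gradient-weighted) or `"score-cam"`.
#' @return object of class `saliency_map`: the \[0, 1\] map matrix with
#'   attributes `target_class` and `method`.
#' @export
saliency_map <- function(model, image, target_class = NULL,
                         method = c("grad-cam", "score-cam"),
                         score = c("logit", "prob")) {
  method <- match.arg(method)
  if (method == "score-cam")
    return(scorecam_map(model, image, target_class))
  Gi <- channel_gradients(model, image, target_class, score)
  Mi <- weighted_activations(Gi, attr(Gi, "activations"))
  S <- combine_channels(Mi, out_size = nrow(image))
  structure(S, class = c("saliency_map", class(S)),
            target_class = attr(Gi, "target_class"), method = method)
}

#' Gradient-free Score-CAM saliency map
#'
#' Canonical Score-CAM: each last-layer channel's rectified activation
#' map, upsampled and normalized to \[0, 1\], masks the input image; the
#' channel weights are the softmax (over channels) of the target-class
#' logit increases of the masked inputs over a zero baseline; the map is
#' the rectified, normalized weighted sum of the upsampled activation
#' masks.
#'
#' @inheritParams channel_gradients
#' @return object of class `saliency_map`.
#' @export
scorecam_map <- function(model, image, target_class = NULL) {
  check_model_image(model, image)
  n <- nrow(image)
  fwd <- cnn_forward(model, as_image_array(list(image)), train = FALSE)
  cls <- resolve_class(model, target_class, fwd$probs[, 1])
  A <- array(fwd$A_last, dim = dim(fwd$A_last)[1:3])
  act <- pmax(A, 0)
  C <- dim(act)[3]
  ups <- lapply(seq_len(C), function(cc) {
    u <- matrix(as.numeric(EBImage::resize(act[, , cc], n, n)), n, n)
    if (max(u) > 0) u / max(u) else u
  })
  live <- vapply(ups, function(u) max(u) > 0, logical(1))
  if (!any(live)) {
    S <- matrix(0, n, n)
    return(structure(S, class = c("saliency_map", class(S)),
                     target_class = cls, method = "score-cam"))
  }
  masked <- lapply(which(live), function(cc) image * ups[[cc]])
  base_logit <- cnn_forward(model,
                            as_image_array(list(image * 0)),
                            train = FALSE)$logits[cls, 1]
  logits <- cnn_forward(model, as_image_array(masked),
                        train = FALSE)$logits[cls, ]
  w <- exp(logits - base_logit - max(logits - base_logit))
  w <- w / sum(w)
  S <- Reduce(`+`, Map(function(u, wi) u * wi, ups[live], w))
  S <- minmax(pmax(S, 0))
  structure(S, class = c("saliency_map", class(S)), target_class = cls,
            method = "score-cam")
}

#' Saliency maps for every positive (Class II) image of a cohort
#'
#' Classifies all images and emits one saliency map per image whose
#' predicted class (default) or true label is the positive class
#' (the second model class, Class II retrognathia).
#'
#' @param model a trained `ceph_cnn`.
#' @param images named list of preprocessed matrices.
#' @param method saliency method, see [saliency_map()].
#' @param restrict `"predicted"` (images predicted positive) or
#'   `"label"` (images whose `labels` entry is the positive class).
#' @param labels true labels, required for `restrict = "label"`.
#' @return named list of `saliency_map` objects (possibly empty, with a
#'   warning); the evaluation table is in `attr(, "predictions")`.
#' @export
explain_cohort <- function(model, images, method = "grad-cam",
                           restrict = c("predicted", "label"),
                           labels = NULL) {
  restrict <- match.arg(restrict)
  ids <- names(images) %||% as.character(seq_along(images))
  ev <- evaluate_classifier(model, images)
  pos <- model$classes[2]
  keep <- if (restrict == "predicted") {
    ev$predictions$predicted == pos
  } else {
    if (is.null(labels)) stop("labels required for restrict = 'label'",
                              call. = FALSE)
    as.character(labels) == pos
  }
  if (!any(keep)) {
    warning("no positive images; no saliency maps generated")
    out <- list()
  } else {
    out <- lapply(which(keep), function(i)
      saliency_map(model, images[[i]], target_class = pos, method = method))
    names(out) <- ids[keep]
  }
  attr(out, "predictions") <- cbind(id = ids, ev$predictions)
  out
}
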