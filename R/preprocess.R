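#' Preprocessing / augmentation configuration
#'
#' Bundles the deterministic standardization settings (target size, Sobel
#' filtering) and the seeded augmentation magnitudes used at training time.
#' Rotation angles are drawn from integer multiples of `rotation_step`
#' within `±rotation_max`, translations uniformly within
#' `±shift_fraction * size`, and zoom uniformly within `1 ± zoom_range`.
#'
#' @param target_size output image side in pixels.
#' @param apply_sobel logical; replace the image by its Sobel gradient
#'   magnitude after normalization.
#' @param rotation_step rotation grid step in degrees.
#' @param rotation_max maximum absolute rotation in degrees; must be a
#'   multiple of `rotation_step`.
#' @param shift_fraction maximum translation as a fraction of image size.
#' @param zoom_range maximum relative zoom (0.03 = 3%).
#' @param seed optional integer seed for augmentation draws.
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(target_size = 256, apply_sobel = TRUE,
                           rotation_step = 10, rotation_max = 30,
                           shift_fraction = 0.03, zoom_range = 0.03,
                           seed = NULL) {
  stopifnot(target_size > 0, zoom_range >= 0, zoom_range < 1,
            rotation_step >= 0, rotation_max >= 0, shift_fraction >= 0)
  if (rotation_max > 0) {
    if (rotation_step <= 0 || abs(rotation_max / rotation_step -
                                  round(rotation_max / rotation_step)) > 1e-9)
      stop("rotation_step must divide rotation_max", call. = FALSE)
  }
  structure(list(target_size = as.integer(target_size),
                 apply_sobel = isTRUE(apply_sobel),
                 rotation_step = rotation_step, rotation_max = rotation_max,
                 shift_fraction = shift_fraction, zoom_range = zoom_range,
                 seed = seed),
            class = "preproc_config")
}

#' Resize a grayscale image
#'
#' Bilinear resize to a square `target_size` (anti-aliased on downscale).
#' An image already at the target size is returned unchanged.
#'
#' @param image numeric matrix.
#' @param target_size output side length in pixels.
#' @return numeric matrix `target_size x target_size`.
#' @export
img_resize <- function(image, target_size) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  image <- as.matrix(image)
  if (nrow(image) == target_size && ncol(image) == target_size) return(image)
  anti <- target_size < max(dim(image))
  out <- EBImage::resize(image, w = target_size, h = target_size,
                         antialias = anti)
  matrix(as.numeric(out), target_size, target_size)
}

#' Min-max normalize intensities to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant image maps to all zeros.
#'
#' @param image numeric matrix with finite entries.
#' @return numeric matrix in \[0, 1\].
#' @export
img_normalize <- function(image) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  if (any(!is.finite(image))) stop("non-finite intensities", call. = FALSE)
  minmax(image)
}

sobel_kernel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)

#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernels (replicate boundary), combines
#' them as `sqrt(Gx^2 + Gy^2)` and renormalizes the result to \[0, 1\].
#'
#' @param image numeric matrix (typically already normalized).
#' @return numeric matrix in \[0, 1\].
#' @export
img_sobel <- function(image) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  image <- as.matrix(image)
  gx <- EBImage::filter2(image, sobel_kernel_x, boundary = "replicate")
  gy <- EBImage::filter2(image, t(sobel_kernel_x), boundary = "replicate")
  minmax(matrix(sqrt(as.numeric(gx)^2 + as.numeric(gy)^2),
                nrow(image), ncol(image)))
}

#' Random rigid + zoom augmentation of a square image
#'
#' Draws a rotation angle from multiples of `rotation_step` within
#' `±rotation_max`, a zoom factor within `1 ± zoom_range` and a translation
#' within `±shift_fraction * size`, and applies them in a single bilinear
#' warp. The rotation/zoom pivot is the image center at pixel
#' `(size/2, size/2)`; pixels mapped from outside the frame are filled
#' with 0. With all magnitudes zero the output equals the input exactly.
#'
#' @param image square numeric matrix of side `config$target_size`.
#' @param config a [preproc_config()].
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream (used inside the training loop).
#' @return augmented matrix; drawn parameters in `attr(, "params")`.
#' @export
img_augment <- function(image, config, seed = NULL) {
  image <- as.matrix(image)
  n <- nrow(image)
  if (n != ncol(image) || n != config$target_size)
    stop("image must be square of side config$target_size", call. = FALSE)
  pars <- with_seed(seed %||% config$seed, {
    angle <- if (config$rotation_max > 0) {
      sample(seq(-config$rotation_max, config$rotation_max,
                 by = config$rotation_step), 1)
    } else 0
    zoom <- if (config$zoom_range > 0)
      1 + runif(1, -config$zoom_range, config$zoom_range) else 1
    shift <- if (config$shift_fraction > 0)
      runif(2, -config$shift_fraction, config$shift_fraction) * n else c(0, 0)
    list(angle = angle, zoom = zoom, dx = shift[1], dy = shift[2])
  })
  out <- apply_rigid(image, angle = pars$angle, zoom = pars$zoom,
                     dx = pars$dx, dy = pars$dy, fill = 0)
  attr(out, "params") <- pars
  out
}

# forward transform: p_out = zoom * R(angle) %*% (p - c) + c + t, applied by
# inverse-mapping each output pixel; exact identity when all magnitudes are 0
apply_rigid <- function(image, angle = 0, zoom = 1, dx = 0, dy = 0, fill = 0) {
  if (angle == 0 && zoom == 1 && dx == 0 && dy == 0) return(image)
  n <- nrow(image)
  cx <- n / 2; cy <- n / 2
  th <- -angle * pi / 180  # inverse rotation
  s <- 1 / zoom
  m <- c(s * cos(th), -s * sin(th),
         cx - s * (cos(th) * (cx + dx) - sin(th) * (cy + dy)),
         s * sin(th), s * cos(th),
         cy - s * (sin(th) * (cx + dx) + cos(th) * (cy + dy)))
  warp_bilinear(image, m, fill)
}

# the same rigid transform applied to (x, y) point coordinates
transform_points <- function(xy, n, angle = 0, zoom = 1, dx = 0, dy = 0) {
  th <- angle * pi / 180
  ctr <- c(n / 2, n / 2)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t(apply(xy, 1, function(p) zoom * R %*% (p - ctr) + ctr + c(dx, dy)))
}

#' Standardize one image for the classifier
#'
#' Pipeline order: resize to `target_size`, min-max normalize to \[0, 1\],
#' then (optionally) Sobel gradient magnitude. Augmentation is a separate,
#' train-time-only step ([img_augment()]).
#'
#' @param image numeric matrix.
#' @param config a [preproc_config()].
#' @return preprocessed matrix.
#' @export
preprocess_image <- function(image, config = preproc_config()) {
  out <- img_normalize(img_resize(image, config$target_size))
  if (config$apply_sobel) out <- img_sobel(out)
  out
}
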