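#' Read a grayscale image (PNG or TIFF)
#' @param path file path; RGB inputs are averaged to grayscale.
#' @return numeric matrix in \[0, 1\].
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
    png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                          c(1, 2), mean)
  img
}

#' Write a saliency/activation map as 32-bit float TIFF
#' @param map numeric matrix in \[0, 1\].
#' @param path output path.
#' @export
write_map_tiff <- function(map, path) {
  tiff::writeTIFF(as_map_matrix(map), path, bits.per.sample = 32)
  invisible(path)
}

#' Save a heat-map overlay PNG
#'
#' Blends a jet-style colormap of the activation map over the grayscale
#' backdrop, with opacity proportional to activation.
#'
#' @param map activation matrix in \[0, 1\] (or `global_map`).
#' @param backdrop grayscale matrix; `NULL` uses a black background.
#' @param path output PNG path.
#' @param alpha maximum overlay opacity.
#' @export
save_overlay_png <- function(map, backdrop, path, alpha = 0.7) {
  map <- as_map_matrix(map)
  if (is.null(backdrop)) backdrop <- map * 0
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(clamp01(as.numeric(map))) / 255
  a <- clamp01(as.numeric(map)) * alpha
  g <- clamp01(as.numeric(backdrop))
  rgb <- array(0, dim = c(nrow(map), ncol(map), 3))
  for (k in 1:3)
    rgb[, , k] <- matrix((1 - a) * g + a * cols[, k], nrow(map))
  png::writePNG(rgb, path)
  invisible(path)
}
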