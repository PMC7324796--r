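#' Load an RGB raster image
#'
#' Reads PNG, JPEG or TIFF into an `H x W x 3` double array of reflectance
#' values in `[0, 1]`. Integer formats are rescaled by their dtype maximum
#' (8-bit by 255, 16-bit by 65535). Grayscale files are replicated to three
#' channels with a warning; an alpha channel is dropped.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return `H x W x 3` array in `[0, 1]` with attribute `source_path`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = , jpeg = jpeg::readJPEG(path),
           tif = , tiff = tiff::readTIFF(path),
           abort(sprintf("unsupported raster format '.%s': %s", ext, path))),
    error = function(e) abort(sprintf("cannot read image %s: %s",
                                      path, conditionMessage(e))))
  if (is.matrix(px)) {
    warn(sprintf("grayscale image replicated to 3 channels: %s", path))
    px <- array(rep(px, 3L), c(dim(px), 3L))
  }
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3L)
    abort(sprintf("expected 1, 3 or 4 channels, got %d: %s", dim(px)[3], path))
  px <- clamp01(px)
  attr(px, "source_path") <- path
  px
}

#' Write an image or mask to PNG
#'
#' Masks are written as 0/255 grayscale PNG; RGB arrays as colour PNG.
#'
#' @param img RGB array, grayscale matrix, or binary mask.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (inherits(img, "binary_mask") || is.logical(img)) {
    png::writePNG(matrix(as.numeric(img), nrow(img), ncol(img)), path)
  } else {
    png::writePNG(clamp01(unclass(img)), path)
  }
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Weighted luminance `0.2989 R + 0.5870 G + 0.1140 B`, the convention of the
#' classic ITU-R BT.601 luma transform.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
to_grayscale <- function(img) {
  check_rgb(img)
  d <- dim(img)
  matrix(0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3],
         d[1], d[2])
}

check_rgb <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort("expected an H x W x 3 RGB array")
  invisible(img)
}

#' Colour-index plant segmentation (CIS)
#'
#' Segments plant from background pixels with the excess-green colour index
#' `PP = 2g - r - b`, binarised at strictly positive values. Achromatic
#' pixels (`r = g = b`, index exactly 0) fall to background.
#'
#' @param img `H x W x 3` RGB array.
#' @return Full-scale [binary_mask] that is `TRUE` on plant pixels.
#' @export
color_index_segment <- function(img) {
  check_rgb(img)
  d <- dim(img)
  pp <- matrix(2 * img[, , 2] - img[, , 1] - img[, , 3], d[1], d[2])
  binary_mask(pp > 0, "full")
}

#' CIE L* lightness channel
#'
#' Interprets the image as sRGB (D65) and returns the L* channel of CIELAB,
#' rescaled from `[0, 100]` to `[0, 1]`. This is the input to the vesselness
#' filter.
#'
#' @param img `H x W x 3` RGB array.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
lab_lightness <- function(img) {
  check_rgb(img)
  d <- dim(img)
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  matrix(clamp01(lab[, 1] / 100), d[1], d[2])
}

#' Single-level 2-D Haar wavelet decomposition
#'
#' Decomposes a grayscale image into the four sub-bands A (approximation,
#' low-low), H (horizontal detail), V (vertical detail) and D (diagonal
#' detail) with orthonormal Haar filters, so that for even-sized inputs the
#' pixel energy is conserved: `||I||^2 = ||A||^2 + ||H||^2 + ||V||^2 +
#' ||D||^2`. Odd dimensions are handled by symmetric (edge-replicating)
#' extension of the last row/column; each sub-band then has `ceiling(H/2) x
#' ceiling(W/2)` pixels. The half-resolution A image carries the texture
#' information used downstream.
#'
#' @param img `H x W` matrix, both dimensions at least 2.
#' @return Object of class `haar_dwt`: list with matrices `A`, `H`, `V`, `D`,
#'   plus `wavelet = "haar"`, `level = 1` and the original dimensions.
#' @seealso [idwt_haar()] for the inverse transform.
#' @export
dwt_haar <- function(img) {
  if (!is.matrix(img)) abort("expected a grayscale matrix")
  h <- nrow(img); w <- ncol(img)
  if (h < 2 || w < 2) abort("image must be at least 2x2 for a Haar level")
  m <- img
  if (h %% 2 == 1) m <- rbind(m, m[h, , drop = FALSE])
  if (w %% 2 == 1) m <- cbind(m, m[, w, drop = FALSE])
  ro <- seq(1, nrow(m), by = 2); co <- seq(1, ncol(m), by = 2)
  a <- m[ro, co, drop = FALSE];     b <- m[ro + 1, co, drop = FALSE]
  cc <- m[ro, co + 1, drop = FALSE]; d <- m[ro + 1, co + 1, drop = FALSE]
  structure(list(
    A = (a + b + cc + d) / 2,
    H = (a - b + cc - d) / 2,   # high-pass across rows
    V = (a + b - cc - d) / 2,   # high-pass across columns
    D = (a - b - cc + d) / 2,
    wavelet = "haar", level = 1L, orig_dim = c(h, w)
  ), class = "haar_dwt")
}

#' @export
print.haar_dwt <- function(x, ...) {
  cat(sprintf("<haar_dwt level %d: sub-bands %dx%d from %dx%d image>\n",
              x$level, nrow(x$A), ncol(x$A), x$orig_dim[1], x$orig_dim[2]))
  invisible(x)
}

#' Inverse single-level Haar transform
#'
#' Reconstructs the image from its four sub-bands; exact (to floating point)
#' for even-sized originals.
#'
#' @param dec A `haar_dwt` object.
#' @return `H x W` matrix with the original dimensions.
#' @export
idwt_haar <- function(dec) {
  if (!inherits(dec, "haar_dwt")) abort("expected a haar_dwt object")
  A <- dec$A; H <- dec$H; V <- dec$V; D <- dec$D
  h2 <- nrow(A); w2 <- ncol(A)
  out <- matrix(0, 2 * h2, 2 * w2)
  ro <- seq(1, 2 * h2, by = 2); co <- seq(1, 2 * w2, by = 2)
  out[ro, co]         <- (A + H + V + D) / 2
  out[ro + 1, co]     <- (A - H + V - D) / 2
  out[ro, co + 1]     <- (A + H - V - D) / 2
  out[ro + 1, co + 1] <- (A - H - V + D) / 2
  out[seq_len(dec$orig_dim[1]), seq_len(dec$orig_dim[2]), drop = FALSE]
}

#' Downscale a full-resolution mask to the wavelet grid
#'
#' 2x2 block OR-pooling: a half-scale pixel is plant if any pixel of its
#' source block is. Output dimensions match the A sub-band
#' (`ceiling(H/2) x ceiling(W/2)`).
#'
#' @param mask Full-scale [binary_mask].
#' @return Half-scale [binary_mask].
#' @export
downscale_mask <- function(mask) {
  if (mask_scale(mask) != "full") abort("expected a full-scale mask")
  m <- as_logical_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  if (h %% 2 == 1) m <- rbind(m, FALSE)
  if (w %% 2 == 1) m <- cbind(m, FALSE)
  ro <- seq(1, nrow(m), by = 2); co <- seq(1, ncol(m), by = 2)
  binary_mask(m[ro, co] | m[ro + 1, co] | m[ro, co + 1] | m[ro + 1, co + 1],
              "half")
}

#' Upscale a half-resolution mask to the full image grid
#'
#' Nearest-neighbour 2x replication cropped to `target_shape`, which must be
#' within one pixel of twice the mask dimensions.
#'
#' @param mask Half-scale [binary_mask].
#' @param target_shape Integer vector `c(H, W)` of the full image.
#' @return Full-scale [binary_mask].
#' @export
upscale_mask <- function(mask, target_shape) {
  if (mask_scale(mask) != "half") abort("expected a half-scale mask")
  m <- as_logical_matrix(mask)
  h2 <- nrow(m); w2 <- ncol(m)
  th <- target_shape[1]; tw <- target_shape[2]
  if (th > 2 * h2 || th < 2 * h2 - 1 || tw > 2 * w2 || tw < 2 * w2 - 1)
    abort(sprintf("target shape %dx%d incompatible with half mask %dx%d",
                  th, tw, h2, w2))
  big <- m[rep(seq_len(h2), each = 2), rep(seq_len(w2), each = 2)]
  binary_mask(big[seq_len(th), seq_len(tw), drop = FALSE], "full")
}
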