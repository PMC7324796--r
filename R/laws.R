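#' The eight zero-sum 3x3 Laws texture masks
#'
#' Builds the 2-D Laws masks as outer products of the 1-D level, edge and
#' spot vectors `L3 = (1, 2, 1)`, `E3 = (-1, 0, 1)`, `S3 = (-1, 2, -1)`
#' (column vector times row vector). The level-level product `L3L3` is not
#' zero-sum and is excluded, leaving eight masks; every returned kernel sums
#' to zero, so its response is invariant to adding a constant to the image.
#'
#' @return Named list of eight 3x3 integer matrices, in the fixed order
#'   `L3E3, E3L3, L3S3, S3L3, E3S3, S3E3, E3E3, S3S3`.
#' @export
laws_masks <- function() {
  v <- list(L3 = c(1, 2, 1), E3 = c(-1, 0, 1), S3 = c(-1, 2, -1))
  pairs <- list(c("L3", "E3"), c("E3", "L3"), c("L3", "S3"), c("S3", "L3"),
                c("E3", "S3"), c("S3", "E3"), c("E3", "E3"), c("S3", "S3"))
  masks <- lapply(pairs, function(p) outer(v[[p[1]]], v[[p[2]]]))
  names(masks) <- vapply(pairs, paste0, "", collapse = "")
  masks
}

#' Laws texture-energy features on the approximation image
#'
#' Convolves the wavelet approximation image with each of the eight Laws
#' masks and normalises every response image to zero mean and unit standard
#' deviation over a moving `window x window` neighbourhood (default 25), the
#' macro-window step of Laws' texture-energy method:
#' `f' = (f - localmean(f)) / max(localstd(f), eps)`.
#' Borders are handled by symmetric extension; locally flat regions (std
#' below `eps`) yield feature value 0.
#'
#' @param A Grayscale matrix (the `A` sub-band of [dwt_haar()]).
#' @param masks Mask set from [laws_masks()].
#' @param window Odd window side for local normalisation, in A-image pixels.
#' @param eps Floor for the local standard deviation.
#' @return Object of class `feature_stack`: `H' x W' x 8` array with channel
#'   names, plus attribute `window`.
#' @export
laws_features <- function(A, masks = laws_masks(), window = 25L,
                          eps = 1e-6) {
  if (!is.matrix(A)) abort("expected a grayscale matrix")
  if (window %% 2 == 0) abort("`window` must be odd")
  if (min(dim(A)) < window)
    abort(sprintf("image %dx%d smaller than the %d-pixel window",
                  nrow(A), ncol(A), window))
  stack <- array(0, c(nrow(A), ncol(A), length(masks)),
                 dimnames = list(NULL, NULL, names(masks)))
  for (i in seq_along(masks)) {
    f <- conv_same(A, masks[[i]])
    mu <- box_mean(f, window)
    sdv <- box_sd(f, window)
    stack[, , i] <- ifelse(sdv > eps, (f - mu) / pmax(sdv, eps), 0)
  }
  structure(stack, window = as.integer(window), class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack %dx%dx%d, window=%d>\n",
              dim(x)[1], dim(x)[2], dim(x)[3], attr(x, "window")))
  invisible(x)
}

#' Extract per-pixel feature rows at plant pixels
#'
#' Returns one row per `TRUE` pixel of the half-scale plant mask, in raster
#' (column-major) order, with the eight feature values at that pixel.
#' Restricting the classifier to plant pixels is what keeps the per-image
#' workload small.
#'
#' @param stack A `feature_stack`.
#' @param plant_mask_half Half-scale [binary_mask] matching the stack.
#' @return Tibble with columns `row`, `col`, `f1` ... `f8`.
#' @export
extract_pixel_features <- function(stack, plant_mask_half) {
  if (mask_scale(plant_mask_half) != "half")
    abort("expected a half-scale plant mask")
  if (!all(dim(plant_mask_half) == dim(stack)[1:2]))
    stop_shape(plant_mask_half, stack, "mask and feature stack")
  idx <- which(as_logical_matrix(plant_mask_half))
  n <- dim(stack)[1] * dim(stack)[2]
  feats <- matrix(stack, nrow = n)[idx, , drop = FALSE]
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  rc <- arrayInd(idx, dim(stack)[1:2])
  dplyr::bind_cols(tibble(row = rc[, 1], col = rc[, 2]), as_tibble(feats))
}
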