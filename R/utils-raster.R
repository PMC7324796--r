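# Internal raster helpers shared across the pipeline stages.
#
# Images are plain base-R objects throughout: an RGB image is an H x W x 3
# double array with values in [0,1]; a grayscale image is an H x W matrix.
# Binary masks are logical matrices carrying a scale tag ("full" or "half")
# because texture classification happens on the half-resolution wavelet
# approximation image while colour segmentation and vesselness happen at
# full resolution -- mixing the two silently is the main bug risk.

#' Construct a binary mask
#'
#' A binary mask is a logical matrix tagged with the resolution it lives at:
#' `"full"` (original image grid) or `"half"` (the grid of the wavelet
#' approximation image, which has ceiling(H/2) x ceiling(W/2) pixels).
#'
#' @param x Logical (or coercible) matrix.
#' @param scale `"full"` or `"half"`.
#' @return A logical matrix of class `binary_mask` with attribute `scale`.
#' @export
binary_mask <- function(x, scale = c("full", "half")) {
  scale <- match.arg(scale)
  if (!is.matrix(x)) abort("`x` must be a matrix.")
  m <- matrix(as.logical(x), nrow(x), ncol(x))
  if (anyNA(m)) abort("mask contains NA values")
  structure(m, scale = scale, class = c("binary_mask", "matrix", "array"))
}

#' @rdname binary_mask
#' @export
mask_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "full" else s
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, scale=%s, %d true px>\n",
              nrow(x), ncol(x), mask_scale(x), sum(x)))
  invisible(x)
}

as_logical_matrix <- function(x) {
  matrix(as.logical(x), nrow(x), ncol(x))
}

stop_shape <- function(a, b, what = "inputs") {
  abort(sprintf("%s have mismatched shapes: %s vs %s", what,
                paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

# --- seeded evaluation -------------------------------------------------------

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically mix a base seed with stream indices (Lehmer-style),
# keeping the result a valid positive 32-bit integer seed.
derive_seed <- function(seed, ...) {
  s <- as.double(seed %% 2147483647L)
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

# --- padding and convolution -------------------------------------------------

# Symmetric (half-sample, "reflect") padding by pr rows / pc cols on each side.
pad_symmetric <- function(m, pr, pc = pr) {
  h <- nrow(m); w <- ncol(m)
  if (pr >= h || pc >= w) abort("padding exceeds image size")
  ri <- c(rev(seq_len(pr)), seq_len(h), h + 1 - seq_len(pr))
  ci <- c(rev(seq_len(pc)), seq_len(w), w + 1 - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

# Same-size 2-D convolution with symmetric border handling.
# EBImage::filter2 applies the kernel in convolution orientation; padding by
# the kernel half-width keeps the FFT wrap-around out of the returned region.
conv_same <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  if (kr %% 2 == 0 || kc %% 2 == 0) abort("kernel dimensions must be odd")
  pr <- kr %/% 2; pc <- kc %/% 2
  p <- pad_symmetric(m, pr, pc)
  r <- EBImage::filter2(p, k, boundary = "circular")
  r[(pr + 1):(pr + nrow(m)), (pc + 1):(pc + ncol(m)), drop = FALSE]
}

# Exact moving-window mean over a w x w window (w odd), symmetric border,
# computed with a summed-area table.
box_mean <- function(m, w) {
  if (w %% 2 == 0) abort("window size must be odd")
  r <- w %/% 2
  p <- pad_symmetric(m, r, r)
  # summed-area table with a leading zero row/col
  s <- rbind(0, apply(p, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  h <- nrow(m); wd <- ncol(m)
  i2 <- (1 + 2 * r) + seq_len(h) - 1; i1 <- i2 - w + 1
  j2 <- (1 + 2 * r) + seq_len(wd) - 1; j1 <- j2 - w + 1
  (s[i2 + 1, j2 + 1, drop = FALSE] - s[i1, j2 + 1, drop = FALSE] -
     s[i2 + 1, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (w * w)
}

# Moving-window standard deviation (population form), floored at zero.
box_sd <- function(m, w) {
  mu <- box_mean(m, w)
  v <- box_mean(m * m, w) - mu * mu
  sqrt(pmax(v, 0))
}

# --- connected components ----------------------------------------------------

# 8-connected component labelling. EBImage::bwlabel is 4-connected; labels
# that touch diagonally are merged through an igraph component pass.
label_components <- function(mask) {
  m <- as_logical_matrix(mask)
  lab <- EBImage::bwlabel(m * 1)
  nmax <- max(lab)
  if (nmax <= 1) return(matrix(as.integer(lab), nrow(m), ncol(m)))
  h <- nrow(lab); w <- ncol(lab)
  edges <- list(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # (r,c)-(r+1,c+1)
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # (r+1,c)-(r,c+1)
  )
  e <- do.call(rbind, edges)
  e <- e[e[, 1] > 0 & e[, 2] > 0 & e[, 1] != e[, 2], , drop = FALSE]
  if (nrow(e) == 0) return(matrix(as.integer(lab), h, w))
  g <- igraph::graph_from_edgelist(matrix(as.character(e), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(as.character(seq_len(nmax)),
                      igraph::V(g)$name)),
    name = setdiff(as.character(seq_len(nmax)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- integer(nmax)
  remap[as.integer(names(comp))] <- as.integer(comp)
  out <- matrix(0L, h, w)
  out[lab > 0] <- remap[lab[lab > 0]]
  # renumber components consecutively in first-pixel raster order
  u <- unique(out[out > 0])
  ren <- integer(max(u)); ren[u] <- seq_along(u)
  out[out > 0] <- ren[out[out > 0]]
  out
}

# Binary morphology wrappers on logical matrices.
mask_dilate <- function(m, brush) EBImage::dilate(m * 1, brush) > 0.5
mask_erode <- function(m, brush) EBImage::erode(m * 1, brush) > 0.5

disc_brush <- function(radius) {
  if (radius < 1) abort("radius must be >= 1")
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
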