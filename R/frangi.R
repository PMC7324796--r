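# Multi-scale Frangi vessel enhancement on the L* lightness image.
#
# Leaf crossings produce elongated bright ridges whose texture energy mimics
# spikes; the vesselness response locates them so the post-processing stage
# can delete the corresponding candidate-spike components.

# Sampled Gaussian and Gaussian-derivative kernels, truncated at 4*sigma and
# moment-corrected so that convolution of a quadratic reproduces its exact
# derivatives (sum g = 1; sum g1*x = -1 after centring; sum g2*x^2 = 2).
gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g1 <- g1 - mean(g1)
  g1 <- g1 / (-sum(g1 * x))
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - mean(g2)
  g2 <- g2 * (2 / sum(g2 * x^2))
  list(g = g, g1 = g1, g2 = g2)
}

#' Scale-space Hessian of an image
#'
#' Second derivatives of the Gaussian-smoothed image at scale `sigma`
#' (Gaussian-derivative convolutions, truncated at four sigma, symmetric
#' borders), multiplied by the scale-normalisation prefactor
#' `sigma^gamma` (default exponent 1). `x` runs along columns, `y` along
#' rows; the field is symmetric by construction (`h12 = h21`).
#'
#' @param img Grayscale matrix.
#' @param sigma Scale in pixels, at least 0.5.
#' @param gamma Scale-normalisation exponent.
#' @return Object of class `hessian_field`: list `h11` (d2/dx2), `h12`,
#'   `h22` (d2/dy2), `sigma`.
#' @export
hessian_at_scale <- function(img, sigma, gamma = 1) {
  if (!is.matrix(img)) abort("expected a grayscale matrix")
  if (sigma < 0.5) abort("sigma must be >= 0.5")
  k <- gauss_kernels(sigma)
  pre <- sigma^gamma
  # kernel[row, col]: smooth along rows (y) with g, differentiate along
  # columns (x) with g2 for h11, and vice versa; mixed term uses g1 x g1
  # (its sign survives convolution because both factors flip).
  h11 <- pre * conv_same(img, outer(k$g, k$g2))
  h22 <- pre * conv_same(img, outer(k$g2, k$g))
  h12 <- pre * conv_same(img, outer(k$g1, k$g1))
  structure(list(h11 = h11, h12 = h12, h22 = h22, sigma = sigma),
            class = "hessian_field")
}

#' Eigenvalues of a 2x2 symmetric Hessian field
#'
#' Closed-form per-pixel eigenvalues, ordered by magnitude so that
#' `|lambda1| <= |lambda2|` everywhere.
#'
#' @param h A `hessian_field`.
#' @return Object of class `eigen_pair`: list of matrices `lambda1`,
#'   `lambda2`.
#' @export
eigen_decompose <- function(h) {
  if (!inherits(h, "hessian_field")) abort("expected a hessian_field")
  half_tr <- (h$h11 + h$h22) / 2
  disc <- sqrt(((h$h11 - h$h22) / 2)^2 + h$h12^2)
  e1 <- half_tr + disc
  e2 <- half_tr - disc
  swap <- abs(e1) > abs(e2)
  lambda1 <- ifelse(swap, e2, e1)
  lambda2 <- ifelse(swap, e1, e2)
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "eigen_pair")
}

#' Classify local structure from Hessian eigenvalues
#'
#' Maps each pixel's ordered eigenvalue pair to one of the canonical 2-D
#' second-order structure patterns: `noisy` (both magnitudes below the noise
#' floor), `vessel_bright` (`|lambda1|` low, `lambda2` strongly negative),
#' `vessel_dark` (`|lambda1|` low, `lambda2` strongly positive),
#' `blob_bright` (both strongly negative) and `blob_dark` (both strongly
#' positive). "Low" means `|lambda1| < ratio * |lambda2|`.
#'
#' @param e An `eigen_pair`.
#' @param noise_floor Magnitude below which an eigenvalue counts as noise.
#' @param ratio Anisotropy threshold for the vessel patterns.
#' @return Character matrix of pattern labels (pixels matching no pattern
#'   fall back to `"noisy"`).
#' @export
classify_structure <- function(e, noise_floor, ratio = 0.5) {
  if (!inherits(e, "eigen_pair")) abort("expected an eigen_pair")
  l1 <- e$lambda1; l2 <- e$lambda2
  out <- matrix("noisy", nrow(l1), ncol(l1))
  low1 <- abs(l1) < ratio * abs(l2)
  out[low1 & l2 <= -noise_floor] <- "vessel_bright"
  out[low1 & l2 >= noise_floor] <- "vessel_dark"
  out[!low1 & l1 <= -noise_floor & l2 <= -noise_floor] <- "blob_bright"
  out[!low1 & l1 >= noise_floor & l2 >= noise_floor] <- "blob_dark"
  out[abs(l1) < noise_floor & abs(l2) < noise_floor] <- "noisy"
  out
}

#' Single-scale vesselness response
#'
#' Bright-ridge vesselness at one scale:
#' `V = exp(-RB^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' `RB = lambda1/lambda2` and second-order structure strength
#' `S = sqrt(lambda1^2 + lambda2^2)`; the response is forced to zero
#' wherever `lambda2 > 0` (dark ridges) and wherever `lambda2 = 0` (flat,
#' where `S = 0` anyway).
#'
#' @param img Grayscale matrix.
#' @param sigma Scale in pixels.
#' @param beta Blobness sensitivity (canonically 0.5).
#' @param c Structure-strength sensitivity; `NULL` uses half the maximum of
#'   `S` over the image at this scale.
#' @param gamma Scale-normalisation exponent of the Hessian.
#' @return Matrix of responses in `[0, 1]`, with attributes `sigma` and `c`.
#' @export
vesselness_at_scale <- function(img, sigma, beta = 0.5, c = NULL, gamma = 1) {
  if (!is.null(c) && c <= 0) abort("c must be positive")
  if (beta <= 0) abort("beta must be positive")
  e <- eigen_decompose(hessian_at_scale(img, sigma, gamma))
  l1 <- e$lambda1; l2 <- e$lambda2
  s2 <- l1^2 + l2^2
  if (is.null(c)) {
    smax <- sqrt(max(s2))
    c <- if (smax > 0) smax / 2 else 1
  }
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c^2)))
  v[l2 >= 0] <- 0    # zero branch (lambda2 > 0) plus flat pixels (S = 0)
  v <- clamp01(v)
  attr(v, "sigma") <- sigma
  attr(v, "c") <- c
  v
}

#' Multi-scale Frangi vesselness
#'
#' Per-pixel maximum of the single-scale responses over the scale set
#' (default `{1, 3, 5, 7, 9}`); the maximising scale is recorded per pixel.
#'
#' @inheritParams vesselness_at_scale
#' @param sigmas Non-empty vector of scales.
#' @return Object of class `vesselness_map`: list with `response` in
#'   `[0, 1]`, `argmax_sigma`, `sigmas`, `beta`, `c_used` (per scale) and
#'   `gamma`.
#' @export
frangi_multiscale <- function(img, sigmas = c(1, 3, 5, 7, 9), beta = 0.5,
                              c = NULL, gamma = 1) {
  if (length(sigmas) == 0) abort("need at least one scale")
  best <- matrix(0, nrow(img), ncol(img))
  argmax <- matrix(sigmas[1], nrow(img), ncol(img))
  c_used <- numeric(length(sigmas))
  for (i in seq_along(sigmas)) {
    v <- vesselness_at_scale(img, sigmas[i], beta = beta, c = c,
                             gamma = gamma)
    c_used[i] <- attr(v, "c")
    better <- v > best
    argmax[better] <- sigmas[i]
    best[better] <- v[better]
  }
  structure(list(response = best, argmax_sigma = argmax, sigmas = sigmas,
                 beta = beta, c_used = c_used, gamma = gamma),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat(sprintf("<vesselness_map %dx%d, scales {%s}, max %.3f>\n",
              nrow(x$response), ncol(x$response),
              paste(x$sigmas, collapse = ","), max(x$response)))
  invisible(x)
}

#' Threshold a vesselness map into a vessel mask
#'
#' Relative threshold: pixels whose response exceeds `tau_rel` times the
#' image maximum. An all-zero response yields an empty mask.
#'
#' @param map A `vesselness_map`.
#' @param tau_rel Relative threshold in (0, 1).
#' @return Full-scale [binary_mask] of vessel (leaf-edge / crossing) pixels.
#' @export
vessel_mask <- function(map, tau_rel = 0.25) {
  if (!inherits(map, "vesselness_map")) abort("expected a vesselness_map")
  if (tau_rel <= 0 || tau_rel >= 1) abort("tau_rel must be in (0, 1)")
  mx <- max(map$response)
  binary_mask(map$response > tau_rel * mx & mx > 0, "full")
}
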