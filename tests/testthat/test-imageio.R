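test_that("PNG loading rescales 8-bit values to [0,1]", {
  f <- withr::local_tempfile(fileext = ".png")
  px <- array(0, c(2, 2, 3))
  px[1, 1, 2] <- 1          # pure green pixel
  png::writePNG(px, f)
  img <- load_image(f)
  expect_equal(dim(img), c(2L, 2L, 3L))
  expect_equal(as.numeric(img[1, 1, ]), c(0, 1, 0))
  expect_equal(as.numeric(img[2, 2, ]), c(0, 0, 0))
})

test_that("16-bit TIFF values rescale by the dtype maximum and round-trip", {
  f <- withr::local_tempfile(fileext = ".tif")
  px <- array(c(1, 0.5, 0.25), c(1, 1, 3))
  tiff::writeTIFF(px, f, bits.per.sample = 16L)
  img <- load_image(f)
  expect_equal(as.numeric(img[1, 1, ]), c(1, 0.5, 0.25),
               tolerance = 1e-4)
})

test_that("grayscale rasters are replicated to three channels with a warning", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 3, 3), f)
  expect_warning(img <- load_image(f), "grayscale")
  expect_equal(dim(img), c(3L, 3L, 3L))
  expect_equal(img[2, 2, 1], img[2, 2, 3])
})

test_that("alpha channels are dropped and bad paths error", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(2, 2, 4)), f)
  expect_equal(dim(load_image(f))[3], 3L)
  expect_error(load_image("nonexistent.png"), "not found")
})

test_that("grayscale conversion uses the BT.601 luma weights", {
  one <- function(rgb) to_grayscale(array(rgb, c(1, 1, 3)))[1, 1]
  expect_equal(one(c(1, 1, 1)), 0.9999, tolerance = 1e-4)
  expect_equal(one(c(0, 1, 0)), 0.5870)
  expect_equal(one(c(0, 0, 0)), 0)
})

test_that("colour-index segmentation follows 2g - r - b > 0 strictly", {
  img <- array(0, c(1, 3, 3))
  img[1, 1, ] <- c(0.2, 0.5, 0.1)   # 0.7 > 0  -> plant
  img[1, 2, ] <- c(0.4, 0.4, 0.4)   # 0 -> background (strict)
  img[1, 3, ] <- c(0.5, 0.2, 0.1)   # -0.2 -> background
  m <- color_index_segment(img)
  expect_identical(as.logical(m), c(TRUE, FALSE, FALSE))
  expect_equal(mask_scale(m), "full")
})

test_that("colour index is invariant to adding grey and saturates pure hues", {
  sc <- fixture_scene()
  # add the same offset to every channel (no clipping): index unchanged
  img2 <- sc$image * 0.5 + 0.1
  expect_identical(as.logical(color_index_segment(img2 + 0.3)),
                   as.logical(color_index_segment(img2)))
  green <- array(rep(c(0, 1, 0), each = 16), c(4, 4, 3))
  red <- array(rep(c(1, 0, 0), each = 16), c(4, 4, 3))
  expect_true(all(color_index_segment(green)))
  expect_false(any(color_index_segment(red)))
})

test_that("CIS recovers the synthetic plant and rejects the background", {
  sc <- fixture_scene()
  m <- as.logical(color_index_segment(sc$image))
  plant <- as.logical(sc$leaf_mask) | as.logical(sc$spike_mask)
  bg <- !plant & !as.logical(sc$crossing_mask)
  expect_gte(mean(m[plant]), 0.95)
  expect_lte(mean(m[bg]), 0.01)
})

test_that("L* lightness matches the sRGB/D65 closed form", {
  one <- function(rgb) lab_lightness(array(rgb, c(1, 1, 3)))[1, 1]
  expect_equal(one(c(1, 1, 1)), 1)
  expect_equal(one(c(0, 0, 0)), 0)
  expect_equal(one(c(0.5, 0.5, 0.5)), 0.5339, tolerance = 1e-3)
})

test_that("Haar decomposition of a constant image is A = 2c, details zero", {
  d <- dwt_haar(matrix(0.3, 8, 8))
  expect_equal(d$A, matrix(0.6, 4, 4))
  expect_equal(d$H, matrix(0, 4, 4))
  expect_equal(d$V, matrix(0, 4, 4))
  expect_equal(d$D, matrix(0, 4, 4))
})

test_that("2x2 Haar approximation is the half-sum of the four pixels", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)   # a=1 c=3 / b=2 d=4 column-major
  d <- dwt_haar(m)
  expect_equal(dim(d$A), c(1L, 1L))
  expect_equal(d$A[1, 1], sum(m) / 2)
})

test_that("Haar transform conserves energy and matches a brute-force oracle", {
  set.seed(101)
  img <- matrix(runif(64 * 64), 64, 64)
  d <- dwt_haar(img)
  expect_equal(sum(img^2),
               sum(d$A^2) + sum(d$H^2) + sum(d$V^2) + sum(d$D^2),
               tolerance = 1e-6)
  # oracle: separable filter-and-downsample with orthonormal Haar taps
  lo <- c(1, 1) / sqrt(2); hi <- c(1, -1) / sqrt(2)
  filt_cols <- function(m, k) k[1] * m[seq(1, nrow(m), 2), ] +
    k[2] * m[seq(2, nrow(m), 2), ]
  filt_rows <- function(m, k) k[1] * m[, seq(1, ncol(m), 2)] +
    k[2] * m[, seq(2, ncol(m), 2)]
  expect_equal(d$A, filt_rows(filt_cols(img, lo), lo), tolerance = 1e-12)
  expect_equal(d$H, filt_rows(filt_cols(img, hi), lo), tolerance = 1e-12)
  expect_equal(d$V, filt_rows(filt_cols(img, lo), hi), tolerance = 1e-12)
  expect_equal(d$D, filt_rows(filt_cols(img, hi), hi), tolerance = 1e-12)
})

test_that("Haar transform is linear and invertible", {
  set.seed(7)
  a <- matrix(runif(256), 16, 16); b <- matrix(runif(256), 16, 16)
  da <- dwt_haar(a); db <- dwt_haar(b); dc <- dwt_haar(2 * a - 3 * b)
  for (band in c("A", "H", "V", "D"))
    expect_equal(dc[[band]], 2 * da[[band]] - 3 * db[[band]],
                 tolerance = 1e-9)
  expect_equal(idwt_haar(da), a, tolerance = 1e-9)
})

test_that("odd dimensions pad symmetrically; tiny images error", {
  d <- dwt_haar(matrix(runif(15 * 9), 15, 9))
  expect_equal(dim(d$A), c(8L, 5L))
  expect_error(dwt_haar(matrix(1, 1, 1)), "2x2")
})

test_that("mask downscaling is 2x2 OR-pooling", {
  m <- matrix(FALSE, 4, 4); m[3, 2] <- TRUE
  half <- downscale_mask(binary_mask(m, "full"))
  expect_equal(dim(half), c(2L, 2L))
  expect_equal(sum(half), 1)
  expect_true(half[2, 1])
  full <- binary_mask(matrix(TRUE, 6, 6), "full")
  expect_true(all(downscale_mask(full)))
  expect_error(downscale_mask(downscale_mask(full)), "full-scale")
})

test_that("OR-pooling matches an exhaustive block check on random masks", {
  set.seed(11)
  m <- matrix(runif(64 * 64) < 0.2, 64, 64)
  half <- downscale_mask(binary_mask(m, "full"))
  for (i in seq_len(32)) for (j in seq_len(32)) {
    blk <- m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    expect_identical(half[i, j], any(blk))
  }
})

test_that("mask upscaling replicates and round-trips as a superset", {
  half <- binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), "half")
  full <- upscale_mask(half, c(4, 4))
  expect_equal(sum(full), 4)
  expect_true(all(full[1:2, 1:2]))
  set.seed(3)
  for (k in 1:5) {
    m <- binary_mask(matrix(runif(49) < 0.3, 7, 7), "full")
    rt <- upscale_mask(downscale_mask(m), dim(m))
    expect_true(all(rt[as.logical(m)]))
  }
  expect_error(upscale_mask(half, c(10, 10)), "incompatible")
  expect_error(upscale_mask(binary_mask(matrix(TRUE, 2, 2), "full"), c(4, 4)),
               "half-scale")
})
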