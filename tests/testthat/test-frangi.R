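test_that("the Hessian of a constant image vanishes", {
  h <- hessian_at_scale(matrix(2, 40, 40), sigma = 2)
  expect_equal(max(abs(h$h11)), 0, tolerance = 1e-10)
  expect_equal(max(abs(h$h12)), 0, tolerance = 1e-10)
  expect_equal(max(abs(h$h22)), 0, tolerance = 1e-10)
})

test_that("the Hessian of a quadratic matches the analytic derivatives", {
  # f(x, y) = x^2 with x along columns: d2/dx2 = 2, mixed and d2/dy2 = 0.
  n <- 80
  img <- matrix(rep(((1:n) / n)^2, each = n), n, n)
  sigma <- 2
  h <- hessian_at_scale(img, sigma)
  inner <- 30:50
  expect_equal(mean(h$h11[inner, inner]), sigma * 2 / n^2, tolerance = 1e-3)
  expect_lt(max(abs(h$h12[inner, inner])), 1e-8)
  expect_lt(max(abs(h$h22[inner, inner])), 1e-8)
  expect_error(hessian_at_scale(img, 0), "sigma")
  expect_error(hessian_at_scale(img, -1), "sigma")
})

test_that("h12 equals the transposed mixed derivative", {
  set.seed(13)
  img <- matrix(runif(60 * 60), 60, 60)
  h <- hessian_at_scale(img, 1.5)
  ht <- hessian_at_scale(t(img), 1.5)
  expect_lt(max(abs(h$h12 - t(ht$h12))), 1e-10)
  expect_lt(max(abs(h$h11 - t(ht$h22))), 1e-10)
})

fake_field <- function(h11, h12, h22) {
  structure(list(h11 = matrix(h11, 1, 1), h12 = matrix(h12, 1, 1),
                 h22 = matrix(h22, 1, 1), sigma = 1),
            class = "hessian_field")
}

test_that("closed-form eigenvalues are ordered by magnitude", {
  e <- eigen_decompose(fake_field(2, 0, -5))
  expect_equal(e$lambda1[1, 1], 2)
  expect_equal(e$lambda2[1, 1], -5)
  e2 <- eigen_decompose(fake_field(0, 1, 0))
  expect_setequal(c(e2$lambda1[1, 1], e2$lambda2[1, 1]), c(-1, 1))
})

test_that("eigenvalues match a generic eigensolver on random fields", {
  set.seed(21)
  n <- 40
  h <- structure(list(h11 = matrix(rnorm(n * n), n, n),
                      h12 = matrix(rnorm(n * n), n, n),
                      h22 = matrix(rnorm(n * n), n, n), sigma = 1),
                 class = "hessian_field")
  e <- eigen_decompose(h)
  expect_true(all(abs(e$lambda1) <= abs(e$lambda2) + 1e-12))
  for (k in sample(n * n, 50)) {
    ij <- arrayInd(k, c(n, n))
    m <- matrix(c(h$h11[k], h$h12[k], h$h12[k], h$h22[k]), 2, 2)
    ref <- sort(eigen(m, symmetric = TRUE)$values)
    got <- sort(c(e$lambda1[ij[1], ij[2]], e$lambda2[ij[1], ij[2]]))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("structure patterns follow the eigenvalue table", {
  pat <- function(l1, l2, floor = 0.1) {
    e <- structure(list(lambda1 = matrix(l1, 1, 1),
                        lambda2 = matrix(l2, 1, 1)), class = "eigen_pair")
    classify_structure(e, noise_floor = floor)[1, 1]
  }
  expect_equal(pat(0.01, -10), "vessel_bright")
  expect_equal(pat(0.01, 10), "vessel_dark")
  expect_equal(pat(-8, -10), "blob_bright")
  expect_equal(pat(8, 10), "blob_dark")
  expect_equal(pat(0.001, 0.002), "noisy")
})

test_that("vesselness is zero on flat regions and wherever lambda2 > 0", {
  flat <- vesselness_at_scale(matrix(1, 40, 40), sigma = 2, c = 1)
  expect_equal(max(flat), 0)
  # dark bar on bright background: lambda2 > 0 at the bar centre
  img <- matrix(1, 64, 64); img[30:34, ] <- 0
  v <- vesselness_at_scale(img, sigma = 3)
  h <- hessian_at_scale(img, 3)
  e <- eigen_decompose(h)
  expect_true(all(v[e$lambda2 > 0] == 0))
  expect_equal(v[32, 32], 0)
})

test_that("a width-5 bright bar responds maximally at its centre for sigma 5", {
  img <- matrix(0, 128, 128); img[62:66, ] <- 1
  v5 <- vesselness_at_scale(img, sigma = 5)
  expect_equal(v5[64, 64], max(v5), tolerance = 1e-6)
  v1 <- vesselness_at_scale(img, sigma = 1)
  expect_gt(v5[64, 64], v1[64, 64])
  expect_true(all(v5 >= 0 & v5 <= 1))
})

test_that("single-scale response equals a direct per-pixel evaluation", {
  img <- matrix(0, 128, 128); img[62:66, ] <- 1
  sigma <- 5; beta <- 0.5
  v <- vesselness_at_scale(img, sigma, beta = beta)
  cval <- attr(v, "c")
  h <- hessian_at_scale(img, sigma)
  oracle <- matrix(0, 128, 128)
  for (i in seq_len(128)) for (j in seq_len(128)) {
    m <- matrix(c(h$h11[i, j], h$h12[i, j], h$h12[i, j], h$h22[i, j]), 2, 2)
    ev <- eigen(m, symmetric = TRUE)$values
    ev <- ev[order(abs(ev))]
    if (ev[2] > 0 || (ev[1] == 0 && ev[2] == 0)) next
    rb <- ev[1] / ev[2]; s2 <- sum(ev^2)
    oracle[i, j] <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cval^2)))
  }
  expect_equal(as.vector(v), as.vector(oracle), tolerance = 1e-8)
})

test_that("multi-scale response is the pointwise maximum over scales", {
  img <- matrix(0, 96, 96); img[40:48, ] <- 1
  single <- frangi_multiscale(img, sigmas = 3)
  direct <- vesselness_at_scale(img, 3)
  expect_equal(single$response, matrix(direct, 96, 96))
  two <- frangi_multiscale(img, sigmas = c(3, 7))
  expect_true(all(two$response >= single$response - 1e-12))
  expect_error(frangi_multiscale(img, sigmas = numeric(0)), "at least one")
})

test_that("a two-width bar image peaks near both bars", {
  img <- matrix(0, 128, 128); img[30:32, ] <- 1; img[90:98, ] <- 1
  vm <- frangi_multiscale(img)
  expect_gt(vm$response[31, 64], 0.8 * max(vm$response))
  expect_gt(vm$response[94, 64], 0.8 * max(vm$response))
  expect_gt(vm$argmax_sigma[94, 64], vm$argmax_sigma[31, 64])
})

test_that("vesselness is invariant to an intensity offset", {
  set.seed(31)
  img <- matrix(runif(64 * 64), 64, 64)
  v1 <- frangi_multiscale(img, sigmas = c(1, 3))
  v2 <- frangi_multiscale(img + 0.3, sigmas = c(1, 3))
  expect_equal(v1$response, v2$response, tolerance = 1e-10)
})

test_that("response maps rotate with the image", {
  img <- matrix(0, 128, 128); img[62:66, ] <- 1
  m1 <- vessel_mask(frangi_multiscale(img), 0.25)
  m2 <- vessel_mask(frangi_multiscale(t(img)), 0.25)  # 90-degree rotation
  m2r <- t(matrix(as.logical(m2), 128, 128))
  iou <- sum(m1 & m2r) / sum(m1 | m2r)
  expect_gte(iou, 0.9)
})

test_that("vessel mask thresholding behaves at the limits", {
  zero <- structure(list(response = matrix(0, 8, 8), argmax_sigma = NULL,
                         sigmas = 1, beta = 0.5, c_used = 1, gamma = 1),
                    class = "vesselness_map")
  expect_equal(sum(vessel_mask(zero, 0.5)), 0)
  img <- matrix(0, 96, 96); img[40:44, ] <- 1
  vm <- frangi_multiscale(img)
  m <- vessel_mask(vm, 1e-6)
  expect_equal(as.logical(m), as.vector(vm$response > 1e-6 * max(vm$response)))
  expect_error(vessel_mask(vm, 0), "tau_rel")
  expect_error(vessel_mask(vm, 1), "tau_rel")
})

test_that("crossings light up more than spikes on synthetic scenes", {
  sc <- fixture_scene()
  vm <- frangi_multiscale(lab_lightness(sc$image))
  vmask <- vessel_mask(vm)
  expect_gte(mean(as.logical(vmask)[as.logical(sc$crossing_mask)]), 0.6)
  expect_lt(mean(vm$response[as.logical(sc$spike_mask)]),
            mean(vm$response[as.logical(sc$crossing_mask)]))
})
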