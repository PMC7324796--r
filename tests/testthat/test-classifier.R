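# A hand-built classifier whose prediction rule is known exactly:
# spike iff f1 > 0 (steep logistic on the first feature).
rule_model <- function() {
  structure(list(
    n_in = 8L, hidden = 10L,
    center = rep(0, 8), scale = rep(1, 8),
    w1 = rbind(c(50, rep(0, 7)), matrix(0, 9, 8)), b1 = rep(0, 10),
    w2 = rbind(c(40, rep(0, 9)), rep(0, 10)), b2 = c(-20, 0),
    train_seed = 0L, epochs = 0L, val_loss = NA_real_,
    levels = c("spike", "nonspike")), class = "spike_classifier")
}

# An always-spike predictor.
constant_model <- function() {
  m <- rule_model()
  m$w1[] <- 0; m$w2[] <- 0; m$b2 <- c(10, 0)
  m
}

feature_table <- function(f1, label) {
  tab <- tibble::as_tibble(setNames(as.data.frame(
    cbind(f1, matrix(0, length(f1), 7))), paste0("f", 1:8)))
  tab$label <- label
  tab
}

cloud_table <- function(n, shift = 3, sd = 0.1, seed = 1) {
  set.seed(seed)
  sp <- matrix(rnorm(n * 8, shift, sd), n, 8)
  ns <- matrix(rnorm(n * 8, 0, sd), n, 8)
  tab <- tibble::as_tibble(as.data.frame(rbind(sp, ns)))
  names(tab) <- paste0("f", 1:8)
  tab$label <- rep(c("spike", "nonspike"), each = n)
  tab[sample(nrow(tab)), ]
}

test_that("stratified split gives 70:15:15 per class, disjoint and complete", {
  tab <- feature_table(rnorm(2000), rep(c("spike", "nonspike"), each = 1000))
  tab$id <- seq_len(2000)
  s <- split_pixels(tab, seed = 3)
  for (cls in c("spike", "nonspike")) {
    expect_equal(sum(s$training$label == cls), 700)
    expect_equal(sum(s$testing$label == cls), 150)
    expect_equal(sum(s$validation$label == cls), 150)
  }
  ids <- sort(c(s$training$id, s$testing$id, s$validation$id))
  expect_identical(ids, tab$id)           # disjoint union = input
  s2 <- split_pixels(tab, seed = 3)
  expect_identical(s, s2)
  expect_error(split_pixels(feature_table(1:4, c("spike", "spike",
                                                 "spike", "nonspike"))),
               "at least 3")
})

test_that("split preserves the class ratio in every part", {
  tab <- feature_table(rnorm(1340), rep(c("spike", "nonspike"),
                                        c(340, 1000)))
  s <- split_pixels(tab, seed = 5)
  global <- 340 / 1340
  for (part in s) {
    expect_equal(mean(part$label == "spike"), global, tolerance = 0.01)
  }
})

test_that("training separates shifted Gaussian clouds almost perfectly", {
  tab <- cloud_table(400, shift = 3, sd = 0.1, seed = 2)
  s <- split_pixels(tab, seed = 2)
  m <- train_classifier(s$training, s$validation, seed = 4)
  # oracle: the clouds are linearly separable at f1 = 1.5
  expect_true(all((tab$f1 > 1.5) == (tab$label == "spike")))
  ev <- evaluate_classifier(m, s$testing)
  expect_gte(ev$accuracy, 0.99)
  expect_equal(dim(m$w1), c(10L, 8L))
  expect_equal(dim(m$w2), c(2L, 10L))
  expect_length(m$b1, 10)
  expect_length(m$b2, 2)
})

test_that("shuffled labels train to chance level", {
  tab <- cloud_table(1000, shift = 3, sd = 0.1, seed = 6)
  set.seed(9)
  tab$label <- sample(tab$label)    # destroy the signal
  s <- split_pixels(tab, seed = 7)
  m <- train_classifier(s$training, s$validation, seed = 8)
  ev <- evaluate_classifier(m, s$validation)
  prior <- max(mean(s$validation$label == "spike"),
               mean(s$validation$label == "nonspike"))
  expect_lte(abs(ev$accuracy - prior), 0.05)
})

test_that("training is reproducible and validates its inputs", {
  tab <- cloud_table(100, seed = 3)
  s <- split_pixels(tab, seed = 1)
  m1 <- train_classifier(s$training, s$validation, seed = 5)
  m2 <- train_classifier(s$training, s$validation, seed = 5)
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
  bad <- s$training
  bad$f3[2] <- NA
  expect_error(train_classifier(bad, s$validation, seed = 1), "non-finite")
  onecls <- s$training[s$training$label == "spike", ]
  expect_error(train_classifier(onecls, s$validation, seed = 1),
               "both classes")
})

test_that("confusion metrics follow the stated formulas", {
  # 9 true spikes + 1 miss, 9 true non-spikes + 1 false alarm
  tab <- feature_table(c(rep(1, 9), -1, rep(-1, 9), 1),
                       rep(c("spike", "nonspike"), each = 10))
  ev <- evaluate_classifier(rule_model(), tab)
  expect_equal(ev$tp, 9); expect_equal(ev$fn, 1)
  expect_equal(ev$tn, 9); expect_equal(ev$fp, 1)
  expect_equal(ev$tp_rate, 0.9)
  expect_equal(ev$tn_rate, 0.9)
  expect_equal(ev$accuracy, 0.9)

  perfect <- feature_table(c(1, 1, -1, -1),
                           c("spike", "spike", "nonspike", "nonspike"))
  evp <- evaluate_classifier(rule_model(), perfect)
  expect_equal(c(evp$tp_rate, evp$tn_rate, evp$accuracy), c(1, 1, 1))
  expect_error(evaluate_classifier(rule_model(), perfect[0, ]), "empty")
})

test_that("an all-spike predictor scores the class prior", {
  tab <- feature_table(rnorm(400), rep(c("spike", "nonspike"), c(100, 300)))
  ev <- evaluate_classifier(constant_model(), tab)
  expect_equal(ev$accuracy, 0.25)
  expect_equal(ev$tp_rate, 1)
  expect_equal(ev$tn_rate, 0)
})

test_that("confusion counts are additive over table unions", {
  t1 <- feature_table(rnorm(50), sample(c("spike", "nonspike"), 50, TRUE))
  t2 <- feature_table(rnorm(70), sample(c("spike", "nonspike"), 70, TRUE))
  m <- rule_model()
  e1 <- evaluate_classifier(m, t1)
  e2 <- evaluate_classifier(m, t2)
  eu <- evaluate_classifier(m, dplyr::bind_rows(t1, t2))
  for (cell in c("tp", "fp", "fn", "tn"))
    expect_equal(eu[[cell]], e1[[cell]] + e2[[cell]])
})

test_that("image classification respects the plant mask", {
  fx <- fixture_features()
  dims <- dim(fx$stack)[1:2]
  m <- fixture_model()
  empty <- binary_mask(matrix(FALSE, dims[1], dims[2]), "half")
  expect_equal(sum(classify_image(m, fx$stack, empty)), 0)
  plant_half <- downscale_mask(color_index_segment(fx$scene$image))
  out <- classify_image(m, fx$stack, plant_half)
  expect_true(all(as.logical(plant_half)[as.logical(out)]))
  expect_equal(mask_scale(out), "half")
})

test_that("most half-scale spike pixels are recovered on a fresh scene", {
  m <- fixture_model()
  sc <- generate_scene(scene_spec(rng_seed = 4040))
  A <- dwt_haar(to_grayscale(sc$image))$A
  st <- laws_features(A)
  plant_half <- downscale_mask(color_index_segment(sc$image))
  out <- classify_image(m, st, plant_half)
  gt_half <- wheatspike:::downscale_pool(sc$spike_mask, 3L)
  expect_gte(mean(as.logical(out)[as.logical(gt_half)]), 0.70)
})

test_that("model save/load round-trips predictions bit-exactly", {
  m <- fixture_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  set.seed(12)
  x <- matrix(rnorm(1000 * 8), 1000, 8)
  expect_identical(predict(m, x), predict(m2, x))
  expect_equal(m2$n_in, 8L)
  expect_equal(m2$hidden, 10L)
})

test_that("corrupt model files and feature mismatches error cleanly", {
  m <- fixture_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  txt <- readLines(f)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), f)   # truncate
  expect_error(load_model(f), "corrupt|not a wheatspike")
  expect_error(predict(m, matrix(0, 5, 7)), "expects 8 features")
})

test_that("tidy and glance summarise the network", {
  m <- fixture_model()
  td <- tidy(m)
  expect_equal(nrow(td), (8 + 1) * 10 + (10 + 1) * 2)
  gl <- glance(m)
  expect_equal(gl$n_parameters, 112L)
  expect_equal(gl$hidden_units, 10L)
})
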